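#' State-averaged connectivity per episode
#'
#' For every episode and every state the episode visits, averages the
#' episode's window vectors assigned to that state (on the Fisher-Z scale).
#' Episodes that never visit a state simply contribute no record for it —
#' absence is explicit, never a zero matrix.
#'
#' @param seriesList list of [DynFCSeries-class] objects, in the order used
#'   to build the clustered window matrix.
#' @param model the [StateModel-class] fitted on [poolWindows()] of the same
#'   list (row counts are checked).
#' @return A [StateFCSet-class].
#' @export
computeStateFC <- function(seriesList, model) {
  nw <- vapply(seriesList, nWindows, integer(1))
  if (sum(nw) != length(model@assignments))
    stop("model assignments do not match the total window count of seriesList")
  offs <- c(0L, cumsum(nw))
  rows <- list(); info <- list(); r <- 0L
  for (e in seq_along(seriesList)) {
    s <- seriesList[[e]]
    a <- model@assignments[(offs[e] + 1L):offs[e + 1L]]
    for (k in sort(unique(a))) {
      r <- r + 1L
      sel <- a == k
      rows[[r]] <- colMeans(s@z[sel, , drop = FALSE])
      info[[r]] <- data.frame(subject = s@subjectId, episode = s@episodeId,
                              condition = s@condition, state = k,
                              nWindows = sum(sel), stringsAsFactors = FALSE)
    }
  }
  new("StateFCSet", fc = do.call(rbind, rows), info = do.call(rbind, info),
      p = seriesList[[1L]]@p)
}

#' One episode's state-averaged FC matrix
#'
#' Arithmetic mean of the episode's windows assigned to `state`, or NULL
#' when the episode never visits the state.
#'
#' @param series a [DynFCSeries-class].
#' @param model the fitted [StateModel-class] (must carry window `info`).
#' @param state state index in 1..K.
#' @return symmetric p x p matrix, or NULL when absent.
#' @export
episodeStateFC <- function(series, model, state) {
  state <- as.integer(state)
  if (state < 1L || state > model@K) stop("state out of 1..K")
  if (nrow(model@info) == 0L) stop("model carries no window info")
  sel <- model@info$subject == series@subjectId &
    model@info$episode == series@episodeId &
    model@info$condition == series@condition &
    model@assignments == state
  if (!any(sel)) return(NULL)
  w <- model@info$window[sel]
  unvectorizeUpper(colMeans(series@z[w, , drop = FALSE]), series@p)
}

#' Paired condition contrast of one state's connectivity
#'
#' For each subject, the episode-level state-average matrices are averaged
#' within each condition; only subjects exhibiting the state in both
#' conditions are included. Each upper-triangle edge is then tested with a
#' paired t-test (first condition minus second, so condition-1-stronger
#' edges get positive t), and p-values are Benjamini-Hochberg adjusted
#' across all edges.
#'
#' @param sfc a [StateFCSet-class] for the cohort.
#' @param state state index.
#' @param conditions length-2 character; the contrast is
#'   `conditions[1] - conditions[2]`.
#' @param alpha significance level applied to the adjusted q (default 0.05).
#' @return data.frame with one row per edge: idx, i, j, t, p, q, sig, sign;
#'   attributes `nIncluded` (subjects used), `state`, `df`.
#' @export
stateConditionContrast <- function(sfc, state, conditions = c("happy", "sad"),
                                   alpha = 0.05) {
  info <- sfc@info
  sel <- info$state == state & info$condition %in% conditions
  if (!any(sel)) stop("state never observed under the requested conditions")
  sub <- info[sel, , drop = FALSE]
  fc <- sfc@fc[sel, , drop = FALSE]

  condMean <- function(subject, condition) {
    r <- which(sub$subject == subject & sub$condition == condition)
    if (!length(r)) return(NULL)
    colMeans(fc[r, , drop = FALSE])
  }
  subjects <- unique(sub$subject)
  diffs <- list()
  for (s in subjects) {
    a <- condMean(s, conditions[1L]); b <- condMean(s, conditions[2L])
    if (!is.null(a) && !is.null(b)) diffs[[s]] <- a - b
  }
  n <- length(diffs)
  if (n < 3L)
    stop(sprintf("only %d subject(s) exhibit state %d in both conditions (need >= 3)",
                 n, state))
  D <- do.call(rbind, diffs)
  m <- colMeans(D)
  s2 <- colSums(sweep(D, 2L, m)^2) / (n - 1)
  sdv <- sqrt(s2)
  tstat <- ifelse(sdv > 0, m / (sdv / sqrt(n)),
                  ifelse(m == 0, 0, sign(m) * Inf))
  pval <- 2 * stats::pt(-abs(tstat), df = n - 1)
  pval[!is.finite(tstat)] <- 0
  pval[sdv == 0 & m == 0] <- 1
  q <- fdrBH(pval)
  map <- upperIndexMap(sfc@p)
  out <- data.frame(idx = map$idx, i = map$i, j = map$j, t = tstat, p = pval,
                    q = q, sig = q < alpha, sign = sign(tstat))
  attr(out, "nIncluded") <- n
  attr(out, "state") <- state
  attr(out, "df") <- n - 1
  out
}

#' Network-pair summary of significant contrast edges
#'
#' Mean t-value over the FDR-significant edges of each network pair; pairs
#' with no significant edge are NA (explicitly "no evidence", not zero).
#'
#' @param contrast output of [stateConditionContrast()].
#' @param partition a [NetworkPartition-class] matching the contrast's p.
#' @param alpha significance level on q (default 0.05).
#' @return symmetric nNetworks x nNetworks matrix with NA where no edge is
#'   significant.
#' @export
networkMeanT <- function(contrast, partition, alpha = 0.05) {
  labs <- networkLabels(partition)
  pairs <- edgeNetworkPairs(partition)
  if (length(pairs) != nrow(contrast))
    stop("partition does not match the contrast's edge count")
  out <- matrix(NA_real_, length(labs), length(labs),
                dimnames = list(labs, labs))
  sig <- contrast$q < alpha
  if (any(sig)) {
    means <- tapply(contrast$t[sig], pairs[sig], mean)
    for (nm in names(means)) {
      ab <- strsplit(nm, "--", fixed = TRUE)[[1L]]
      out[ab[1L], ab[2L]] <- out[ab[2L], ab[1L]] <- means[[nm]]
    }
  }
  out
}
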