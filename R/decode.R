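#' Enumerate state-combination models
#'
#' All non-empty subsets of \{1..K\}, ordered by subset size then
#' lexicographically — 15 models for K = 4 (state 1, 2, 3, 4, 12, 13, ...,
#' 1234).
#'
#' @param K number of states (>= 1).
#' @return named list of sorted integer vectors; names like "34".
#' @export
enumerateCombos <- function(K) {
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  combos <- list()
  for (s in seq_len(K)) {
    cb <- combn(K, s)
    for (c2 in seq_len(ncol(cb)))
      combos[[length(combos) + 1L]] <- cb[, c2]
  }
  names(combos) <- vapply(combos, function(x) paste(x, collapse = ""), "")
  combos
}

#' Assemble decoding samples for one state combination
#'
#' One sample per episode: the concatenation, in ascending state order, of
#' the vectorized upper triangles of the episode's state-average matrices
#' for the states in `combo`. Episodes missing any of those states are
#' excluded (and counted), mirroring the both-conditions inclusion rule of
#' the contrast analysis.
#'
#' @param sfc a [StateFCSet-class].
#' @param combo sorted integer vector of states.
#' @return list: `x` (samples x features), `y` (condition factor),
#'   `subjects` (character), `excluded` (episodes dropped), `combo`.
#' @export
buildComboSamples <- function(sfc, combo) {
  combo <- sort(as.integer(combo))
  info <- sfc@info
  key <- paste(info$subject, info$episode, info$condition, sep = "\r")
  eps <- unique(key)
  d <- ncol(sfc@fc)
  xs <- list(); ys <- character(); subj <- character(); excluded <- 0L
  for (e in eps) {
    rows <- which(key == e)
    have <- info$state[rows]
    if (!all(combo %in% have)) { excluded <- excluded + 1L; next }
    v <- unlist(lapply(combo, function(k) sfc@fc[rows[match(k, have)], ]))
    xs[[length(xs) + 1L]] <- v
    ys <- c(ys, info$condition[rows[1L]])
    subj <- c(subj, info$subject[rows[1L]])
  }
  if (!length(xs)) stop("no episode retains all states of the combination")
  list(x = do.call(rbind, xs), y = factor(ys), subjects = subj,
       excluded = excluded, combo = combo)
}

#' ReliefF feature scores
#'
#' Binary-class ReliefF: features are range-scaled to \[0, 1\]; for every
#' sample, the `k` nearest same-class hits and `k` nearest other-class
#' misses (L1 distance) update each feature's score by mean |diff to miss| -
#' mean |diff to hit|. Higher scores mark features that separate the
#' classes locally.
#'
#' @param x samples x features matrix.
#' @param y two-level factor.
#' @param k neighbours per class (default 10).
#' @return numeric score per feature.
#' @export
reliefScores <- function(x, y, k = 10L) {
  y <- factor(y)
  stopifnot(nlevels(y) == 2L)
  n <- nrow(x); d <- ncol(x)
  lo <- apply(x, 2L, min); hi <- apply(x, 2L, max)
  den <- hi - lo; den[den == 0] <- 1
  xn <- sweep(sweep(x, 2L, lo), 2L, den, "/")
  D <- as.matrix(stats::dist(xn, method = "manhattan"))
  W <- numeric(d)
  for (i in seq_len(n)) {
    same <- setdiff(which(y == y[i]), i)
    othr <- which(y != y[i])
    kh <- min(k, length(same)); km <- min(k, length(othr))
    if (kh < 1L || km < 1L) next
    hits <- same[order(D[i, same])[seq_len(kh)]]
    miss <- othr[order(D[i, othr])[seq_len(km)]]
    xi <- xn[i, ]
    W <- W +
      colMeans(abs(xn[miss, , drop = FALSE] - matrix(xi, km, d, byrow = TRUE))) -
      colMeans(abs(xn[hits, , drop = FALSE] - matrix(xi, kh, d, byrow = TRUE)))
  }
  W / n
}

#' Leave-one-subject-out ReliefF + linear SVM decoding
#'
#' Each fold holds out every episode of one subject. Within the fold,
#' features are standardised with training-set statistics, ranked by ReliefF
#' on the training samples, the top `nSelected` retained, and a linear SVM
#' (cost `cost`) fitted; fold accuracy is the fraction of the held-out
#' subject's episodes classified correctly. The per-fold selected feature
#' index sets are recorded for the stable-feature intersection.
#'
#' @param x samples x features matrix.
#' @param y two-level factor of condition labels.
#' @param subjects subject id per sample.
#' @param nSelected features kept per fold (default 1000, capped at d).
#' @param reliefNeighbors ReliefF neighbours (default 10).
#' @param cost linear-SVM cost (default 1).
#' @param standardize standardise per training fold (default TRUE).
#' @param seed optional integer seed.
#' @return list of class `decodingResult`: `foldAccuracy` (named by held-out
#'   subject), `mean`, `sd`, `selected` (list of index sets), plus settings.
#' @export
losoDecode <- function(x, y, subjects, nSelected = 1000L,
                       reliefNeighbors = 10L, cost = 1, standardize = TRUE,
                       seed = NULL) {
  y <- factor(y)
  stopifnot(nlevels(y) == 2L, nrow(x) == length(y), length(subjects) == length(y))
  subs <- unique(subjects)
  if (length(subs) < 2L) stop("need at least 2 subjects")
  if (!is.null(seed)) set.seed(seed)
  nSelected <- min(as.integer(nSelected), ncol(x))

  acc <- numeric(length(subs))
  selected <- vector("list", length(subs))
  for (f in seq_along(subs)) {
    te <- subjects == subs[f]
    xtr <- x[!te, , drop = FALSE]; ytr <- droplevels(y[!te])
    if (nlevels(ytr) < 2L)
      stop(sprintf("training split for subject %s lost a class", subs[f]))
    xte <- x[te, , drop = FALSE]
    if (standardize) {
      mu <- colMeans(xtr)
      sg <- apply(xtr, 2L, stats::sd); sg[sg == 0] <- 1
      xtr <- sweep(sweep(xtr, 2L, mu), 2L, sg, "/")
      xte <- sweep(sweep(xte, 2L, mu), 2L, sg, "/")
    }
    sc <- reliefScores(xtr, ytr, k = reliefNeighbors)
    sel <- sort(order(sc, decreasing = TRUE)[seq_len(nSelected)])
    fit <- e1071::svm(xtr[, sel, drop = FALSE], ytr, kernel = "linear",
                      cost = cost, scale = FALSE)
    pred <- predict(fit, xte[, sel, drop = FALSE])
    acc[f] <- mean(as.character(pred) == as.character(y[te]))
    selected[[f]] <- sel
  }
  structure(list(foldAccuracy = setNames(acc, subs), mean = mean(acc),
                 sd = stats::sd(acc), selected = selected,
                 nSelected = nSelected, cost = cost,
                 reliefNeighbors = reliefNeighbors),
            class = "decodingResult")
}

#' @export
print.decodingResult <- function(x, ...) {
  cat(sprintf("LOSO decoding: %.2f +- %.2f%% over %d folds (top %d features)\n",
              100 * x$mean, 100 * x$sd, length(x$foldAccuracy), x$nSelected))
  invisible(x)
}

#' Optimal-model rule over state combinations
#'
#' Among the combinations whose mean accuracy lies within `tolerance` of the
#' maximum, returns the one with the smallest accuracy SD; remaining ties
#' break deterministically toward the earlier combination. The tolerance
#' reconciles the highest-mean and smallest-SD criteria when two models are
#' practically equivalent (on Table-2-style percentage summaries the default
#' is 0.5 points).
#'
#' @param means,sds aligned numeric vectors (any common scale).
#' @param tolerance accuracy band below the maximum (same scale as `means`).
#' @return integer index of the selected combination (named if `means` is).
#' @export
selectOptimalModel <- function(means, sds, tolerance = 0.5) {
  stopifnot(length(means) == length(sds), length(means) >= 1L)
  cand <- which(means >= max(means) - tolerance)
  idx <- cand[which.min(sds[cand])]
  if (!is.null(names(means))) names(idx) <- names(means)[idx]
  idx
}

#' Stable features across cross-validation folds
#'
#' The intersection of the per-fold selected feature index sets; an empty
#' intersection is legal and yields all-zero DEFN weights downstream.
#'
#' @param selected list of integer index vectors, one per fold.
#' @export
stableFeatures <- function(selected) {
  stopifnot(length(selected) >= 1L)
  sort(Reduce(intersect, selected))
}

#' DEFN weights from stable features
#'
#' Maps each stable index of a combination's concatenated feature space back
#' to its state block and (ROI_i, ROI_j) edge, takes the union of edge
#' identities across state blocks (an edge stable in several states counts
#' once), and weights every network pair by the fraction of its edges in
#' that union: |union ∩ edges(A,B)| / |edges(A,B)|.
#'
#' @param stable integer indices into the concatenated feature space.
#' @param combo sorted states of the model the features came from.
#' @param partition a [NetworkPartition-class].
#' @return A [DefnWeights-class] covering all network pairs.
#' @export
defnWeights <- function(stable, combo, partition) {
  p <- nRois(partition)
  d <- p * (p - 1L) / 2L
  combo <- sort(as.integer(combo))
  stable <- as.integer(stable)
  if (length(stable) && (min(stable) < 1L || max(stable) > d * length(combo)))
    stop("stable feature index out of range for the combination")
  edges <- unique((stable - 1L) %% d + 1L)
  pairs <- allNetworkPairs(partition)
  epairs <- edgeNetworkPairs(partition)
  cnt <- table(epairs[edges])
  pairs$stableCount <- as.integer(ifelse(is.na(match(pairs$pair, names(cnt))),
                                         0L, cnt[pairs$pair]))
  pairs$weight <- ifelse(pairs$edgeCount > 0,
                         pairs$stableCount / pairs$edgeCount, 0)
  new("DefnWeights",
      table = pairs[, c("netA", "netB", "pair", "stableCount", "edgeCount",
                        "weight")],
      labels = networkLabels(partition))
}

#' @describeIn defnWeights the pair table of a `DefnWeights` object.
#' @param w a `DefnWeights`.
#' @export
weightTable <- function(w) w@table

#' @describeIn defnWeights symmetric nNetworks x nNetworks weight matrix.
#' @export
weightMatrix <- function(w) {
  labs <- w@labels
  m <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  tb <- w@table
  for (r in seq_len(nrow(tb)))
    m[tb$netA[r], tb$netB[r]] <- m[tb$netB[r], tb$netA[r]] <- tb$weight[r]
  m
}

#' Compare decoding models against a reference
#'
#' For each non-reference combination, the paired per-fold accuracy
#' differences (reference minus competitor) are gated by a Lilliefors
#' normality test at alpha 0.05: normal differences get a paired t-test,
#' non-normal ones a Wilcoxon signed-rank test. P-values are
#' Benjamini-Hochberg adjusted across the comparisons. All-zero differences
#' report p = 1.
#'
#' @param accMatrix folds x combos matrix of per-fold accuracies (columns
#'   named; folds paired by subject).
#' @param reference column name or index of the reference combination.
#' @return data.frame: combo, method, statistic, p, q.
#' @export
compareModels <- function(accMatrix, reference) {
  accMatrix <- as.matrix(accMatrix)
  if (is.character(reference)) reference <- match(reference, colnames(accMatrix))
  stopifnot(!is.na(reference))
  others <- setdiff(seq_len(ncol(accMatrix)), reference)
  res <- lapply(others, function(j) {
    d <- accMatrix[, reference] - accMatrix[, j]
    if (all(d == 0))
      return(data.frame(combo = colnames(accMatrix)[j], method = "degenerate",
                        statistic = 0, p = 1))
    normal <- tryCatch(lilliefors(d)$p >= 0.05, error = function(e) TRUE)
    r <- if (normal) pairedT(d) else wilcoxonSignedRank(d)
    data.frame(combo = colnames(accMatrix)[j], method = r$method,
               statistic = r$statistic, p = r$p)
  })
  out <- do.call(rbind, res)
  out$q <- fdrBH(out$p)
  rownames(out) <- NULL
  out
}
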