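#' Two-step L1 k-means state clustering
#'
#' Clusters pooled window vectors into K recurring brain states with the
#' cityblock k-means variant: nearest-centroid assignment under the L1
#' metric and coordinate-wise median centroid updates. Step 1 runs the
#' algorithm to convergence from `nInit` random starts (initial centroids
#' drawn uniformly from the data rows) and keeps the best-inertia solution;
#' step 2 re-clusters all windows initialised at those centroids for at most
#' `maxIter` iterations. An empty cluster is repaired by reseeding its
#' centroid at the point farthest from its current centroid.
#'
#' @param x numeric matrix, windows x features (vectorized upper triangles).
#' @param K number of states.
#' @param nInit random restarts in step 1 (default 100).
#' @param maxIter iteration cap per run (default 1000).
#' @param seed integer seed making the restarts reproducible.
#' @param info optional data.frame (subject, episode, condition, window)
#'   aligned with the rows of `x`, as produced by [poolWindows()].
#' @return A [StateModel-class].
#' @export
clusterStatesTwoStep <- function(x, K, nInit = 100L, maxIter = 1000L,
                                 seed = NULL, info = NULL) {
  x <- as.matrix(x)
  K <- as.integer(K)
  n <- nrow(x)
  if (n <= K) stop("need more windows than states")
  if (anyNA(x)) stop("window matrix contains NaN edges; drop degenerate windows first")
  if (!is.null(seed)) set.seed(seed)

  best <- NULL
  for (r in seq_len(nInit)) {
    init <- x[sample.int(n, K), , drop = FALSE]
    fit <- cpp_l1_kmeans(x, init, as.integer(maxIter))
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  step1 <- best$inertia
  fit2 <- cpp_l1_kmeans(x, best$centroids, as.integer(maxIter))

  if (is.null(info)) info <- data.frame()
  new("StateModel", K = K, centroids = fit2$centroids,
      assignments = as.integer(fit2$cluster), info = info,
      inertia = fit2$inertia, step1Inertia = step1)
}

#' Elbow-based selection of the state count
#'
#' Fits the two-step clustering at each candidate K, records the total
#' within-cluster L1 inertia J(K), and returns the interior K maximising the
#' discrete second difference J(K-1) - 2 J(K) + J(K+1) — the sharpest drop
#' in the rate of improvement.
#'
#' @param x windows x features matrix.
#' @param kRange ascending integer candidates (length >= 3, max < nrow(x)).
#' @param nInit,maxIter,seed forwarded to [clusterStatesTwoStep()].
#' @return the selected K, with the inertia profile in attribute `"inertia"`.
#' @export
elbowSelectK <- function(x, kRange, nInit = 20L, maxIter = 200L, seed = NULL) {
  kRange <- as.integer(kRange)
  if (length(kRange) < 3L) stop("kRange must contain at least 3 values")
  if (is.unsorted(kRange, strictly = TRUE)) stop("kRange must be strictly ascending")
  if (min(kRange) < 1L || max(kRange) >= nrow(x)) stop("kRange out of range")
  if (!is.null(seed)) set.seed(seed)
  J <- vapply(kRange, function(k)
    clusterStatesTwoStep(x, k, nInit = nInit, maxIter = maxIter)@inertia,
    numeric(1))
  structure(elbowFromInertia(J, kRange), inertia = setNames(J, kRange))
}

#' @describeIn elbowSelectK the elbow rule itself: given the inertia profile
#'   J over `kRange`, return the interior K maximising the discrete second
#'   difference (first on ties).
#' @param J numeric inertia per candidate K.
#' @export
elbowFromInertia <- function(J, kRange) {
  stopifnot(length(J) == length(kRange), length(J) >= 3L)
  interior <- 2:(length(J) - 1L)
  d2 <- J[interior - 1L] - 2 * J[interior] + J[interior + 1L]
  kRange[interior[which.max(d2)]]
}

#' Majority latent state per analysis window
#'
#' Reduces a per-time-point latent state path to one label per sliding
#' window (the modal state inside the window, earliest state on ties), for
#' comparing clustered window assignments against generator ground truth.
#'
#' @param path integer state per time point.
#' @param windowLength,step window parameters matching [slidingWindowFC()].
#' @export
windowMajorityStates <- function(path, windowLength = 30L, step = 2L) {
  n <- length(path)
  nw <- (n - windowLength) %/% step + 1L
  vapply(seq_len(nw), function(w) {
    seg <- path[((w - 1L) * step + 1L):((w - 1L) * step + windowLength)]
    tab <- table(seg)
    as.integer(names(tab)[which.max(tab)])
  }, integer(1))
}

#' State occupancy frequencies
#'
#' Proportion of all windows assigned to each state; sums to 1.
#'
#' @param model a [StateModel-class].
#' @export
stateFrequencies <- function(model) {
  tab <- tabulate(model@assignments, nbins = model@K)
  setNames(tab / length(model@assignments), paste0("state", seq_len(model@K)))
}

#' Mean dwell time per state for one episode
#'
#' Mean length (in windows) of the consecutive runs an episode spends in
#' each state before switching; states the episode never visits are NA.
#'
#' @param states integer vector of one episode's window-state sequence.
#' @param K number of states.
#' @export
dwellTime <- function(states, K) {
  r <- rle(as.integer(states))
  out <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    len <- r$lengths[r$values == k]
    if (length(len)) out[k] <- mean(len)
  }
  setNames(out, paste0("state", seq_len(K)))
}

#' Empirical state transition matrix for one episode
#'
#' transition\[i, j\] = count(i -> j) / count(i -> any) over consecutive
#' window pairs. States with no outgoing transitions receive a uniform row
#' and are flagged in attribute `"noOutgoing"`.
#'
#' @param states integer window-state sequence (length >= 2).
#' @param K number of states.
#' @return K x K row-stochastic matrix.
#' @export
transitionMatrix <- function(states, K) {
  states <- as.integer(states)
  if (length(states) < 2L) stop("need at least 2 windows")
  cnt <- matrix(0, K, K)
  for (t in seq_len(length(states) - 1L))
    cnt[states[t], states[t + 1L]] <- cnt[states[t], states[t + 1L]] + 1
  rs <- rowSums(cnt)
  none <- which(rs == 0)
  P <- cnt / ifelse(rs > 0, rs, 1)
  P[none, ] <- 1 / K
  dimnames(P) <- rep(list(paste0("state", seq_len(K))), 2)
  attr(P, "noOutgoing") <- none
  P
}
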