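#' Sliding-window dynamic functional connectivity
#'
#' Splits a T x p ROI time series into overlapping windows of
#' `windowLength` time points advancing by `step`, computes the Pearson
#' correlation between every ROI pair within each window, and (by default)
#' applies the Fisher Z transform. Window i (0-based) covers the half-open
#' row range \[i*step, i*step + windowLength); the window count is
#' floor((T - windowLength)/step) + 1, e.g. 286 windows for a 600-point
#' series at window 30 / step 2.
#'
#' A ROI with zero variance inside a window yields NaN edges for that window
#' (with a warning); downstream consumers must reject such windows.
#'
#' @param ts numeric matrix, time points x ROIs.
#' @param windowLength window length in time points (default 30).
#' @param step sliding step in time points (default 2).
#' @param fisherZ apply arctanh with clipping (default TRUE).
#' @param subjectId,episodeId,condition episode identity carried along.
#' @return A [DynFCSeries-class] with one row of vectorized upper-triangle
#'   values per window.
#' @export
slidingWindowFC <- function(ts, windowLength = 30L, step = 2L,
                            fisherZ = TRUE, subjectId = NA_character_,
                            episodeId = NA_character_,
                            condition = NA_character_) {
  ts <- as.matrix(ts)
  if (anyNA(ts)) stop("time series contains missing values")
  tlen <- nrow(ts)
  p <- ncol(ts)
  windowLength <- as.integer(windowLength)
  step <- as.integer(step)
  if (windowLength < 2L) stop("windowLength must be >= 2")
  if (step < 1L) stop("step must be >= 1")
  if (tlen < windowLength) stop("series shorter than one window")

  nw <- (tlen - windowLength) %/% step + 1L
  starts <- (seq_len(nw) - 1L) * step
  map <- upperIndexMap(p)
  z <- matrix(NA_real_, nw, nrow(map))
  degenerate <- 0L
  for (w in seq_len(nw)) {
    seg <- ts[(starts[w] + 1L):(starts[w] + windowLength), , drop = FALSE]
    sds <- apply(seg, 2L, stats::sd)
    if (any(sds == 0)) degenerate <- degenerate + 1L
    r <- suppressWarnings(stats::cor(seg))
    v <- r[cbind(map$i, map$j)]
    z[w, ] <- if (fisherZ) defnet::fisherZ(v) else v
  }
  z[is.na(z)] <- NaN
  if (degenerate > 0L)
    warning(sprintf("%d window(s) contain a zero-variance ROI; NaN edges emitted",
                    degenerate))
  new("DynFCSeries", z = z, p = as.integer(p), windowStarts = starts,
      windowLength = windowLength, step = step, fisherZ = isTRUE(fisherZ),
      subjectId = as.character(subjectId), episodeId = as.character(episodeId),
      condition = as.character(condition))
}

#' @describeIn slidingWindowFC number of windows of a series.
#' @param x a `DynFCSeries`.
#' @export
nWindows <- function(x) nrow(x@z)

#' @describeIn slidingWindowFC reconstruct window `w` as a symmetric p x p
#'   matrix (diagonal 0 on the Z scale).
#' @param w window index (1-based).
#' @export
windowMatrix <- function(x, w) unvectorizeUpper(x@z[w, ], x@p)

#' Pool the windows of many episodes into one matrix
#'
#' Stacks the vectorized windows of a list of [DynFCSeries-class] objects
#' into the N x d input of the state clustering, with an aligned info
#' data.frame (subject, episode, condition, window) describing every row.
#'
#' @param seriesList list of `DynFCSeries` with identical p.
#' @return list with elements `x` (matrix) and `info` (data.frame).
#' @export
poolWindows <- function(seriesList) {
  stopifnot(length(seriesList) > 0)
  ps <- vapply(seriesList, function(s) s@p, integer(1))
  if (length(unique(ps)) != 1L) stop("all series must share the same p")
  x <- do.call(rbind, lapply(seriesList, function(s) s@z))
  info <- do.call(rbind, lapply(seriesList, function(s)
    data.frame(subject = s@subjectId, episode = s@episodeId,
               condition = s@condition, window = seq_len(nrow(s@z)),
               stringsAsFactors = FALSE)))
  rownames(info) <- NULL
  list(x = x, info = info)
}
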