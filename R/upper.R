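.upperCache <- new.env(parent = emptyenv())

#' Row-major upper-triangle index map
#'
#' Enumerates the strict upper triangle of a p x p matrix in row-major order:
#' (1,2), (1,3), ..., (1,p), (2,3), ... This single map defines the meaning
#' of every vectorized connectivity vector in the package, so that any vector
#' position can be traced back to its (ROI_i, ROI_j) pair and, through a
#' [NetworkPartition-class], to a network pair.
#'
#' @param p matrix dimension (>= 2).
#' @return data.frame with columns idx, i, j (i < j), p(p-1)/2 rows.
#' @export
upperIndexMap <- function(p) {
  p <- as.integer(p)
  stopifnot(p >= 2L)
  key <- as.character(p)
  if (!is.null(.upperCache[[key]])) return(.upperCache[[key]])
  i <- rep.int(seq_len(p - 1L), times = (p - 1L):1L)
  j <- sequence((p - 1L):1L, from = 2:p)
  map <- data.frame(idx = seq_along(i), i = i, j = j)
  .upperCache[[key]] <- map
  map
}

#' Vectorize the upper triangle of a symmetric matrix
#'
#' @param m square matrix.
#' @return numeric vector of length p(p-1)/2, row-major strict upper
#'   triangle (the order of [upperIndexMap()]).
#' @seealso [unvectorizeUpper()] for the exact inverse.
#' @export
vectorizeUpper <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("m must be a square matrix")
  map <- upperIndexMap(nrow(m))
  m[cbind(map$i, map$j)]
}

#' Rebuild a symmetric matrix from its vectorized upper triangle
#'
#' @param v vector produced by [vectorizeUpper()].
#' @param p matrix dimension.
#' @param diag value placed on the diagonal (default 0, the Fisher-Z
#'   convention used throughout).
#' @export
unvectorizeUpper <- function(v, p, diag = 0) {
  map <- upperIndexMap(p)
  if (length(v) != nrow(map)) stop("length(v) must equal p(p-1)/2")
  m <- matrix(diag, p, p)
  m[cbind(map$i, map$j)] <- v
  m[cbind(map$j, map$i)] <- v
  m
}

#' Fisher Z transform of a correlation
#'
#' arctanh(r) after clipping |r| to 1 - 1e-7, so that degenerate windows
#' (identical ROI series, |r| = 1) stay finite.
#'
#' @param r correlations in \[-1, 1\].
#' @export
fisherZ <- function(r) {
  lim <- 1 - 1e-7
  atanh(pmin(pmax(r, -lim), lim))
}
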