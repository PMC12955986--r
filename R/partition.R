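#' Build a network partition from contiguous blocks
#'
#' Assigns `sizes[i]` consecutive ROIs to `labels[i]`, in the order given.
#' This is the layout of hierarchical cortical parcellations in which ROIs of
#' a network occupy a contiguous index range; partitions read from an atlas
#' table ([readPartition()]) need not be contiguous.
#'
#' @param sizes positive integer vector of ROIs per network.
#' @param labels character vector of distinct network labels, same length.
#' @param roiIds optional ROI identifiers (default `ROI_1..ROI_p`).
#' @return A [NetworkPartition-class] object.
#' @examples
#' gapart <- genNetworkPartition(c(3, 2), c("A", "B"))
#' networkOf(gapart)
#' @export
genNetworkPartition <- function(sizes, labels, roiIds = NULL) {
  if (length(sizes) != length(labels))
    stop("sizes and labels must have equal length")
  if (any(sizes < 1) || any(sizes != as.integer(sizes)))
    stop("sizes must be positive integers")
  if (anyDuplicated(labels))
    stop("duplicate network labels")
  p <- sum(sizes)
  if (is.null(roiIds)) roiIds <- sprintf("ROI_%d", seq_len(p))
  nets <- factor(rep(labels, times = sizes), levels = labels)
  new("NetworkPartition", roiIds = as.character(roiIds), networks = nets)
}

#' @describeIn genNetworkPartition number of ROIs.
#' @param x a `NetworkPartition`.
#' @export
nRois <- function(x) length(x@roiIds)

#' @describeIn genNetworkPartition ROI identifiers, in matrix order.
#' @export
roiIds <- function(x) x@roiIds

#' @describeIn genNetworkPartition network label per ROI (factor).
#' @export
networkOf <- function(x) x@networks

#' @describeIn genNetworkPartition network labels in canonical order.
#' @export
networkLabels <- function(x) levels(x@networks)

#' @describeIn genNetworkPartition ROI count per network.
#' @export
networkSizes <- function(x) {
  tab <- table(x@networks)
  setNames(as.integer(tab), names(tab))
}

#' Enumerate all unordered network pairs
#'
#' Lists every unordered pair of networks, within-network pairs included, in
#' canonical order: by the first network's level index, then the second's.
#' `edgeCount` is the number of ROI-pair edges spanned by the pair —
#' n(n-1)/2 within a network of size n, `nA * nB` between distinct networks.
#'
#' @param partition a [NetworkPartition-class].
#' @return data.frame with columns netA, netB, pair, edgeCount.
#' @export
allNetworkPairs <- function(partition) {
  labs <- networkLabels(partition)
  sz <- networkSizes(partition)[labs]
  idx <- which(upper.tri(diag(length(labs)), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  a <- labs[idx[, "row"]]
  b <- labs[idx[, "col"]]
  ec <- ifelse(a == b, sz[a] * (sz[a] - 1L) / 2L, sz[a] * sz[b])
  data.frame(netA = a, netB = b, pair = paste(a, b, sep = "--"),
             edgeCount = as.integer(ec), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Network pair of every upper-triangle edge
#'
#' Maps each vectorized-upper-triangle edge index (row-major order, see
#' [upperIndexMap()]) to its canonical network-pair label.
#'
#' @param partition a [NetworkPartition-class].
#' @return character vector of length p(p-1)/2 of pair labels.
#' @export
edgeNetworkPairs <- function(partition) {
  p <- nRois(partition)
  map <- upperIndexMap(p)
  ni <- as.integer(networkOf(partition))
  labs <- networkLabels(partition)
  a <- pmin(ni[map$i], ni[map$j])
  b <- pmax(ni[map$i], ni[map$j])
  paste(labs[a], labs[b], sep = "--")
}
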