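#' Network partition of a ROI set
#'
#' Maps each ROI of an atlas to exactly one named functional network. The ROI
#' order is fixed and defines the row/column order of every connectivity
#' matrix in the package; the level order of `networks` defines the canonical
#' network (and network-pair) order used for ranking and tie-breaking.
#'
#' @slot roiIds character vector of unique ROI identifiers.
#' @slot networks factor of the same length assigning each ROI to a network;
#'   its levels are the network labels in canonical order.
#' @export
setClass("NetworkPartition",
  slots = c(roiIds = "character", networks = "factor"))

setValidity("NetworkPartition", function(object) {
  msg <- character()
  if (length(object@roiIds) != length(object@networks))
    msg <- c(msg, "roiIds and networks must have equal length")
  if (anyDuplicated(object@roiIds))
    msg <- c(msg, "duplicate ROI identifiers")
  if (anyNA(object@networks))
    msg <- c(msg, "every ROI must map to a network")
  if (!all(levels(object@networks) %in% as.character(object@networks)))
    msg <- c(msg, "unused network labels in levels")
  if (length(msg)) msg else TRUE
})

#' Windowed dynamic functional connectivity for one episode
#'
#' Sliding-window Pearson correlations of one episode's ROI time series,
#' stored as vectorized upper triangles (one row per window) on the Fisher-Z
#' scale when `fisherZ` is set.
#'
#' @slot z numeric matrix, windows x p(p-1)/2 edge values.
#' @slot p integer, number of ROIs.
#' @slot windowStarts integer vector of 0-based window start indices.
#' @slot windowLength,step integer window parameters (time points).
#' @slot fisherZ logical, whether values are arctanh-transformed.
#' @slot subjectId,episodeId,condition episode identity.
#' @export
setClass("DynFCSeries",
  slots = c(z = "matrix", p = "integer", windowStarts = "integer",
            windowLength = "integer", step = "integer", fisherZ = "logical",
            subjectId = "character", episodeId = "character",
            condition = "character"))

setValidity("DynFCSeries", function(object) {
  d <- object@p * (object@p - 1L) / 2L
  msg <- character()
  if (ncol(object@z) != d)
    msg <- c(msg, sprintf("z must have p(p-1)/2 = %d columns", d))
  if (nrow(object@z) != length(object@windowStarts))
    msg <- c(msg, "one windowStart per window row")
  if (length(msg)) msg else TRUE
})

#' Fitted brain-state model
#'
#' Result of two-step L1 k-means over pooled window vectors: K centroids
#' (coordinate-wise medians on the vectorized-upper-triangle scale), one state
#' assignment per window, and the total L1 inertia after each step.
#'
#' @slot K integer number of states.
#' @slot centroids K x d numeric matrix.
#' @slot assignments integer vector, state in 1..K per window.
#' @slot info data.frame aligned with `assignments` (subject, episode,
#'   condition, window) or a zero-row data.frame when unknown.
#' @slot inertia total L1 distance of windows to assigned centroids (step 2).
#' @slot step1Inertia best inertia over the random restarts of step 1.
#' @export
setClass("StateModel",
  slots = c(K = "integer", centroids = "matrix", assignments = "integer",
            info = "data.frame", inertia = "numeric",
            step1Inertia = "numeric"))

setValidity("StateModel", function(object) {
  msg <- character()
  if (nrow(object@centroids) != object@K)
    msg <- c(msg, "one centroid row per state")
  if (any(object@assignments < 1L | object@assignments > object@K))
    msg <- c(msg, "assignments must lie in 1..K")
  if (nrow(object@info) > 0 && nrow(object@info) != length(object@assignments))
    msg <- c(msg, "info rows must align with assignments")
  if (length(msg)) msg else TRUE
})

#' Per-episode state-averaged connectivity
#'
#' One row of `fc` per (subject, episode, condition, state) combination for
#' which the episode has at least one window assigned to the state; absent
#' states are represented by the absence of a row, never by zeros.
#'
#' @slot fc numeric matrix, records x p(p-1)/2, vectorized upper triangles.
#' @slot info data.frame with columns subject, episode, condition, state,
#'   nWindows, aligned with the rows of `fc`.
#' @slot p integer number of ROIs.
#' @export
setClass("StateFCSet",
  slots = c(fc = "matrix", info = "data.frame", p = "integer"))

setValidity("StateFCSet", function(object) {
  msg <- character()
  if (nrow(object@fc) != nrow(object@info))
    msg <- c(msg, "fc rows and info rows must align")
  need <- c("subject", "episode", "condition", "state")
  if (!all(need %in% names(object@info)))
    msg <- c(msg, "info must have subject/episode/condition/state columns")
  if (length(msg)) msg else TRUE
})

#' DEFN network-pair weights
#'
#' For every unordered network pair (within-network pairs included), the
#' fraction of the pair's ROI-pair edges that are stable discriminative
#' features of the emotion decoder.
#'
#' @slot table data.frame with columns netA, netB, pair, stableCount,
#'   edgeCount, weight; one row per network pair in canonical order.
#' @slot labels character vector of network labels in canonical order.
#' @export
setClass("DefnWeights",
  slots = c(table = "data.frame", labels = "character"))

setValidity("DefnWeights", function(object) {
  tb <- object@table
  msg <- character()
  need <- c("netA", "netB", "pair", "stableCount", "edgeCount", "weight")
  if (!all(need %in% names(tb)))
    msg <- c(msg, "table missing required columns")
  else {
    if (any(tb$weight < 0 | tb$weight > 1)) msg <- c(msg, "weights must lie in [0,1]")
    if (any(tb$stableCount > tb$edgeCount)) msg <- c(msg, "stableCount exceeds edgeCount")
  }
  nl <- length(object@labels)
  if (nrow(tb) != nl * (nl + 1) / 2)
    msg <- c(msg, "one row per unordered network pair required")
  if (length(msg)) msg else TRUE
})

#' Cross-validated classification report
#'
#' Pooled outer-fold predictions and decision scores of a cross-validated
#' linear SVM, with per-fold accuracies, ROC/AUC, the mask size selected per
#' outer fold (nested models only) and per-fold feature-weight detail used
#' for network-importance maps.
#'
#' @slot foldAccuracy numeric per-fold accuracy.
#' @slot predictions data.frame: row, truth, pred, score, fold.
#' @slot accuracy pooled accuracy over all outer-fold test predictions.
#' @slot auc area under the pooled-score ROC curve.
#' @slot roc data.frame of (fpr, tpr) points.
#' @slot selectedNTop integer mask size chosen per outer fold (empty for the
#'   baseline model).
#' @slot finalNTop modal selected mask size (NA for the baseline model).
#' @slot foldDetails list of per-fold detail (mask indices, absolute SVM
#'   weights) consumed by [networkImportance()].
#' @slot leakageTouches integer count of inner-loop accesses to outer-test
#'   rows (instrumented; always 0 for a correct run).
#' @export
setClass("ClassificationReport",
  slots = c(foldAccuracy = "numeric", predictions = "data.frame",
            accuracy = "numeric", auc = "numeric", roc = "data.frame",
            selectedNTop = "integer", finalNTop = "integer",
            foldDetails = "list", leakageTouches = "integer"))

setValidity("ClassificationReport", function(object) {
  msg <- character()
  ok <- is.finite(object@accuracy) && object@accuracy >= 0 && object@accuracy <= 1
  if (!ok) msg <- c(msg, "accuracy must lie in [0,1]")
  if (length(object@auc) && is.finite(object@auc) &&
      (object@auc < 0 || object@auc > 1))
    msg <- c(msg, "auc must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "NetworkPartition", function(object) {
  cat("NetworkPartition:", length(object@roiIds), "ROIs in",
      nlevels(object@networks), "networks\n")
  cat("  networks:", paste(levels(object@networks), collapse = ", "), "\n")
})

setMethod("show", "DynFCSeries", function(object) {
  cat(sprintf("DynFCSeries: %d windows x %d edges (p = %d, window %d, step %d%s)\n",
              nrow(object@z), ncol(object@z), object@p, object@windowLength,
              object@step, if (object@fisherZ) ", Fisher Z" else ""))
  cat(sprintf("  subject %s, episode %s, condition %s\n", object@subjectId,
              object@episodeId, object@condition))
})

setMethod("show", "StateModel", function(object) {
  cat(sprintf("StateModel: K = %d over %d windows, L1 inertia %.4g\n",
              object@K, length(object@assignments), object@inertia))
  fr <- stateFrequencies(object)
  cat("  occupancy:", paste(sprintf("%.1f%%", 100 * fr), collapse = " "), "\n")
})

setMethod("show", "StateFCSet", function(object) {
  cat(sprintf("StateFCSet: %d (episode, state) records, p = %d\n",
              nrow(object@info), object@p))
})

setMethod("show", "DefnWeights", function(object) {
  tb <- object@table
  nz <- sum(tb$weight > 0)
  cat(sprintf("DefnWeights: %d network pairs (%d with nonzero weight)\n",
              nrow(tb), nz))
  top <- head(tb[order(-tb$weight), c("pair", "weight")], 5L)
  if (nz > 0) {
    cat("  top pairs:\n")
    for (r in seq_len(nrow(top)))
      if (top$weight[r] > 0)
        cat(sprintf("    %s  %.3f\n", top$pair[r], top$weight[r]))
  }
})

setMethod("show", "ClassificationReport", function(object) {
  cat(sprintf("ClassificationReport: pooled accuracy %.2f%%, AUC %.3f over %d folds\n",
              100 * object@accuracy, object@auc, length(object@foldAccuracy)))
  if (length(object@selectedNTop))
    cat(sprintf("  final mask size (modal n_top): %d\n", object@finalNTop))
})
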