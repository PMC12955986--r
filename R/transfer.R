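#' Static functional connectivity of one scan
#'
#' Pearson correlation between every ROI pair over the whole series, Fisher
#' Z transformed, symmetric with zero diagonal on the Z scale. Zero-variance
#' ROIs yield NaN edges with a warning.
#'
#' @param ts numeric matrix, time points x ROIs (T >= 3).
#' @return p x p symmetric matrix.
#' @export
staticFC <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3L) stop("need at least 3 time points")
  if (anyNA(ts)) stop("time series contains missing values")
  if (any(apply(ts, 2L, stats::sd) == 0))
    warning("zero-variance ROI; NaN edges emitted")
  r <- suppressWarnings(stats::cor(ts))
  z <- fisherZ(r)
  z[is.na(z)] <- NaN
  diag(z) <- 0
  z
}

#' Rank network pairs by DEFN weight
#'
#' Descending by weight; ties (and the all-zero tail) break by the fixed
#' canonical pair order, so the ranking is deterministic and zero-weight
#' pairs remain reachable at the end of the candidate grid.
#'
#' @param weights a [DefnWeights-class].
#' @return the weight table reordered, with a `rank` column.
#' @export
rankNetworkPairs <- function(weights) {
  tb <- weightTable(weights)
  ord <- order(-tb$weight, seq_len(nrow(tb)))
  out <- tb[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Resolve a top-n DEFN mask to edge indices
#'
#' The mask of rank n is the union of the edge sets of the n top-ranked
#' network pairs; feature counts are therefore non-decreasing in n.
#'
#' @param ranked output of [rankNetworkPairs()].
#' @param nTop how many top pairs to include.
#' @param partition a [NetworkPartition-class].
#' @return list of class `maskSpec`: `pairs`, `nTop`, `featureIdx` (sorted
#'   edge indices into the vectorized upper triangle).
#' @export
buildMask <- function(ranked, nTop, partition) {
  nTop <- as.integer(nTop)
  if (nTop < 1L || nTop > nrow(ranked)) stop("nTop out of range")
  sel <- ranked$pair[seq_len(nTop)]
  epairs <- edgeNetworkPairs(partition)
  structure(list(pairs = sel, nTop = nTop,
                 featureIdx = which(epairs %in% sel)),
            class = "maskSpec")
}

#' Fit / apply a linear age + sex confound model
#'
#' Per-feature ordinary least squares on the training rows only; the fitted
#' coefficients are applied unchanged to any later rows (validation or
#' test), so no information flows back from held-out data. A constant
#' covariate is dropped with a warning.
#'
#' @param x training features (rows x features).
#' @param age numeric covariate.
#' @param sex covariate coded 0/1.
#' @return list of class `confoundModel` with the coefficient matrix.
#' @export
fitConfoundModel <- function(x, age, sex) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 3L, length(age) == nrow(x), length(sex) == nrow(x))
  if (anyNA(age) || anyNA(sex)) stop("covariates contain missing values")
  design <- cbind(intercept = 1, age = age, sex = sex)
  keep <- c(TRUE, apply(design[, -1L, drop = FALSE], 2L, stats::var) > 0)
  if (!all(keep))
    warning("constant covariate dropped: ",
            paste(colnames(design)[!keep], collapse = ", "))
  design <- design[, keep, drop = FALSE]
  fit <- stats::lm.fit(design, x)
  structure(list(coef = as.matrix(fit$coefficients), columns = colnames(design)),
            class = "confoundModel")
}

#' @rdname fitConfoundModel
#' @param model a fitted `confoundModel`.
#' @export
applyConfoundModel <- function(model, x, age, sex) {
  x <- as.matrix(x)
  design <- cbind(intercept = 1, age = age, sex = sex)
  design <- design[, model$columns, drop = FALSE]
  x - design %*% model$coef
}

# Stratified fold assignment: per class, a random permutation receives fold
# ids cyclically, so class balance is preserved up to one sample.
stratifiedFolds <- function(y, k) {
  y <- factor(y)
  folds <- integer(length(y))
  for (lev in levels(y)) {
    idx <- which(y == lev)
    folds[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  if (any(vapply(split(y, folds), nlevels, integer(1)) < nlevels(y)))
    stop("a fold lost a class; reduce the fold count")
  folds
}

# Linear SVM helpers: fit on (x, y), return predictions and a decision score
# oriented so that larger scores favour the second factor level.
svmFitPredict <- function(xtr, ytr, xte, cost) {
  fit <- e1071::svm(xtr, ytr, kernel = "linear", cost = cost, scale = FALSE)
  pred <- predict(fit, xte, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  # column name "A/B" means positive values favour A
  fav <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1L]][1L]
  score <- if (fav == levels(ytr)[2L]) dv[, 1L] else -dv[, 1L]
  w <- crossprod(fit$coefs, fit$SV)[1L, ]
  list(pred = as.character(pred), score = as.numeric(score), absW = abs(w))
}

standardizeBy <- function(xtr, xte) {
  mu <- colMeans(xtr)
  sg <- apply(xtr, 2L, stats::sd); sg[sg == 0] <- 1
  list(tr = sweep(sweep(xtr, 2L, mu), 2L, sg, "/"),
       te = sweep(sweep(xte, 2L, mu), 2L, sg, "/"))
}

#' Nested cross-validated DEFN-masked classification
#'
#' Stratified nested 10 x 10-fold cross-validation of a linear SVM over
#' DEFN-ranked masks. Within each outer fold, every candidate mask size
#' `nTop` in `grid` is scored by inner cross-validation on the outer
#' training set only; the best (smallest on ties) wins, a model with that
#' mask is trained on the full outer training set and evaluated on the
#' outer test fold. When `confounds` is supplied, an age/sex regression is
#' fitted inside each training partition and applied to its
#' validation/test partition before masking. The final reported mask is the
#' modal selected `nTop` (smallest on ties); accuracy and ROC/AUC are
#' computed from the pooled outer-fold predictions and decision scores.
#'
#' The run is instrumented against leakage: every row index consumed by an
#' inner-loop computation is recorded and checked against the outer test
#' fold; the count of violations is reported (always 0).
#'
#' @param x subjects x features matrix (vectorized static FC).
#' @param y two-level factor; the second level is the positive class.
#' @param weights a [DefnWeights-class] from the emotion decoder.
#' @param partition the matching [NetworkPartition-class].
#' @param outerFolds,innerFolds fold counts (default 10/10).
#' @param confounds optional data.frame with columns age and sex.
#' @param cost linear SVM cost (default 1).
#' @param grid candidate mask sizes; default 1..(number of nonzero-weight
#'   pairs).
#' @param seed integer seed; [baselineClassify()] with the same seed uses
#'   identical outer folds, giving paired predictions for McNemar.
#' @return A [ClassificationReport-class].
#' @export
nestedCVClassify <- function(x, y, weights, partition, outerFolds = 10L,
                             innerFolds = 10L, confounds = NULL, cost = 1,
                             grid = NULL, seed = NULL) {
  x <- as.matrix(x)
  y <- factor(y)
  stopifnot(nlevels(y) == 2L, nrow(x) >= 20L)
  if (!is.null(confounds))
    stopifnot(all(c("age", "sex") %in% names(confounds)),
              nrow(confounds) == nrow(x))
  ranked <- rankNetworkPairs(weights)
  if (is.null(grid)) grid <- seq_len(sum(ranked$weight > 0))
  if (!length(grid)) stop("empty candidate grid: no nonzero-weight pairs")
  masks <- lapply(grid, function(n) buildMask(ranked, n, partition)$featureIdx)

  if (!is.null(seed)) set.seed(seed)
  outer <- stratifiedFolds(y, outerFolds)

  n <- nrow(x)
  preds <- character(n); scores <- numeric(n)
  foldAcc <- numeric(outerFolds); chosen <- integer(outerFolds)
  foldDetails <- vector("list", outerFolds)
  leakage <- 0L

  for (f in seq_len(outerFolds)) {
    teIdx <- which(outer == f)
    trIdx <- which(outer != f)
    innerAssign <- stratifiedFolds(y[trIdx], innerFolds)

    innerAcc <- matrix(NA_real_, length(grid), innerFolds)
    for (g in seq_len(innerFolds)) {
      itr <- trIdx[innerAssign != g]
      ival <- trIdx[innerAssign == g]
      leakage <- leakage + length(intersect(c(itr, ival), teIdx))
      xtr <- x[itr, , drop = FALSE]; xv <- x[ival, , drop = FALSE]
      if (!is.null(confounds)) {
        cm <- fitConfoundModel(xtr, confounds$age[itr], confounds$sex[itr])
        xtr <- applyConfoundModel(cm, xtr, confounds$age[itr], confounds$sex[itr])
        xv <- applyConfoundModel(cm, xv, confounds$age[ival], confounds$sex[ival])
      }
      for (m in seq_along(grid)) {
        st <- standardizeBy(xtr[, masks[[m]], drop = FALSE],
                            xv[, masks[[m]], drop = FALSE])
        fitp <- svmFitPredict(st$tr, y[itr], st$te, cost)
        innerAcc[m, g] <- mean(fitp$pred == as.character(y[ival]))
      }
    }
    best <- which.max(rowMeans(innerAcc))
    chosen[f] <- grid[best]

    xtr <- x[trIdx, , drop = FALSE]; xte <- x[teIdx, , drop = FALSE]
    if (!is.null(confounds)) {
      cm <- fitConfoundModel(xtr, confounds$age[trIdx], confounds$sex[trIdx])
      xtr <- applyConfoundModel(cm, xtr, confounds$age[trIdx], confounds$sex[trIdx])
      xte <- applyConfoundModel(cm, xte, confounds$age[teIdx], confounds$sex[teIdx])
    }
    mi <- masks[[best]]
    st <- standardizeBy(xtr[, mi, drop = FALSE], xte[, mi, drop = FALSE])
    fitp <- svmFitPredict(st$tr, y[trIdx], st$te, cost)
    preds[teIdx] <- fitp$pred
    scores[teIdx] <- fitp$score
    foldAcc[f] <- mean(fitp$pred == as.character(y[teIdx]))
    foldDetails[[f]] <- list(nTop = grid[best], featureIdx = mi,
                             absW = fitp$absW)
  }

  tt <- table(chosen)
  finalN <- min(as.integer(names(tt)[tt == max(tt)]))
  ra <- rocAuc(scores, y)
  new("ClassificationReport",
      foldAccuracy = foldAcc,
      predictions = data.frame(row = seq_len(n), truth = as.character(y),
                               pred = preds, score = scores, fold = outer,
                               stringsAsFactors = FALSE),
      accuracy = mean(preds == as.character(y)), auc = ra$auc, roc = ra$roc,
      selectedNTop = chosen, finalNTop = finalN, foldDetails = foldDetails,
      leakageTouches = leakage)
}

#' Whole-brain baseline classifier
#'
#' Stratified k-fold cross-validation of the same linear SVM on all
#' features, with the same optional in-fold confound regression and — when
#' called with the seed used for [nestedCVClassify()] — the identical fold
#' assignment, so the two prediction vectors are paired for
#' [mcnemarCompare()].
#'
#' @inheritParams nestedCVClassify
#' @param folds fold count (default 10).
#' @return A [ClassificationReport-class] (`selectedNTop` empty).
#' @export
baselineClassify <- function(x, y, folds = 10L, confounds = NULL, cost = 1,
                             seed = NULL) {
  x <- as.matrix(x)
  y <- factor(y)
  stopifnot(nlevels(y) == 2L)
  if (!is.null(seed)) set.seed(seed)
  outer <- stratifiedFolds(y, folds)
  n <- nrow(x)
  preds <- character(n); scores <- numeric(n); foldAcc <- numeric(folds)
  for (f in seq_len(folds)) {
    teIdx <- which(outer == f); trIdx <- which(outer != f)
    xtr <- x[trIdx, , drop = FALSE]; xte <- x[teIdx, , drop = FALSE]
    if (!is.null(confounds)) {
      cm <- fitConfoundModel(xtr, confounds$age[trIdx], confounds$sex[trIdx])
      xtr <- applyConfoundModel(cm, xtr, confounds$age[trIdx], confounds$sex[trIdx])
      xte <- applyConfoundModel(cm, xte, confounds$age[teIdx], confounds$sex[teIdx])
    }
    st <- standardizeBy(xtr, xte)
    fitp <- svmFitPredict(st$tr, y[trIdx], st$te, cost)
    preds[teIdx] <- fitp$pred
    scores[teIdx] <- fitp$score
    foldAcc[f] <- mean(fitp$pred == as.character(y[teIdx]))
  }
  ra <- rocAuc(scores, y)
  new("ClassificationReport",
      foldAccuracy = foldAcc,
      predictions = data.frame(row = seq_len(n), truth = as.character(y),
                               pred = preds, score = scores, fold = outer,
                               stringsAsFactors = FALSE),
      accuracy = mean(preds == as.character(y)), auc = ra$auc, roc = ra$roc,
      selectedNTop = integer(0), finalNTop = NA_integer_,
      foldDetails = list(), leakageTouches = 0L)
}

#' McNemar comparison of two paired classifiers
#'
#' Builds the 2 x 2 discordant table of the aligned prediction vectors
#' (b = A correct & B wrong, c = A wrong & B correct) and tests
#' (b - c)^2 / (b + c) against chi-square(1). Continuity correction is
#' available by flag; b + c = 0 reports p = 1.
#'
#' @param predA,predB aligned prediction vectors.
#' @param truth true labels, same length.
#' @param correct apply the continuity correction (default FALSE).
#' @return list: statistic, p, b, c, method.
#' @export
mcnemarCompare <- function(predA, predB, truth, correct = FALSE) {
  stopifnot(length(predA) == length(truth), length(predB) == length(truth))
  okA <- as.character(predA) == as.character(truth)
  okB <- as.character(predB) == as.character(truth)
  b <- sum(okA & !okB)
  cc <- sum(!okA & okB)
  if (b + cc == 0)
    return(list(statistic = 0, p = 1, b = b, c = cc, method = "mcnemar"))
  num <- (abs(b - cc) - if (correct) 1 else 0)^2
  stat <- max(num, 0) / (b + cc)
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       b = b, c = cc,
       method = if (correct) "mcnemar (continuity-corrected)" else "mcnemar")
}

#' Network-pair importance of a nested-CV model
#'
#' For each network pair, the mean absolute SVM coefficient over the pair's
#' masked edges, averaged across the outer folds in which the pair was
#' masked, then max-normalised to \[0, 1\]. Pairs never entering a mask are
#' NA.
#'
#' @param report a [ClassificationReport-class] from [nestedCVClassify()].
#' @param partition the matching [NetworkPartition-class].
#' @return data.frame: netA, netB, pair, importance (NA when never masked).
#' @export
networkImportance <- function(report, partition) {
  if (!length(report@foldDetails)) stop("report carries no fold detail")
  pairs <- allNetworkPairs(partition)
  epairs <- edgeNetworkPairs(partition)
  acc <- matrix(NA_real_, nrow(pairs), length(report@foldDetails))
  for (f in seq_along(report@foldDetails)) {
    det <- report@foldDetails[[f]]
    pm <- epairs[det$featureIdx]
    means <- tapply(det$absW, pm, mean)
    acc[match(names(means), pairs$pair), f] <- means
  }
  imp <- rowMeans(acc, na.rm = TRUE)
  imp[is.nan(imp)] <- NA_real_
  mx <- max(imp, na.rm = TRUE)
  if (is.finite(mx) && mx > 0) imp <- imp / mx
  data.frame(netA = pairs$netA, netB = pairs$netB, pair = pairs$pair,
             importance = imp, stringsAsFactors = FALSE)
}

#' ROC curve and AUC from pooled decision scores
#'
#' AUC is the probability that a random positive-class score exceeds a
#' random negative-class score, ties counted one half (computed via pROC
#' with a fixed direction, so it is never silently flipped above 0.5).
#'
#' @param scores numeric decision scores (larger favours the positive class).
#' @param labels two-level factor; second level is positive.
#' @return list: `roc` data.frame of (fpr, tpr), `auc`.
#' @export
rocAuc <- function(scores, labels) {
  labels <- factor(labels)
  stopifnot(nlevels(labels) == 2L)
  if (length(unique(labels)) < 2L) stop("both classes required")
  r <- pROC::roc(response = labels, predictor = as.numeric(scores),
                 levels = levels(labels), direction = "<", quiet = TRUE)
  ord <- order(1 - r$specificities, r$sensitivities)
  list(roc = data.frame(fpr = (1 - r$specificities)[ord],
                        tpr = r$sensitivities[ord]),
       auc = as.numeric(r$auc))
}
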