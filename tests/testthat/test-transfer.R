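test_that("static FC is symmetric Fisher-Z with near-zero edges for independent noise", {
  set.seed(40)
  ts <- matrix(rnorm(600 * 12), 600, 12)
  z <- staticFC(ts)
  expect_equal(z, t(z))
  expect_equal(unname(diag(z)), rep(0, 12))
  expect_gte(mean(abs(vectorizeUpper(z)) < 0.2), 0.99)
  expect_warning(staticFC(cbind(rnorm(10), rep(1, 10))), "zero-variance")
  dup <- cbind(rnorm(20)); dup <- cbind(dup, dup)
  expect_equal(staticFC(dup)[1, 2], atanh(1 - 1e-7))
})

test_that("pair ranking is weight-descending with canonical tie-breaks", {
  part <- tinyPartition()
  w <- syntheticWeights(part, "A--B")
  rk <- rankNetworkPairs(w)
  expect_equal(rk$pair[1], "A--B")
  expect_equal(rk$pair[-1], c("A--A", "B--B"))  # zero tail in canonical order

  wz <- defnWeights(integer(0), 1L, part)
  expect_equal(rankNetworkPairs(wz)$pair, c("A--A", "A--B", "B--B"))
})

test_that("masks grow monotonically and resolve the right edges", {
  part <- tinyPartition()
  rk <- rankNetworkPairs(defnWeights(integer(0), 1L, part))  # canonical order
  m1 <- buildMask(rk, 1L, part)   # A--A: 3 edges
  m2 <- buildMask(rk, 2L, part)   # + A--B: 6 edges
  expect_length(m1$featureIdx, 3L)
  expect_length(m2$featureIdx, 9L)
  expect_true(all(m1$featureIdx %in% m2$featureIdx))
  expect_length(buildMask(rk, 3L, part)$featureIdx, 10L)
  counts <- vapply(1:3, function(n) length(buildMask(rk, n, part)$featureIdx),
                   integer(1))
  expect_true(all(diff(counts) >= 0))
  expect_error(buildMask(rk, 4L, part), "out of range")
})

test_that("confound regression learns on training rows only", {
  set.seed(41)
  age <- rnorm(30, 40, 10); sex <- rbinom(30, 1, 0.5)
  x <- cbind(2 * age, rnorm(30))
  cm <- fitConfoundModel(x, age, sex)
  resid <- applyConfoundModel(cm, x, age, sex)
  expect_lt(max(abs(resid[, 1])), 1e-8)
  expect_gt(cor(resid[, 2], x[, 2] - mean(x[, 2])), 0.9)
  expect_warning(fitConfoundModel(x, age, rep(1, 30)), "constant covariate")

  # coefficients from training rows applied unchanged to new rows
  newx <- cbind(2 * age[1:5] + 1, rnorm(5))
  r2 <- applyConfoundModel(cm, newx, age[1:5], sex[1:5])
  expect_equal(max(abs(r2[, 1] - 1)), 0, tolerance = 1e-6)
})

test_that("group effects orthogonal to covariates survive in-fold residualization", {
  part <- sixNetPartition(3L, 4L)   # 12 ROIs, 66 edges
  dAUC <- vapply(1:10, function(i) {
    coh <- genClinicalCohort(25, 25, part, effectPairs = "Net1--Net2",
                             effectSize = 1.2, seed = 500 + i)
    conf <- data.frame(age = coh$phenotype$age, sex = coh$phenotype$sex)
    a1 <- baselineClassify(coh$features, coh$group, folds = 5L, seed = i)@auc
    a2 <- baselineClassify(coh$features, coh$group, folds = 5L,
                           confounds = conf, seed = i)@auc
    a2 - a1
  }, numeric(1))
  expect_lte(mean(abs(dAUC)), 0.05)
})

test_that("nested CV finds the planted mask without leaking test rows", {
  part <- sixNetPartition(4L, 5L)   # 20 ROIs, 190 edges
  w <- syntheticWeights(part, c("Net1--Net2", "Net3--Net4", "Net5--Net5"))
  accs <- modal <- numeric(5)
  for (i in 1:5) {
    coh <- genClinicalCohort(30, 30, part, effectPairs = "Net1--Net2",
                             effectSize = 1.5, seed = 600 + i)
    rep_ <- nestedCVClassify(coh$features, coh$group, w, part,
                             outerFolds = 5L, innerFolds = 5L, seed = i)
    accs[i] <- rep_@accuracy
    modal[i] <- rep_@finalNTop
    expect_identical(rep_@leakageTouches, 0L)
    expect_equal(rep_@accuracy,
                 mean(rep_@predictions$pred == rep_@predictions$truth))
  }
  expect_gte(mean(accs), 0.9)
  expect_true(all(modal == 1))
})

test_that("baseline shares folds with the nested model under a common seed", {
  part <- sixNetPartition(3L, 4L)
  coh <- genClinicalCohort(20, 20, part, effectPairs = "Net1--Net2",
                           effectSize = 1, seed = 7)
  w <- syntheticWeights(part, "Net1--Net2")
  a <- nestedCVClassify(coh$features, coh$group, w, part, outerFolds = 5L,
                        innerFolds = 5L, seed = 42L)
  b <- baselineClassify(coh$features, coh$group, folds = 5L, seed = 42L)
  expect_identical(a@predictions$fold, b@predictions$fold)
})

test_that("null cohorts give no masked-over-baseline optimism", {
  part <- sixNetPartition(3L, 4L)
  w <- syntheticWeights(part, c("Net1--Net2", "Net2--Net3"))
  diffs <- vapply(1:20, function(i) {
    coh <- genClinicalCohort(30, 30, part, seed = 700 + i)
    a <- nestedCVClassify(coh$features, coh$group, w, part, outerFolds = 5L,
                          innerFolds = 5L, seed = i)@accuracy
    b <- baselineClassify(coh$features, coh$group, folds = 5L, seed = i)@accuracy
    a - b
  }, numeric(1))
  expect_lte(abs(mean(diffs)), 0.05)
})

test_that("McNemar statistic matches the discordant-pair formula", {
  truth <- rep("a", 20)
  predA <- truth; predB <- truth
  predB[1:10] <- "b"           # b = 10
  predA[11:12] <- "b"          # c = 2
  r <- mcnemarCompare(predA, predB, truth)
  expect_equal(r$statistic, (10 - 2)^2 / 12)
  expect_equal(r$statistic, 5.3333, tolerance = 1e-4)
  expect_equal(r$p, pchisq(16 / 3, 1, lower.tail = FALSE))

  # symmetric in model order, p = 1 when concordant
  r2 <- mcnemarCompare(predB, predA, truth)
  expect_equal(r2$statistic, r$statistic)
  same <- mcnemarCompare(predA, predA, truth)
  expect_equal(same$p, 1)
  rc <- mcnemarCompare(predA, predB, truth, correct = TRUE)
  expect_equal(rc$statistic, (8 - 1)^2 / 12)
})

test_that("network importance normalises masked-pair SVM weights", {
  part <- tinyPartition()
  ep <- edgeNetworkPairs(part)
  fi <- which(ep %in% c("A--A", "A--B"))
  det <- list(list(nTop = 2L, featureIdx = fi,
                   absW = ifelse(ep[fi] == "A--A", 2, 4)))
  rep_ <- new("ClassificationReport", foldAccuracy = 1, predictions = data.frame(),
              accuracy = 1, auc = 1, roc = data.frame(), selectedNTop = 2L,
              finalNTop = 2L, foldDetails = det, leakageTouches = 0L)
  imp <- networkImportance(rep_, part)
  expect_equal(imp$importance[imp$pair == "A--B"], 1)
  expect_equal(imp$importance[imp$pair == "A--A"], 0.5)
  expect_true(is.na(imp$importance[imp$pair == "B--B"]))
})

test_that("AUC counts concordant pairs with ties at one half", {
  lab <- factor(c("neg", "neg", "pos", "pos"), levels = c("neg", "pos"))
  expect_equal(rocAuc(c(0.1, 0.5, 0.4, 0.9), lab)$auc, 0.75)
  expect_equal(rocAuc(c(0, 0, 1, 1), lab)$auc, 1)
  expect_equal(rocAuc(rep(0.3, 4), lab)$auc, 0.5)
  r <- rocAuc(c(0.1, 0.5, 0.4, 0.9), lab)
  expect_true(all(diff(r$roc$fpr) >= 0))
  expect_true(all(r$roc$tpr >= 0 & r$roc$tpr <= 1))
})
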