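test_that("simConfig validates its invariants", {
  expect_error(simConfig(nRois = 10L, networkSizes = c(4L, 4L)), "sum to nRois")
  expect_error(simConfig(nSubjects = 0L), "positive")
  expect_error(simConfig(conditions = "happy"), "two conditions")
  cfg <- simConfig()
  expect_equal(cfg$nTimepoints, 600L)
  expect_equal(cfg$K, 4L)
})

test_that("a fixed seed reproduces the healthy cohort exactly", {
  cfg <- simConfig(nSubjects = 2L, episodesPerCondition = 1L,
                   nTimepoints = 80L, nRois = 12L,
                   networkSizes = rep(3L, 4L), K = 2L, seed = 99L)
  a <- genHealthyCohort(cfg)
  b <- genHealthyCohort(cfg)
  expect_identical(a$episodes, b$episodes)
  expect_identical(a$truth$statePaths, b$truth$statePaths)
})

test_that("healthy-cohort truth satisfies its structural invariants", {
  cfg <- simConfig(nSubjects = 2L, episodesPerCondition = 1L,
                   nTimepoints = 100L, nRois = 12L,
                   networkSizes = rep(3L, 4L), K = 3L, seed = 5L)
  coh <- genHealthyCohort(cfg)
  for (P in coh$truth$transitionMatrices)
    expect_equal(unname(rowSums(P)), rep(1, 3), tolerance = 1e-9)
  for (path in coh$truth$statePaths)
    expect_true(all(path >= 1 & path <= 3))
  for (k in 1:3) for (c2 in 1:2) {
    m <- coh$truth$trueCentroidFC[[k]][[c2]]
    expect_equal(m, t(m))
    expect_equal(unname(diag(m)), rep(1, 12))
  }
  map <- upperIndexMap(12L)
  ee <- coh$truth$conditionEffectEdges
  expect_true(all(map$i[ee] < map$j[ee]))
})

test_that("state-path occupancy converges to the stationary distribution", {
  cfg <- simConfig(nSubjects = 1L, episodesPerCondition = 1L,
                   nTimepoints = 50L, nRois = 12L, networkSizes = rep(3L, 4L),
                   K = 4L, seed = 3L)
  coh <- genHealthyCohort(cfg)
  P <- coh$truth$transitionMatrices[[1]]
  pi0 <- coh$truth$stationary[[1]]
  set.seed(17)
  path <- defnet:::markovPath(1e5, P, pi0)
  # thin far beyond the chain's mixing time so counts are effectively iid
  obs <- tabulate(path[seq(1L, 1e5L, by = 250L)], 4L)
  expect_gt(chisq.test(obs, p = pi0)$p.value, 0.01)
})

test_that("one-state generation reproduces the generating correlation", {
  cfg <- simConfig(nSubjects = 1L, episodesPerCondition = 1L,
                   nTimepoints = 600L, nRois = 12L,
                   networkSizes = rep(3L, 4L), K = 1L, conditionEffect = 0,
                   seed = 21L)
  coh <- genHealthyCohort(cfg)
  ts <- coh$episodes[[1]]$ts
  s <- slidingWindowFC(ts, fisherZ = FALSE)
  meanFC <- unvectorizeUpper(colMeans(s@z), 12L, diag = 1)
  expect_lt(max(abs(meanFC - coh$truth$trueCentroidFC[[1]][[1]])), 0.1)
})

test_that("windows inside latent segments are L1-closer to their own state template", {
  cfg <- simConfig(nSubjects = 2L, episodesPerCondition = 2L,
                   nTimepoints = 300L, nRois = 16L,
                   networkSizes = rep(4L, 4L), K = 2L, conditionEffect = 0,
                   withinR = 0.1, activeR = 0.8, betweenR = 0, seed = 31L)
  coh <- genHealthyCohort(cfg)
  cent <- lapply(1:2, function(k)
    fisherZ(vectorizeUpper(coh$truth$trueCentroidFC[[k]][[1]])))
  good <- total <- 0L
  for (e in coh$episodes) {
    s <- slidingWindowFC(e$ts)
    path <- coh$truth$statePaths[[paste(e$subject, e$episode, sep = "|")]]
    for (w in seq_len(nWindows(s))) {
      seg <- path[(s@windowStarts[w] + 1):(s@windowStarts[w] + 30)]
      if (length(unique(seg)) > 1L) next     # only windows wholly inside a segment
      k <- seg[1]
      dOwn <- sum(abs(s@z[w, ] - cent[[k]]))
      dOther <- sum(abs(s@z[w, ] - cent[[3 - k]]))
      good <- good + (dOwn < dOther)
      total <- total + 1L
    }
  }
  expect_gt(total, 50L)
  expect_gte(good / total, 0.95)
})

test_that("clustering generated windows recovers the planted states", {
  skip_if_not_installed("mclust")
  cfg <- simConfig(nSubjects = 4L, episodesPerCondition = 2L,
                   nTimepoints = 200L, nRois = 16L,
                   networkSizes = rep(4L, 4L), K = 2L, conditionEffect = 0,
                   withinR = 0.1, activeR = 0.8, betweenR = 0, seed = 41L)
  coh <- genHealthyCohort(cfg)
  series <- lapply(coh$episodes, function(e)
    slidingWindowFC(e$ts, subjectId = e$subject, episodeId = e$episode,
                    condition = e$condition))
  pw <- poolWindows(series)
  model <- clusterStatesTwoStep(pw$x, 2L, nInit = 5L, maxIter = 100L, seed = 1L,
                                info = pw$info)
  truthStates <- unlist(lapply(coh$episodes, function(e)
    windowMajorityStates(coh$truth$statePaths[[paste(e$subject, e$episode,
                                                     sep = "|")]])))
  expect_gte(mclust::adjustedRandIndex(model@assignments, truthStates), 0.8)
})

test_that("clinical cohorts plant group effects and covariates as configured", {
  part <- sixNetPartition(3L, 4L)
  expect_error(genClinicalCohort(10, 10, part, effectSize = 1), "effectPairs")
  expect_error(genClinicalCohort(10, 10, part, effectPairs = "Nope--X",
                                 effectSize = 1), "unknown")

  coh <- genClinicalCohort(40, 40, part, effectPairs = "Net1--Net2",
                           effectSize = 1, seed = 8L)
  expect_equal(dim(coh$features), c(80L, 66L))
  expect_equal(levels(coh$group), c("control", "patient"))
  ee <- coh$truth$effectEdges
  shift <- colMeans(coh$features[coh$group == "patient", ee, drop = FALSE]) -
    colMeans(coh$features[coh$group == "control", ee, drop = FALSE])
  expect_equal(mean(shift), 0.2, tolerance = 0.05)  # effectSize * noiseSd
  expect_identical(genClinicalCohort(5, 5, part, seed = 3L),
                   genClinicalCohort(5, 5, part, seed = 3L))
})

test_that("null clinical cohorts keep downstream classifiers at chance", {
  part <- sixNetPartition(3L, 4L)
  auc <- vapply(1:20, function(i) {
    coh <- genClinicalCohort(20, 20, part, seed = 900 + i)
    baselineClassify(coh$features, coh$group, folds = 5L, seed = i)@auc
  }, numeric(1))
  expect_gte(mean(auc), 0.4)
  expect_lte(mean(auc), 0.6)
})

test_that("planted effects on five pairs support accurate masked classification", {
  part <- sixNetPartition(4L, 6L)  # 24 ROIs
  pairs5 <- c("Net1--Net2", "Net1--Net3", "Net2--Net4", "Net3--Net5",
              "Net4--Net6")
  w <- syntheticWeights(part, pairs5)
  acc <- vapply(1:10, function(i) {
    coh <- genClinicalCohort(50, 50, part, effectPairs = pairs5,
                             effectSize = 1, seed = 1000 + i)
    nestedCVClassify(coh$features, coh$group, w, part, outerFolds = 5L,
                     innerFolds = 5L, seed = i)@accuracy
  }, numeric(1))
  expect_gt(mean(acc), 0.7)
})

test_that("confound-driven separability disappears under in-fold regression", {
  part <- sixNetPartition(3L, 4L)
  aucBefore <- aucAfter <- numeric(10)
  for (i in 1:10) {
    coh <- genClinicalCohort(25, 25, part,
                             confoundCoupling = c(age = 0.02, sex = 0),
                             ageMean = c(control = 30, patient = 45),
                             seed = 1100 + i)
    conf <- data.frame(age = coh$phenotype$age, sex = coh$phenotype$sex)
    aucBefore[i] <- baselineClassify(coh$features, coh$group, folds = 5L,
                                     seed = i)@auc
    aucAfter[i] <- baselineClassify(coh$features, coh$group, folds = 5L,
                                    confounds = conf, seed = i)@auc
  }
  expect_gt(mean(aucBefore), 0.65)
  expect_gte(mean(aucAfter), 0.4)
  expect_lte(mean(aucAfter), 0.6)
})
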