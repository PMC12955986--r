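test_that("state combinations enumerate all non-empty subsets in size order", {
  expect_length(enumerateCombos(4L), 15L)
  expect_length(enumerateCombos(1L), 1L)
  expect_length(enumerateCombos(3L), 7L)
  c4 <- enumerateCombos(4L)
  expect_equal(names(c4)[1:6], c("1", "2", "3", "4", "12", "13"))
  expect_equal(c4[["34"]], c(3L, 4L))
  expect_error(enumerateCombos(0L), ">= 1")
})

test_that("combo samples concatenate state blocks and exclude incomplete episodes", {
  set.seed(30)
  p <- 5L; d <- 10L
  info <- data.frame(
    subject = c("s1", "s1", "s1", "s2", "s2"),
    episode = c("e1", "e1", "e2", "e1", "e1"),
    condition = c("happy", "happy", "sad", "sad", "sad"),
    state = c(1L, 2L, 1L, 1L, 2L), nWindows = 5L)
  fc <- matrix(rnorm(5 * d), 5, d)
  sfc <- makeStateFCSet(fc, info, p)

  smp <- buildComboSamples(sfc, c(1L, 2L))
  expect_equal(ncol(smp$x), 2L * d)
  expect_equal(nrow(smp$x), 2L)     # s1/e2 lacks state 2
  expect_equal(smp$excluded, 1L)
  expect_equal(smp$x[1, ], c(fc[1, ], fc[2, ]))  # ascending state order

  smp1 <- buildComboSamples(sfc, 1L)
  expect_equal(nrow(smp1$x), 3L)
  expect_error(buildComboSamples(makeStateFCSet(fc[1, , drop = FALSE],
                                                info[1, ], p), 2L),
               "no episode")
})

test_that("LOSO decoding separates planted signal and is at chance under permuted labels", {
  set.seed(31)
  nSub <- 8L; eps <- 6L
  subjects <- rep(sprintf("s%d", 1:nSub), each = eps)
  y <- factor(rep(c("happy", "sad"), length.out = nSub * eps))
  x <- matrix(rnorm(nSub * eps * 100), ncol = 100)
  x[y == "happy", 1:10] <- x[y == "happy", 1:10] + 5
  res <- losoDecode(x, y, subjects, nSelected = 20L, seed = 1L)
  expect_equal(res$mean, 1)
  expect_length(res$foldAccuracy, nSub)
  expect_true(all(vapply(res$selected, length, integer(1)) <= 20L))
  expect_true(all(vapply(res$selected, function(s) all(1:10 %in% s), logical(1))))

  nullAcc <- vapply(1:20, function(i) {
    set.seed(400 + i)
    xp <- matrix(rnorm(24 * 40), 24, 40)
    yp <- factor(sample(rep(c("happy", "sad"), 12)))
    losoDecode(xp, yp, rep(sprintf("s%d", 1:6), each = 4), nSelected = 10L)$mean
  }, numeric(1))
  expect_gte(mean(nullAcc), 0.35)
  expect_lte(mean(nullAcc), 0.65)
})

test_that("optimal-model rule prefers small SD within the accuracy band", {
  expect_equal(unname(selectOptimalModel(80, 10)), 1L)
  expect_equal(unname(selectOptimalModel(c(a = 80, b = 80), c(10, 5))), 2L)
  expect_equal(unname(selectOptimalModel(c(80, 80), c(5, 5))), 1L)  # earlier combo
  # outside the band the higher mean wins regardless of SD
  expect_equal(unname(selectOptimalModel(c(70, 80), c(1, 20), tolerance = 0.5)), 2L)
})

test_that("stable features intersect folds; DEFN weights are edge fractions", {
  expect_equal(stableFeatures(list(c(1, 2, 3), c(2, 3, 4), c(2, 3))), c(2, 3))
  expect_length(stableFeatures(list(1:3, 4:6)), 0L)

  part <- tinyPartition()  # A: ROIs 1-3, B: ROIs 4-5
  map <- upperIndexMap(5L)
  withinA <- which(map$i <= 3 & map$j <= 3)[1:2]
  between <- which(map$i <= 3 & map$j >= 4)[1:3]
  w <- defnWeights(c(withinA, between), 1L, part)
  tb <- weightTable(w)
  expect_equal(tb$weight[tb$pair == "A--A"], 2 / 3)
  expect_equal(tb$weight[tb$pair == "A--B"], 0.5)
  expect_equal(tb$weight[tb$pair == "B--B"], 0)

  # union across state blocks deduplicates edge identities
  w2 <- defnWeights(c(withinA, withinA + 10L), c(1L, 2L), part)
  expect_equal(weightTable(w2)$stableCount[1], 2L)

  expect_true(all(weightTable(defnWeights(integer(0), 1L, part))$weight == 0))
  expect_true(all(weightTable(defnWeights(1:10, 1L, part))$weight == 1))
  expect_error(defnWeights(11L, 1L, part), "out of range")
  wm <- weightMatrix(w)
  expect_equal(wm["A", "B"], 0.5)
  expect_equal(wm, t(wm))
})

test_that("model comparison gates on normality and adjusts with BH", {
  set.seed(33)
  acc <- cbind(ref = rnorm(51, 0.84, 0.05),
               worse = NA, same = NA)
  acc[, "worse"] <- acc[, "ref"] - 0.10 + rnorm(51, 0, 0.01)
  acc[, "same"] <- acc[, "ref"]
  out <- compareModels(acc, "ref")
  expect_equal(out$p[out$combo == "same"], 1)
  expect_lt(out$q[out$combo == "worse"], 0.05)
  expect_true(all(out$q >= out$p))
})
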