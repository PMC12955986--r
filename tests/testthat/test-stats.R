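test_that("summary-based and raw pooled t agree exactly", {
  set.seed(50)
  for (i in 1:5) {
    x <- rnorm(17, 1, 2); y <- rnorm(23, 0, 3)
    a <- tTwoSample(x, y)
    b <- tFromSummary(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
    expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
    expect_equal(a$p, b$p, tolerance = 1e-12)
    s <- tTwoSample(y, x)
    expect_equal(s$statistic, -a$statistic, tolerance = 1e-12)
  }
  same <- tFromSummary(5, 1, 10, 5, 1, 10)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
})

test_that("chi-square is uncorrected Pearson and transpose-invariant", {
  tab <- matrix(c(37, 29, 63, 29), 2)
  r <- pearsonChi2(tab)
  expect_equal(r$statistic, pearsonChi2(t(tab))$statistic)
  expect_equal(r$df, 1)
  prop <- matrix(c(10, 20, 30, 60), 2)
  expect_equal(pearsonChi2(prop)$statistic, 0)
  expect_error(pearsonChi2(matrix(c(0, 0, 5, 5), 2)), "marginal")
})

test_that("paired t handles hand values and degenerate differences", {
  r <- pairedT(c(2, 0, 4, 2))
  expect_equal(r$statistic, 2.449, tolerance = 1e-3)
  expect_equal(r$statistic, mean(c(2, 0, 4, 2)) / (sd(c(2, 0, 4, 2)) / 2),
               tolerance = 1e-12)
  expect_equal(r$df, 3)

  z <- pairedT(rep(0, 6))
  expect_equal(z$p, 1)
  expect_true(z$degenerate)
  cst <- pairedT(c(1, 1, 1, 1))
  expect_true(cst$degenerate)
  expect_true(is.infinite(cst$statistic))
})

test_that("Wilcoxon exact p matches exhaustive sign enumeration", {
  # all-positive n = 6: two-sided exact p = 2/64
  allpos <- wilcoxonSignedRank(c(1, 2, 3, 4, 5, 6))
  expect_equal(allpos$p, 1 / 32)
  expect_true(allpos$exact)

  set.seed(51)
  for (n in 5:10) {
    d <- round(runif(n, 0.5, 10), 3) * sample(c(-1, 1), n, replace = TRUE)
    if (any(duplicated(abs(d)))) next
    expect_equal(wilcoxonSignedRank(d)$p, wilcoxExactOracle(d),
                 tolerance = 1e-12)
  }

  # exact and normal approximation agree reasonably at n = 20
  set.seed(52)
  for (i in 1:5) {
    d <- rnorm(20) + 0.3
    pe <- wilcoxonSignedRank(d)$p
    dn <- d[d != 0]
    pa <- suppressWarnings(wilcox.test(dn, exact = FALSE, correct = FALSE)$p.value)
    expect_lt(abs(pe - pa), 0.02)
  }
  expect_error(wilcoxonSignedRank(c(0, 0, 0, 0, 0, 1)), "fewer than 5")
})

test_that("Lilliefors gate is calibrated and powered", {
  set.seed(53)
  rej <- vapply(1:1000, function(i) lilliefors(rnorm(50))$p < 0.05, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.075)
  rejExp <- vapply(1:200, function(i) lilliefors(rexp(50))$p < 0.05, logical(1))
  expect_gte(mean(rejExp), 0.8)
  expect_error(lilliefors(rep(1, 10)), "zero variance")
})

test_that("BH adjustment matches the hand-stepped example and preserves order", {
  expect_equal(fdrBH(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdrBH(0.2), 0.2)
  expect_equal(fdrBH(rep(1, 5)), rep(1, 5))
  set.seed(54)
  p <- runif(50)
  q <- fdrBH(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))  # q monotone in p
  expect_true(all(q >= p) && all(q <= 1))
  expect_error(fdrBH(c(0.5, 1.2)), "outside")
})

test_that("phenotype tables recompute group statistics per variable", {
  set.seed(55)
  ph <- data.frame(group = rep(c("hc", "pat"), c(30, 25)),
                   age = c(rnorm(30, 45, 10), rnorm(25, 40, 10)),
                   sex = rbinom(55, 1, 0.5),
                   bdi = c(rnorm(30, 8, 5), rnorm(25, 25, 8)))
  ph$bdi[1:5] <- NA   # subscale measured on a subset
  out <- tableStats(ph, groups = c("hc", "pat"))
  expect_setequal(out$variable, c("age", "bdi", "sex"))
  bdi <- out[out$variable == "bdi", ]
  expect_equal(bdi$n1, 25)
  ref <- tTwoSample(ph$age[ph$group == "hc"], ph$age[ph$group == "pat"])
  expect_equal(out$statistic[out$variable == "age"], ref$statistic)
  expect_equal(out$method[out$variable == "sex"], "Pearson chi-square")
})
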