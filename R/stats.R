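#' Pooled two-sample t-test from group summaries
#'
#' Student's t with pooled variance computed directly from printed group
#' summaries (mean, sample SD with n-1 denominator, n), as needed to
#' recompute demographic-table statistics:
#' sp^2 = ((n1-1)s1^2 + (n2-1)s2^2) / (n1+n2-2),
#' t = (m1 - m2) / sqrt(sp^2 (1/n1 + 1/n2)), df = n1+n2-2, two-tailed p.
#' Sign convention is group 1 minus group 2.
#'
#' @param m1,s1,n1 mean, SD and size of group 1.
#' @param m2,s2,n2 mean, SD and size of group 2.
#' @return list: statistic, df, p, method.
#' @export
tFromSummary <- function(m1, s1, n1, m2, s2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, s1 >= 0, s2 >= 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(statistic = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df),
       method = "pooled two-sample t")
}

#' Pooled two-sample t-test from raw data
#'
#' Equal-variance Student's t (via [stats::t.test()] with `var.equal`);
#' agrees exactly with [tFromSummary()] applied to the groups' summaries.
#'
#' @param x,y numeric vectors (each n >= 2).
#' @export
tTwoSample <- function(x, y) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  r <- stats::t.test(x, y, var.equal = TRUE)
  list(statistic = unname(r$statistic), df = unname(r$parameter),
       p = r$p.value, method = "pooled two-sample t")
}

#' Pearson chi-square on a 2 x 2 table
#'
#' Uncorrected (no Yates continuity correction) Pearson chi-square with
#' expected counts from the margins, df = 1.
#'
#' @param tab 2 x 2 matrix of counts.
#' @export
pearsonChi2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2L), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal total")
  r <- stats::chisq.test(tab, correct = FALSE)
  list(statistic = unname(r$statistic), df = unname(r$parameter),
       p = r$p.value, method = "Pearson chi-square")
}

#' Paired t-test on differences
#'
#' t = mean(d) / (sd(d)/sqrt(n)), df = n-1, two-tailed. Zero-variance
#' differences are degenerate: all-zero d reports p = 1 (no evidence of a
#' difference); constant nonzero d reports an infinite statistic with p = 0,
#' both flagged.
#'
#' @param d numeric vector of paired differences (n >= 2).
#' @return list: statistic, df, p, method, degenerate flag.
#' @export
pairedT <- function(d) {
  n <- length(d)
  stopifnot(n >= 2L)
  s <- stats::sd(d)
  if (s == 0) {
    if (mean(d) == 0)
      return(list(statistic = 0, df = n - 1, p = 1, method = "paired t",
                  degenerate = TRUE))
    return(list(statistic = sign(mean(d)) * Inf, df = n - 1, p = 0,
                method = "paired t", degenerate = TRUE))
  }
  tstat <- mean(d) / (s / sqrt(n))
  list(statistic = tstat, df = n - 1, p = 2 * stats::pt(-abs(tstat), n - 1),
       method = "paired t", degenerate = FALSE)
}

#' Wilcoxon signed-rank test on differences
#'
#' Zeros are dropped and ties get mid-ranks (via [stats::wilcox.test()]).
#' The p-value is exact when n <= 25 after zero-dropping and no ties are
#' present, otherwise a normal approximation with tie correction (no
#' continuity correction) is used.
#'
#' @param d numeric differences; n >= 5 required after dropping zeros.
#' @return list: statistic (V), p, n, exact flag, method.
#' @export
wilcoxonSignedRank <- function(d) {
  dn <- d[d != 0]
  n <- length(dn)
  if (n < 5L) stop("fewer than 5 nonzero differences")
  ties <- any(duplicated(abs(dn)))
  exact <- n <= 25L && !ties
  r <- suppressWarnings(stats::wilcox.test(dn, exact = exact, correct = FALSE))
  list(statistic = unname(r$statistic), p = r$p.value, n = n, exact = exact,
       method = "Wilcoxon signed-rank")
}

#' Lilliefors normality test
#'
#' Kolmogorov-Smirnov distance against a normal distribution with mean and
#' SD estimated from the sample, with the Lilliefors small-sample p-value
#' (via nortest). Used as the gate that routes paired model comparisons to
#' a paired t-test (normal differences) or a Wilcoxon signed-rank test.
#'
#' @param x numeric vector, n >= 5, non-constant.
#' @return list: statistic (D), p, method.
#' @export
lilliefors <- function(x) {
  if (length(x) < 5L) stop("need at least 5 observations")
  if (stats::sd(x) == 0) stop("zero variance")
  r <- nortest::lillie.test(x)
  list(statistic = unname(r$statistic), p = r$p.value, method = "Lilliefors")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values in the input order; q is monotone in p and
#' capped at 1.
#'
#' @param p p-values in \[0, 1\].
#' @export
fdrBH <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Demographic-table statistics from a phenotype table
#'
#' Recomputes a demographics/clinical table: per continuous variable, group
#' means, sample SDs, sizes and the pooled two-sample t; for sex, the group
#' counts and the uncorrected Pearson chi-square. Rows with a missing value
#' of a variable are dropped for that variable only, so subscale statistics
#' computed on subsets (as clinical scales often are) come out right.
#'
#' @param phenotype data.frame with columns group, sex, and numeric
#'   variables.
#' @param groups length-2 character giving the group order (group 1 minus
#'   group 2 sign convention).
#' @param vars continuous variables to test (default: all numeric columns
#'   except age-unrelated identifiers).
#' @return data.frame: variable, summaries per group, statistic, df, p,
#'   method.
#' @export
tableStats <- function(phenotype, groups = levels(factor(phenotype$group)),
                       vars = NULL) {
  stopifnot(length(groups) == 2L, "group" %in% names(phenotype))
  if (is.null(vars)) {
    numeric_cols <- vapply(phenotype, is.numeric, logical(1))
    vars <- setdiff(names(phenotype)[numeric_cols], c("sex"))
  }
  rows <- lapply(vars, function(v) {
    x <- phenotype[phenotype$group == groups[1L], v]
    y <- phenotype[phenotype$group == groups[2L], v]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    r <- tFromSummary(mean(x), stats::sd(x), length(x),
                      mean(y), stats::sd(y), length(y))
    data.frame(variable = v, mean1 = mean(x), sd1 = stats::sd(x),
               n1 = length(x), mean2 = mean(y), sd2 = stats::sd(y),
               n2 = length(y), statistic = r$statistic, df = r$df, p = r$p,
               method = r$method, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if ("sex" %in% names(phenotype)) {
    ok <- !is.na(phenotype$sex)
    tab <- table(factor(phenotype$group[ok], levels = groups),
                 phenotype$sex[ok])
    if (all(dim(tab) == 2L)) {
      r <- pearsonChi2(tab)
      out <- rbind(out, data.frame(
        variable = "sex", mean1 = NA, sd1 = NA, n1 = sum(tab[1L, ]),
        mean2 = NA, sd2 = NA, n2 = sum(tab[2L, ]), statistic = r$statistic,
        df = r$df, p = r$p, method = r$method, stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}
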