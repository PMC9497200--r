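# The statistical battery, checked against closed forms, enumeration and
# the base-R reference implementations.

test_that("Mann-Whitney handles identical samples and reports mean ranks", {
  mw <- mannWhitneyU(c(3, 1, 4), c(4, 1, 3))
  expect_equal(mw$mean_rank_a, mw$mean_rank_b)
  expect_equal(mw$p_two_sided, 1)
  deg <- mannWhitneyU(c(2, 2), c(2, 2, 2))
  expect_true(deg$degenerate)
  expect_equal(deg$p_two_sided, 1)
  expect_error(mannWhitneyU(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney exact p matches full enumeration on the textbook case", {
  mw <- mannWhitneyU(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$method, "exact")
  expect_equal(mw$p_two_sided, 1 / 3)
})

test_that("exact p equals an independent pair-counting enumeration oracle", {
  set.seed(123)
  for (i in 1:30) {
    a <- sample(0:12, sample(2:8, 1), replace = TRUE)
    b <- sample(0:12, sample(2:8, 1), replace = TRUE)
    mw <- mannWhitneyU(a, b, method = "exact")
    # oracle: U by direct pair counting over every group assignment
    pooled <- c(a, b); n1 <- length(a)
    Ufun <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    sel <- utils::combn(length(pooled), n1)
    Us <- apply(sel, 2, function(s) Ufun(pooled[s], pooled[-s]))
    uObs <- Ufun(a, b)
    pOracle <- min(1, 2 * min(mean(Us <= uObs + 1e-9),
                              mean(Us >= uObs - 1e-9)))
    expect_equal(mw$U, uObs)
    expect_equal(mw$p_two_sided, pOracle)
  }
})

test_that("normal approximation tracks the exact p at moderate group sizes", {
  set.seed(55)
  diffs <- replicate(200, {
    a <- stats::runif(6); b <- stats::runif(7)
    abs(mannWhitneyU(a, b, method = "exact")$p_two_sided -
          mannWhitneyU(a, b, method = "normal")$p_two_sided)
  })
  expect_lt(mean(diffs), 0.05)
  expect_lt(max(diffs), 0.075)   # discrete null vs uncorrected normal
})

test_that("Mann-Whitney agrees with the base-R reference and is rank-invariant", {
  set.seed(77)
  a <- rpois(15, 4); b <- rpois(20, 7)
  mw <- mannWhitneyU(a, b, method = "normal")
  ref <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                             correct = FALSE))
  expect_equal(unname(mw$U), unname(ref$statistic))
  expect_equal(mw$p_two_sided, ref$p.value, tolerance = 1e-10)
  # invariance under a strictly monotone transform of the pooled values
  tr <- function(x) exp(x / 2) + 3
  mw2 <- mannWhitneyU(tr(a), tr(b), method = "normal")
  expect_equal(mw2$p_two_sided, mw$p_two_sided)
  expect_equal(mw2$U, mw$U)
})

test_that("Spearman matches the rank-difference formula and stays in [-1, 1]", {
  x <- c(10, 20, 30, 40, 50)
  expect_equal(spearmanRho(x, x)$rho, 1)
  expect_equal(spearmanRho(x, rev(x))$rho, -1)
  set.seed(8)
  for (i in 1:20) {
    x <- sample(1:1000, 8); y <- sample(1:1000, 8)
    d <- rank(x) - rank(y)
    expect_equal(spearmanRho(x, y)$rho, 1 - 6 * sum(d^2) / (8 * 63))
    ref <- stats::cor.test(x, y, method = "spearman")
    expect_equal(spearmanRho(x, y)$rho, unname(ref$estimate))
    expect_gte(spearmanRho(x, y)$rho, -1)
    expect_lte(spearmanRho(x, y)$rho, 1)
  }
  # invariance under strictly increasing transforms
  x <- rpois(20, 5); y <- rpois(20, 9)
  expect_equal(spearmanRho(log1p(x), exp(y))$rho, spearmanRho(x, y)$rho)
  expect_error(spearmanRho(1:3, 1:4), "paired")
  expect_true(spearmanRho(rep(1, 5), 1:5)$degenerate)
})

test_that("the chi-square reproduces the published stage comparison", {
  tab <- matrix(c(56, 48, 48, 18), 2, byrow = TRUE)
  cs <- chiSquare2x2(tab)
  expect_equal(round(cs$p, 3), 0.014)
  ref <- stats::chisq.test(tab, correct = FALSE)
  expect_equal(cs$chi2, unname(ref$statistic))
  expect_equal(cs$p, ref$p.value)
  expect_equal(cs$expected, unname(ref$expected), ignore_attr = TRUE)
})

test_that("chi-square is zero on independent tables and permutation-invariant", {
  expect_equal(chiSquare2x2(matrix(10, 2, 2))$chi2, 0)
  expect_equal(chiSquare2x2(matrix(10, 2, 2))$p, 1)
  tab <- matrix(c(12, 5, 7, 20), 2)
  cs <- chiSquare2x2(tab)
  expect_equal(chiSquare2x2(tab[2:1, ])$chi2, cs$chi2)
  expect_equal(chiSquare2x2(tab[, 2:1])$chi2, cs$chi2)
  expect_equal(chiSquare2x2(t(tab))$chi2, cs$chi2)
  expect_error(chiSquare2x2(matrix(c(0, 0, 3, 4), 2)), "margin")
})

test_that("the paired t statistic matches the hand-computed case", {
  tt <- pairedTTest(c(2, 4, 6), c(1, 2, 3))   # differences 1, 2, 3
  expect_equal(tt$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(tt$df, 2L)
  same <- pairedTTest(1:5, 1:5)
  expect_equal(same$t, 0)
  expect_equal(same$p_two_sided, 1)
  expect_true(same$degenerate)
  deg <- pairedTTest(c(2, 3, 4), c(1, 2, 3))   # constant nonzero differences
  expect_true(deg$degenerate)
})

test_that("counts bin into the published categories with inclusive boundaries", {
  d <- data.frame(stage = "CNPC", ctc = c(0, 1, 4, 5, 12),
                  tdev = c(0, 50, 51, 200, 7))
  bins <- binCounts(d)
  expect_equal(as.character(bins$ctc_category),
               c("0", "1-4", "1-4", ">=5", ">=5"))
  expect_equal(as.character(bins$tdev_category),
               c("<=50", "<=50", ">50", ">50", "<=50"))
})

test_that("the cohort report runs the full battery on a simulated cohort", {
  d <- simulateCohort(nPerStage = 120, seed = 31)
  rep <- cohortReport(d)
  expect_true(all(c("mann_whitney", "chi_square_presence",
                    "spearman_ctc_tdev") %in% rep$tests$test))
  medc <- rep$descriptives
  mCN <- medc$median[medc$stage == "CNPC" & medc$marker == "ctc"]
  mCR <- medc$median[medc$stage == "CRPC" & medc$marker == "ctc"]
  expect_gt(mCR, mCN)
  expect_warning(cohortReport(d[d$stage == "CNPC", ]), "single stage")
  expect_error(cohortReport(d[0, ]), "empty")
  # paired timepoints trigger the paired t tests
  pp <- simulatePairedCohort(n = 20, seed = 32)
  repP <- suppressWarnings(cohortReport(pp))   # single-stage warning expected
  expect_true("paired_t_post_treatment" %in% repP$tests$test)
  out <- withr::local_tempdir()
  cohortReport(d, out = out)
  expect_true(file.exists(file.path(out, "report.md")))
  expect_true(file.exists(file.path(out, "tests.csv")))
})
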