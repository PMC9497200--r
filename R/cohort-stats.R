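# Cohort-level statistics on per-patient count tables: the nonparametric
# battery used to compare the two disease stages and the paired
# pre/post-treatment counts.

#' Mann-Whitney U test with mean ranks
#'
#' Ranks the pooled sample with midranks for ties and computes the U
#' statistic from the rank sums. Mean ranks of both groups are reported
#' (the convention used when cohort comparisons are published). The
#' two-sided p-value uses the normal approximation with tie-corrected
#' variance and no continuity correction; when both groups have at most
#' `exactMax` observations (default 8), the exact permutation distribution
#' of U is enumerated instead.
#'
#' @param a,b numeric samples (non-empty).
#' @param method `"auto"` (exact when both n <= `exactMax`), `"exact"`,
#'   or `"normal"`.
#' @param exactMax group-size limit for automatic exact enumeration.
#' @return list with `U` (for group `a`), `mean_rank_a`, `mean_rank_b`,
#'   `p_two_sided`, `method` and `degenerate` (all pooled values
#'   identical).
#' @export
mannWhitneyU <- function(a, b, method = c("auto", "exact", "normal"),
                         exactMax = 8L) {
  method <- match.arg(method)
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  pooled <- c(a, b)
  rk <- rank(pooled)           # midranks
  R1 <- sum(rk[seq_len(n1)])
  U <- R1 - n1 * (n1 + 1) / 2
  out <- list(U = U, mean_rank_a = R1 / n1,
              mean_rank_b = sum(rk[n1 + seq_len(n2)]) / n2)
  if (length(unique(pooled)) == 1L) {
    out$p_two_sided <- 1; out$method <- "degenerate"; out$degenerate <- TRUE
    return(out)
  }
  out$degenerate <- FALSE
  if (method == "auto")
    method <- if (n1 <= exactMax && n2 <= exactMax) "exact" else "normal"
  if (method == "exact") {
    sel <- utils::combn(N, n1)
    Us <- colSums(matrix(rk[sel], nrow = n1)) - n1 * (n1 + 1) / 2
    pLo <- mean(Us <= U + 1e-9)
    pHi <- mean(Us >= U - 1e-9)
    out$p_two_sided <- min(1, 2 * min(pLo, pHi))
  } else {
    ties <- table(pooled)
    tieTerm <- sum(ties^3 - ties) / (N * (N - 1))
    v <- n1 * n2 / 12 * ((N + 1) - tieTerm)
    z <- (U - n1 * n2 / 2) / sqrt(v)
    out$p_two_sided <- 2 * stats::pnorm(-abs(z))
  }
  out$method <- method
  out
}

#' Spearman rank correlation with two-sided p-value
#'
#' Pearson correlation of midranks; p from the t approximation with
#' n - 2 degrees of freedom.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return list with `rho`, `p_two_sided`, `n` and `degenerate` (zero
#'   variance in either ranked vector; `rho` is then `NA`).
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = NA_real_, p_two_sided = NA_real_, n = n,
                degenerate = TRUE))
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(t), n - 2)
  }
  list(rho = rho, p_two_sided = p, n = n, degenerate = FALSE)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson statistic sum (O - E)^2 / E without continuity correction,
#' with 1 degree of freedom (the uncorrected statistic is the variant
#' that reproduces the published CTC-presence comparison between the two
#' stages).
#'
#' @param tab 2x2 matrix of nonnegative counts (rows = groups,
#'   columns = categories) with positive margins.
#' @return list with `chi2`, `df = 1`, `p` and `expected` (matrix of
#'   expected counts).
#' @export
chiSquare2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("a 2x2 table is required")
  if (any(tab < 0) || sum(tab) <= 0) stop("counts must be nonnegative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in contingency table")
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((tab - E)^2 / E)
  list(chi2 = chi2, df = 1L,
       p = stats::pchisq(chi2, 1L, lower.tail = FALSE), expected = E)
}

#' Paired t test on count differences
#'
#' Standard paired statistic on `pre - post` with n - 1 degrees of
#' freedom, computed on raw counts (a log-scale option is available for
#' heavy-tailed counts).
#'
#' @param pre,post equal-length numeric vectors, n >= 2.
#' @param logScale test `log1p(pre) - log1p(post)` instead of raw
#'   differences (default `FALSE`).
#' @return list with `t`, `df`, `p_two_sided`, `mean_difference` and
#'   `degenerate` (zero-variance differences; p is then `NA`).
#' @export
pairedTTest <- function(pre, post, logScale = FALSE) {
  if (length(pre) != length(post)) stop("pre and post must be paired")
  if (length(pre) < 2L) stop("need at least 2 pairs")
  x <- if (logScale) log1p(pre) else pre
  y <- if (logScale) log1p(post) else post
  d <- x - y
  if (stats::sd(d) == 0) {
    return(list(t = if (all(d == 0)) 0 else NA_real_, df = length(d) - 1L,
                p_two_sided = if (all(d == 0)) 1 else NA_real_,
                mean_difference = mean(d), degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_two_sided = ht$p.value, mean_difference = mean(d),
       degenerate = FALSE)
}

#' Bin patient counts into the published reporting categories
#'
#' CTC counts fall into `{0}`, `[1, 5)` and `[5, Inf)`; tdEV counts into
#' `(-Inf, 50]` and `(50, Inf)`.
#'
#' @param samples cohort data.frame with `stage`, `ctc`, `tdev` columns.
#' @return list with `ctc_category` / `tdev_category` factors (aligned
#'   with `samples`), the per-stage cross-tabulations `ctc_by_stage`
#'   (stages x 3) and `tdev_by_stage` (stages x 2), and
#'   `ctc_presence_by_stage` (stages x {CTC > 0, CTC = 0}), the 2x2 input
#'   of the presence chi-square.
#' @export
binCounts <- function(samples) {
  ctcCat <- cut(samples$ctc, breaks = c(-Inf, 0, 4, Inf),
                labels = c("0", "1-4", ">=5"))
  tdevCat <- cut(samples$tdev, breaks = c(-Inf, 50, Inf),
                 labels = c("<=50", ">50"))
  list(ctc_category = ctcCat, tdev_category = tdevCat,
       ctc_by_stage = table(stage = samples$stage, ctc = ctcCat),
       tdev_by_stage = table(stage = samples$stage, tdev = tdevCat),
       ctc_presence_by_stage =
         table(stage = samples$stage,
               presence = factor(ifelse(samples$ctc > 0, "CTC>0", "CTC=0"),
                                 levels = c("CTC>0", "CTC=0"))))
}

.describe <- function(x) {
  c(n = length(x), median = stats::median(x), min = min(x), max = max(x),
    sd = stats::sd(x))
}

#' Cohort summary report
#'
#' Per-stage descriptives (median, range, SD) for CTC, tdEV and each
#' subclass, plus the between-stage test battery (Mann-Whitney U with
#' mean ranks for CTC, tdEV and each subclass; Spearman CTC--tdEV
#' correlation per stage; presence and tdEV-bin chi-squares) when two
#' stages are present, and the paired t tests when a second timepoint is
#' present.
#'
#' @param samples cohort data.frame (see [simulateCohort()] for the
#'   schema).
#' @param out optional directory; when given, a markdown report and a
#'   tidy CSV of test results are written there.
#' @return list with `descriptives` (data.frame), `tests` (data.frame)
#'   and `tables` (the binned contingency tables).
#' @export
cohortReport <- function(samples, out = NULL) {
  if (!nrow(samples)) stop("empty cohort table")
  base <- samples[samples$timepoint == "BASELINE", , drop = FALSE]
  stages <- unique(base$stage)
  subCols <- intersect(tolower(SUBCLASS_LEVELS), names(base))
  markers <- c("ctc", "tdev", subCols)
  desc <- do.call(rbind, lapply(stages, function(st) {
    d <- base[base$stage == st, ]
    do.call(rbind, lapply(markers, function(mk)
      cbind(data.frame(stage = st, marker = mk),
            as.data.frame(t(.describe(d[[mk]]))))))
  }))
  tests <- data.frame(test = character(0), marker = character(0),
                      statistic = numeric(0), p = numeric(0),
                      detail = character(0))
  addTest <- function(test, marker, statistic, p, detail = "")
    rbind(tests, data.frame(test = test, marker = marker,
                            statistic = statistic, p = p, detail = detail))
  for (st in stages) {
    d <- base[base$stage == st, ]
    sp <- spearmanRho(d$ctc, d$tdev)
    tests <- addTest("spearman_ctc_tdev", st, sp$rho, sp$p_two_sided,
                     if (sp$degenerate) "degenerate" else "")
  }
  if (length(stages) >= 2L) {
    s1 <- base[base$stage == stages[1], ]; s2 <- base[base$stage == stages[2], ]
    for (mk in markers) {
      mw <- mannWhitneyU(s1[[mk]], s2[[mk]])
      tests <- addTest("mann_whitney", mk, mw$U, mw$p_two_sided,
                       sprintf("mean ranks %.2f vs %.2f (%s)",
                               mw$mean_rank_a, mw$mean_rank_b, mw$method))
    }
    bins <- binCounts(base)
    cs <- chiSquare2x2(bins$ctc_presence_by_stage[stages[1:2], ])
    tests <- addTest("chi_square_presence", "ctc", cs$chi2, cs$p)
    cs2 <- chiSquare2x2(bins$tdev_by_stage[stages[1:2], ])
    tests <- addTest("chi_square_tdev_bins", "tdev", cs2$chi2, cs2$p)
  } else {
    bins <- binCounts(base)
    if (length(stages) < 2L)
      warning("single stage: between-stage tests omitted")
  }
  post <- samples[samples$timepoint == "POST_ADT_6M", , drop = FALSE]
  if (nrow(post)) {
    ids <- intersect(base$patient_id, post$patient_id)
    if (length(ids) >= 2L) {
      b <- base[match(ids, base$patient_id), ]
      p <- post[match(ids, post$patient_id), ]
      for (mk in c("ctc", "tdev")) {
        tt <- pairedTTest(b[[mk]], p[[mk]])
        tests <- addTest("paired_t_post_treatment", mk, tt$t, tt$p_two_sided,
                         sprintf("df=%d", tt$df))
      }
    }
  }
  res <- list(descriptives = desc, tests = tests, tables = bins)
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(desc, file.path(out, "descriptives.csv"),
                     row.names = FALSE)
    utils::write.csv(tests, file.path(out, "tests.csv"), row.names = FALSE)
    md <- c("# Cohort report", "", "## Descriptives", "",
            utils::capture.output(print(desc, row.names = FALSE)), "",
            "## Tests (p to 3 decimals)", "",
            utils::capture.output(print(transform(tests, p = round(p, 3)),
                                        row.names = FALSE)))
    writeLines(md, file.path(out, "report.md"))
  }
  res
}
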