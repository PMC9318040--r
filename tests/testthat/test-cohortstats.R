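test_that("group_summary matches hand computation on 1..7", {
  s <- group_summary(1:7)
  expect_equal(s$n, 7)
  expect_equal(s$median, 4)
  expect_equal(s$q1, 2)       # (n+1)p percentile definition
  expect_equal(s$q3, 6)
  expect_equal(s$n_outliers, 0)
  expect_equal(s$whisker_low, 1)
  expect_equal(s$whisker_high, 7)
  # single value: SD flagged undefined, median = value
  s1 <- group_summary(5)
  expect_true(is.na(s1$sd))
  expect_equal(s1$median, 5)
  # constant group: zero SD, whiskers at the constant
  sc <- group_summary(rep(2.5, 9))
  expect_equal(sc$sd, 0)
  expect_equal(sc$whisker_low, 2.5)
  expect_equal(sc$whisker_high, 2.5)
  # outliers are detected and listed
  so <- group_summary(c(1:10, 100))
  expect_equal(so$n_outliers, 1)
  expect_equal(attr(so, "outliers")[[1]], 100)
})

test_that("normality test matches an independent implementation and the
           small-n rule", {
  # frozen oracle: scipy.stats.normaltest on the same vector
  v <- c(1, 2, 2, 3, 3, 3, 4, 4, 5, 8, 9, 12, 15, 20)
  r <- normality_test(v)
  expect_equal(r$statistic, 6.112590008853097, tolerance = 1e-10)
  expect_equal(r$p_value, 0.04706173613454877, tolerance = 1e-10)
  # n < 8 is a typed "not assessable" result, not an error
  r4 <- normality_test(c(29, 31, 22, 35))
  expect_false(r4$assessable)
  expect_true(is.na(r4$p_value))
  expect_true(normality_test(rnorm(8))$assessable)
})

test_that("normality test has correct size and power by simulation", {
  set.seed(11)
  p_norm <- vapply(1:100, function(i) normality_test(rnorm(5000))$p_value, 0)
  expect_gte(mean(p_norm > 0.01), 0.95)
  set.seed(12)
  p_exp <- vapply(1:20, function(i) normality_test(rexp(5000))$p_value, 0)
  expect_true(all(p_exp < 0.01))
})

test_that("unpaired t-test: null identity, hand value, scale invariance", {
  same <- ttest_unpaired(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  tt <- ttest_unpaired(c(1, 2, 3), c(4, 5, 6))
  expect_equal(abs(tt$t), 3.674, tolerance = 1e-3)
  expect_equal(tt$p_value, 0.0214, tolerance = 1e-2)
  expect_equal(tt$df, 4)
  sc <- ttest_unpaired(10 * c(1, 2, 3), 10 * c(4, 5, 6))
  expect_equal(sc$t, tt$t)
  expect_error(ttest_unpaired(1, c(1, 2)), "at least 2")
})

test_that("pearson_with_regression: exact lines and error cases", {
  x <- c(1, 2, 4, 5, 9)
  # suppressWarnings: lm's "essentially perfect fit" note on exact lines
  p <- suppressWarnings(pearson_with_regression(x, 2 * x + 1))
  expect_equal(p$r, 1)
  expect_equal(p$slope, 2)
  expect_equal(p$intercept, 1)
  expect_equal(suppressWarnings(pearson_with_regression(x, -x))$r, -1)
  expect_error(pearson_with_regression(rep(1, 5), 1:5), "variance")
})

test_that("Fisher-z interval covers the true correlation ~95% of the time", {
  # coverage simulation at the study's sample size
  set.seed(5)
  rho <- -0.6
  n <- 195
  covered <- vapply(1:1000, function(i) {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    ci <- pearson_with_regression(x, y)
    ci$ci_low <= rho && rho <= ci$ci_high
  }, logical(1))
  expect_gt(mean(covered), 0.93)
  expect_lt(mean(covered), 0.97)
})

test_that("roc_youden: separable, null, and enumerated-cutoff cases", {
  # perfectly separated, higher-is-positive
  r <- roc_youden(c(1, 2, 3, 4), c(0, 0, 1, 1), positive_is_low = FALSE)
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity_pct, 100)
  expect_equal(r$specificity_pct, 100)
  expect_true(r$cutoff > 2 && r$cutoff < 3)
  # orientation: lower-is-positive mirrors it
  rl <- roc_youden(c(1, 2, 3, 4), c(1, 1, 0, 0), positive_is_low = TRUE)
  expect_equal(rl$auc, 1)
  expect_true(rl$cutoff > 2 && rl$cutoff < 3)
  # label-score independence: AUC near 1/2, chance inside the DeLong CI
  set.seed(31)
  sc <- rnorm(120)
  lb <- sample(rep(c(TRUE, FALSE), 60))
  rn <- roc_youden(sc, lb)
  expect_true(rn$ci_low <= 0.5 && 0.5 <= rn$ci_high)
  expect_gt(rn$p_value, 0.01)
  expect_error(roc_youden(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("AUC rank statistic equals trapezoidal ROC integration", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(10:80, 1)
    sc <- round(rnorm(n), sample(0:2, 1))  # ties included
    lb <- runif(n) < 0.4
    if (!any(lb) || all(lb)) next
    expect_equal(melif:::auc_rank(sc, lb), melif:::auc_trapezoid(sc, lb))
  }
})

test_that("Youden cutoff equals exhaustive threshold enumeration", {
  set.seed(23)
  for (i in 1:10) {
    n <- sample(20:120, 1)
    sc <- round(rnorm(n, mean = ifelse(runif(n) < 0.5, 0, 1)), 1)
    lb <- sc + rnorm(n) > 0.5
    if (!any(lb) || all(lb)) next
    r <- roc_youden(sc, lb, positive_is_low = FALSE)
    # oracle: scan every candidate cutoff by brute force
    cand <- sort(unique(c(sc - 0.05, sc + 0.05)))
    js <- vapply(cand, function(ct) {
      sens <- sum(sc >= ct & lb) / sum(lb)
      spec <- sum(sc < ct & !lb) / sum(!lb)
      sens + spec - 1
    }, 0)
    j_at_r <- {
      sens <- sum(sc >= r$cutoff & lb) / sum(lb)
      spec <- sum(sc < r$cutoff & !lb) / sum(!lb)
      sens + spec - 1
    }
    expect_equal(j_at_r, max(js), tolerance = 1e-12)
  }
})

test_that("binormal model: simulated AUC matches the closed form", {
  set.seed(41)
  mu0 <- 55; sd0 <- 11; mu1 <- 42; sd1 <- 11
  expected <- binormal_auc(mu0, sd0, mu1, sd1)
  aucs <- vapply(1:300, function(i) {
    s <- c(rnorm(132, mu0, sd0), rnorm(59, mu1, sd1))
    lab <- c(rep(FALSE, 132), rep(TRUE, 59))
    melif:::auc_rank(-s, lab)  # lower score = positive
  }, 0)
  expect_equal(mean(aucs), expected, tolerance = 0.01)
})

synthetic_cohort <- function(seed = 1, n = c(40, 25, 4)) {
  set.seed(seed)
  grp <- rep(c("normal", "impaired", "severe"), n)
  meld <- c(sample(6:10, n[1], TRUE), sample(11:18, n[2], TRUE),
            sample(19:25, n[3], TRUE))
  melif <- c(rnorm(n[1], 55, 11), rnorm(n[2], 42, 11), rnorm(n[3], 29, 7.7))
  rrt1 <- c(rnorm(n[1], 54, 10), rnorm(n[2], 43, 12), rnorm(n[3], 31, 14))
  data.frame(id = sprintf("P%03d", seq_along(grp)), meld = meld,
             meld_group = grp, melif = melif, rrt1_mean_pct = rrt1,
             stringsAsFactors = FALSE)
}

test_that("cohort_report assembles the full battery deterministically", {
  co <- synthetic_cohort()
  rep1 <- cohort_report(co)
  expect_equal(rep1$n, 69)
  expect_s3_class(rep1$by_group, "data.frame")
  expect_named(rep1$roc, c("melif", "rrt1"))
  # group ordering of MELIF means
  bg <- rep1$by_group[rep1$by_group$score == "melif", ]
  expect_true(bg$mean[bg$group == "normal"] > bg$mean[bg$group == "impaired"])
  expect_true(bg$mean[bg$group == "impaired"] > bg$mean[bg$group == "severe"])
  # correlations present and negative
  expect_lt(rep1$correlations$melif_vs_meld$r, 0)
  # determinism: identical input, identical report
  rep2 <- cohort_report(synthetic_cohort())
  expect_identical(rep1[setdiff(names(rep1), "notes")],
                   rep2[setdiff(names(rep2), "notes")])
  # files written when requested
  out <- file.path(tempdir(), "report_out")
  cohort_report(co, out_dir = out)
  expect_true(file.exists(file.path(out, "table2_by_group.csv")))
  expect_true(file.exists(file.path(out, "table3_roc.csv")))
  expect_true(file.exists(file.path(out, "report.json")))
})

test_that("cohort_report degrades gracefully with one group", {
  co <- synthetic_cohort(n = c(12, 0, 0))
  rep1 <- cohort_report(co)
  expect_null(rep1$roc)
  expect_true(any(grepl("ROC omitted", rep1$notes)))
  expect_error(cohort_report(co[0, ]), "empty|columns")
  co_dup <- rbind(co, co[1, ])
  expect_error(cohort_report(co_dup), "duplicate")
})
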