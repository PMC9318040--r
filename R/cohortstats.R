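#' @title Cohort-level diagnostic statistics
#'
#' @description
#' The validation battery applied to a scored cohort: per-group descriptive
#' summaries (mean/SD, median/IQR, Tukey boxplot statistics),
#' D'Agostino-Pearson omnibus normality testing, unpaired t-tests, Pearson
#' correlation with Fisher-z confidence intervals and simple linear
#' regression, and ROC analysis with DeLong confidence intervals and
#' Youden-index cutoffs. Score orientation is handled so that LOWER imaging
#' scores indicate impairment (contrast uptake falls with failing liver
#' function).
#' @name cohortstats
NULL

#' Per-group descriptive summary
#'
#' @param values numeric vector.
#' @param group factor/character of the same length (a single group when
#'   omitted).
#' @return data frame with one row per group: `n`, `mean`, `sd` (`NA` when
#'   n < 2), `median`, `q1`, `q3`, `iqr`, Tukey whiskers
#'   (`whisker_low`/`whisker_high` at the most extreme points within
#'   1.5 IQR of the quartiles) and `n_outliers`; outlier values are
#'   attached as the `outliers` attribute (a list). Quartiles use the
#'   (n+1)p percentile definition (R's type 6), the convention of the
#'   statistics package the reporting format emulates.
#' @export
group_summary <- function(values, group = NULL) {
  if (!length(values)) stop("group_summary: empty input")
  if (is.null(group)) group <- rep("all", length(values))
  group <- factor(group)
  out <- lapply(levels(group), function(g) {
    v <- values[group == g & !is.na(values)]
    if (!length(v)) return(NULL)
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 6)
    iqr <- q[3] - q[1]
    lo_fence <- q[1] - 1.5 * iqr
    hi_fence <- q[3] + 1.5 * iqr
    inside <- v >= lo_fence & v <= hi_fence
    data.frame(
      group = g, n = length(v),
      mean = mean(v), sd = if (length(v) >= 2) stats::sd(v) else NA_real_,
      median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
      whisker_low = min(v[inside]), whisker_high = max(v[inside]),
      n_outliers = sum(!inside),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  attr(res, "outliers") <- lapply(levels(group), function(g) {
    v <- values[group == g & !is.na(values)]
    if (!length(v)) return(numeric(0))
    q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 6)
    v[v < q[1] - 1.5 * diff(q) | v > q[2] + 1.5 * diff(q)]
  })
  res
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the D'Agostino skewness z-score and the Anscombe-Glynn kurtosis
#' z-score into the omnibus statistic `K2 = z_s^2 + z_k^2`, chi-square with
#' 2 degrees of freedom under normality. Below the test's validity floor of
#' n = 8 the result is typed as "not assessable" (`assessable = FALSE`,
#' `NA` statistic and p) rather than an error — matching how a tiny
#' severe-disease group must be reported.
#'
#' @param values numeric vector.
#' @return list with `statistic`, `p_value`, `z_skew`, `z_kurt`, `n`,
#'   `assessable`.
#' @export
normality_test <- function(values) {
  v <- values[!is.na(values)]
  n <- length(v)
  if (n < 8)
    return(list(statistic = NA_real_, p_value = NA_real_,
                z_skew = NA_real_, z_kurt = NA_real_,
                n = n, assessable = FALSE))
  m <- mean(v)
  m2 <- mean((v - m)^2)
  m3 <- mean((v - m)^3)
  m4 <- mean((v - m)^4)
  b1 <- m3 / m2^1.5
  b2 <- m4 / m2^2

  # skewness (D'Agostino 1970, Johnson SU transform)
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z_s <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis (Anscombe & Glynn 1983)
  e_b2 <- 3 * (n - 1) / (n + 1)
  var_b2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  x <- (b2 - e_b2) / sqrt(var_b2)
  sqrt_b1_b2 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrt_b1_b2 * (2 / sqrt_b1_b2 + sqrt(1 + 4 / sqrt_b1_b2^2))
  z_k <- ((1 - 2 / (9 * a)) -
            ((1 - 2 / a) / (1 + x * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z_s^2 + z_k^2
  list(statistic = k2,
       p_value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z_s, z_kurt = z_k, n = n, assessable = TRUE)
}

#' Unpaired two-sample t-test
#'
#' Pooled-variance by default (classic unpaired t-test); Welch via
#' `var_equal = FALSE`.
#'
#' @param group_a,group_b numeric vectors, each with at least 2 values.
#' @param var_equal pool the variances (default TRUE).
#' @return list with `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
ttest_unpaired <- function(group_a, group_b, var_equal = TRUE) {
  a <- group_a[!is.na(group_a)]
  b <- group_b[!is.na(group_b)]
  if (length(a) < 2 || length(b) < 2)
    stop("ttest_unpaired: each group needs at least 2 values")
  ht <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Pearson correlation with Fisher-z interval and simple regression
#'
#' @param x,y numeric vectors (n >= 3, both with nonzero variance).
#' @return list with `r`, `ci_low`, `ci_high` (95%, Fisher z-transform),
#'   `p_value` (two-tailed), `slope`, `intercept`, `n`, and `se_fit`
#'   parameters (`sigma`, `mean_x`, `ssx`) for drawing the regression
#'   confidence band.
#' @export
pearson_with_regression <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("pearson_with_regression: need at least 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pearson_with_regression: zero variance in x or y")
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = 0.95)
  fit <- stats::lm(y ~ x)
  list(r = unname(ct$estimate),
       ci_low = ct$conf.int[1], ci_high = ct$conf.int[2],
       p_value = ct$p.value,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = n,
       sigma = summary(fit)$sigma,
       mean_x = mean(x), ssx = sum((x - mean(x))^2))
}

# Empirical AUC by the rank (Mann-Whitney) statistic, with midrank ties.
auc_rank <- function(scores, positive) {
  r <- rank(scores, ties.method = "average")
  n1 <- sum(positive)
  n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# AUC by trapezoidal integration of the empirical ROC curve (independent
# route used by the oracle-equivalence tests).
auc_trapezoid <- function(scores, positive) {
  thr <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(c(Inf, thr), function(t) mean(scores[positive] >= t), 0)
  fpr <- vapply(c(Inf, thr), function(t) mean(scores[!positive] >= t), 0)
  sens <- c(sens, 1); fpr <- c(fpr, 1)
  sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
}

# DeLong variance of the empirical AUC via placement values.
delong_se <- function(scores, positive) {
  xs <- scores[positive]
  ys <- scores[!positive]
  m <- length(xs); n <- length(ys)
  v10 <- vapply(xs, function(x) (sum(x > ys) + 0.5 * sum(x == ys)) / n, 0)
  v01 <- vapply(ys, function(y) (sum(xs > y) + 0.5 * sum(xs == y)) / m, 0)
  s10 <- if (m > 1) stats::var(v10) else 0
  s01 <- if (n > 1) stats::var(v01) else 0
  sqrt(s10 / m + s01 / n)
}

#' ROC analysis with DeLong interval and Youden cutoff
#'
#' Empirical AUC by the rank statistic, a 95% DeLong confidence interval, a
#' DeLong z-test against the chance AUC of 0.5, and the cutoff maximizing
#' the Youden index `J = sensitivity + specificity - 1` (ties broken toward
#' higher sensitivity, then the lower threshold value). When
#' `positive_is_low` (the default, matching imaging scores that fall with
#' disease), a case is called positive when its score is at or below the
#' cutoff; the reported cutoff is the midpoint between the adjacent
#' observed score values.
#'
#' @param scores numeric scores.
#' @param labels logical (or 0/1) vector; `TRUE` = diseased/positive.
#' @param positive_is_low lower scores indicate the positive class.
#' @return list of class `roc_result`: `auc`, `ci_low`, `ci_high`,
#'   `p_value`, `cutoff`, `sensitivity_pct`, `specificity_pct`,
#'   `n_positive`, `n_negative`.
#' @export
roc_youden <- function(scores, labels, positive_is_low = TRUE) {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]
  positive <- as.logical(labels[ok])
  if (!any(positive) || all(positive))
    stop("roc_youden: both classes must be present")
  oriented <- if (positive_is_low) -scores else scores
  auc <- auc_rank(oriented, positive)
  se <- delong_se(oriented, positive)
  ci <- auc + c(-1, 1) * stats::qnorm(0.975) * se
  z <- if (se > 0) (auc - 0.5) / se else Inf * sign(auc - 0.5)
  p <- 2 * stats::pnorm(-abs(z))

  # Youden scan over midpoints between consecutive observed values
  sv <- sort(unique(scores))
  cand <- if (length(sv) > 1) (utils::head(sv, -1) + utils::tail(sv, -1)) / 2
          else sv
  cand <- c(sv[1] - 1, cand, sv[length(sv)] + 1)
  best <- NULL
  for (ct in cand) {
    called <- if (positive_is_low) scores <= ct else scores >= ct
    sens <- sum(called & positive) / sum(positive)
    spec <- sum(!called & !positive) / sum(!positive)
    j <- sens + spec - 1
    better <- is.null(best) || j > best$j + 1e-12 ||
      (abs(j - best$j) <= 1e-12 && sens > best$sens + 1e-12) ||
      (abs(j - best$j) <= 1e-12 && abs(sens - best$sens) <= 1e-12 && ct < best$cutoff)
    if (better) best <- list(cutoff = ct, j = j, sens = sens, spec = spec)
  }
  structure(list(
    auc = auc, ci_low = max(0, ci[1]), ci_high = min(1, ci[2]),
    p_value = p, cutoff = best$cutoff,
    sensitivity_pct = 100 * best$sens, specificity_pct = 100 * best$spec,
    n_positive = sum(positive), n_negative = sum(!positive)
  ), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (%.2f to %.2f), p = %.3g; cutoff %.4g, sens %.1f%%, spec %.1f%%\n",
              x$auc, x$ci_low, x$ci_high, x$p_value, x$cutoff,
              x$sensitivity_pct, x$specificity_pct))
  invisible(x)
}

#' Closed-form AUC of the binormal model
#'
#' `Phi(|mu1 - mu0| / sqrt(sd1^2 + sd0^2))`: the expected AUC when both
#' class score distributions are normal. Used as the analytic oracle for
#' distribution-level AUC reproduction.
#'
#' @param mu0,sd0 negative-class mean and SD.
#' @param mu1,sd1 positive-class mean and SD.
#' @export
binormal_auc <- function(mu0, sd0, mu1, sd1) {
  stats::pnorm(abs(mu1 - mu0) / sqrt(sd0^2 + sd1^2))
}

#' Full cohort report
#'
#' Reproduces the standard reporting battery on a scored cohort table:
#' whole-cohort and per-group summaries of MELIF and rrT1_liver, normality
#' tests, pairwise unpaired t-tests between MELD groups, Pearson
#' correlations of both scores against MELD, and ROC rows (normal vs
#' impaired only; the severe group is excluded from ROC as too small for a
#' stable estimate).
#'
#' @param cohort data frame with columns `id`, `meld`, `meld_group`,
#'   `melif`, `rrt1_mean_pct` (and optionally demographics).
#' @param out_dir when given, writes `report.json` plus CSV tables there.
#' @return list of class `cohort_report` with elements `overall`,
#'   `by_group`, `normality`, `pairwise_t`, `correlations`, `roc`,
#'   `notes`.
#' @export
cohort_report <- function(cohort, out_dir = NULL) {
  req <- c("id", "meld", "meld_group", "melif", "rrt1_mean_pct")
  if (!all(req %in% names(cohort)))
    stop("cohort_report: cohort must have columns ",
         paste(req, collapse = ", "))
  if (anyDuplicated(cohort$id)) stop("cohort_report: duplicate patient ids")
  if (nrow(cohort) < 1) stop("cohort_report: empty cohort")
  grp <- factor(cohort$meld_group, levels = c("normal", "impaired", "severe"))
  notes <- character(0)

  overall <- rbind(
    cbind(score = "melif", group_summary(cohort$melif)),
    cbind(score = "rrt1_mean_pct", group_summary(cohort$rrt1_mean_pct)),
    cbind(score = "meld", group_summary(cohort$meld))
  )
  by_group <- rbind(
    cbind(score = "melif", group_summary(cohort$melif, grp)),
    cbind(score = "rrt1_mean_pct", group_summary(cohort$rrt1_mean_pct, grp))
  )
  normality <- lapply(split(cohort$melif, grp), normality_test)

  present <- levels(droplevels(grp))
  pairwise_t <- list()
  if (length(present) >= 2) {
    for (score in c("melif", "rrt1_mean_pct")) {
      for (pr in utils::combn(present, 2, simplify = FALSE)) {
        a <- cohort[[score]][grp == pr[1]]
        b <- cohort[[score]][grp == pr[2]]
        if (length(a) >= 2 && length(b) >= 2) {
          tt <- ttest_unpaired(a, b)
          pairwise_t[[paste(score, pr[1], pr[2], sep = ":")]] <- tt
        }
      }
    }
  } else {
    notes <- c(notes, "pairwise t-tests omitted: fewer than two MELD groups present")
  }

  correlations <- NULL
  if (nrow(cohort) >= 3 && stats::sd(cohort$meld) > 0) {
    correlations <- list(
      melif_vs_meld = pearson_with_regression(cohort$meld, cohort$melif),
      rrt1_vs_meld = pearson_with_regression(cohort$meld, cohort$rrt1_mean_pct)
    )
  } else {
    notes <- c(notes, "correlations omitted: fewer than 3 patients or constant MELD")
  }

  roc <- NULL
  ni <- cohort$meld_group %in% c("normal", "impaired")
  sub <- cohort[ni, ]
  if (length(unique(sub$meld_group)) == 2) {
    lab <- sub$meld_group == "impaired"
    roc <- list(
      melif = roc_youden(sub$melif, lab, positive_is_low = TRUE),
      rrt1 = roc_youden(sub$rrt1_mean_pct, lab, positive_is_low = TRUE)
    )
  } else {
    notes <- c(notes, "ROC omitted: fewer than two MELD groups present")
  }

  rep <- structure(list(overall = overall, by_group = by_group,
                        normality = normality, pairwise_t = pairwise_t,
                        correlations = correlations, roc = roc,
                        n = nrow(cohort), notes = notes),
                   class = "cohort_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(overall, file.path(out_dir, "table1_overall.csv"),
                     row.names = FALSE)
    utils::write.csv(by_group, file.path(out_dir, "table2_by_group.csv"),
                     row.names = FALSE)
    if (!is.null(roc)) {
      roc_df <- do.call(rbind, lapply(names(roc), function(nm)
        data.frame(score = nm, auc = roc[[nm]]$auc,
                   ci_low = roc[[nm]]$ci_low, ci_high = roc[[nm]]$ci_high,
                   p = roc[[nm]]$p_value, cutoff = roc[[nm]]$cutoff,
                   sensitivity_pct = roc[[nm]]$sensitivity_pct,
                   specificity_pct = roc[[nm]]$specificity_pct)))
      utils::write.csv(roc_df, file.path(out_dir, "table3_roc.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(
      lapply(unclass(rep), function(x) if (is.data.frame(x)) x else x),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  }
  rep
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Cohort report: %d patients\n", x$n))
  print(x$by_group, row.names = FALSE)
  cat(sprintf("MELIF vs MELD: r = %.2f (%.2f to %.2f), p = %.3g\n",
              x$correlations$melif_vs_meld$r,
              x$correlations$melif_vs_meld$ci_low,
              x$correlations$melif_vs_meld$ci_high,
              x$correlations$melif_vs_meld$p_value))
  if (!is.null(x$roc)) {
    cat("ROC (normal vs impaired):\n  MELIF: "); print(x$roc$melif)
    cat("  rrT1:  "); print(x$roc$rrt1)
  }
  invisible(x)
}
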