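#' Test-retest reliability statistics
#'
#' For a variable measured on two occasions in the same subjects: intraclass
#' correlation (two-way, single measure), standard error of measurement
#' (SEM = SD of the test-retest differences / sqrt(2)), within-subject
#' coefficient of variation from log-transformed values, minimal difference
#' (MD = SEM x 1.96 x sqrt(2)), a paired t-test for bias between occasions,
#' and a heteroscedasticity check (correlation of subject means with absolute
#' differences).
#'
#' @name reliability
NULL

#' Single-measure intraclass correlation from two sessions
#'
#' Two-way (subjects x occasions) single-measure ICC. The consistency form
#' `(MS_subjects - MS_error) / (MS_subjects + (k-1) MS_error)` ignores a fixed
#' occasion offset; the agreement form additionally penalises it. Confidence
#' intervals use the F-based interval of the two-way formulation.
#'
#' @param test1,test2 Paired numeric vectors (same subjects, two occasions).
#' @param type `"consistency"` (default) or `"agreement"`.
#' @param conf_level Confidence level for the interval.
#' @return Tibble with `icc`, `icc_lo`, `icc_hi`.
#' @export
icc_consistency <- function(test1, test2, type = c("consistency", "agreement"),
                            conf_level = 0.95) {
  type <- match.arg(type)
  stopifnot(length(test1) == length(test2))
  ok <- is.finite(test1) & is.finite(test2)
  x <- cbind(test1[ok], test2[ok])
  n <- nrow(x); k <- 2
  if (n < 3L) stop("need at least 3 paired observations")
  gm <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ssr <- k * sum((row_m - gm)^2)
  ssc <- n * sum((col_m - gm)^2)
  sst <- sum((x - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr <= 0 || (msr == 0 && mse == 0)) warning("degenerate between-subject variance")
  a <- (1 - conf_level) / 2
  if (type == "consistency") {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
    fobs <- msr / mse
    fl <- fobs / stats::qf(1 - a, n - 1, (n - 1) * (k - 1))
    fu <- fobs * stats::qf(1 - a, (n - 1) * (k - 1), n - 1)
    lo <- (fl - 1) / (fl + k - 1)
    hi <- (fu - 1) / (fu + k - 1)
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    # McGraw & Wong (1996) interval for ICC(A,1)
    fj <- msc / mse
    vn <- (k - 1) * (n - 1) * ((k * icc * fj + n * (1 + (k - 1) * icc) - k * icc))^2
    vd <- (n - 1) * k^2 * icc^2 * fj^2 +
      (n * (1 + (k - 1) * icc) - k * icc)^2
    v <- vn / vd
    f1 <- stats::qf(1 - a, n - 1, v)
    f2 <- stats::qf(1 - a, v, n - 1)
    lo <- n * (msr - f1 * mse) /
      (f1 * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f2 * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f2 * msr)
  }
  tibble::tibble(icc = icc, icc_lo = lo, icc_hi = hi)
}

#' Standard error of measurement from test-retest differences
#'
#' `SEM = SD(test1 - test2) / sqrt(2)` (sample SD). The confidence interval is
#' the chi-square interval for a standard deviation with n - 1 degrees of
#' freedom.
#'
#' @inheritParams icc_consistency
#' @return Tibble with `sem`, `sem_lo`, `sem_hi`.
#' @export
sem_tr <- function(test1, test2, conf_level = 0.95) {
  stopifnot(length(test1) == length(test2), length(test1) >= 2L)
  d <- test1 - test2
  n <- length(d)
  s <- stats::sd(d) / sqrt(2)
  a <- (1 - conf_level) / 2
  lo <- s * sqrt((n - 1) / stats::qchisq(1 - a, n - 1))
  hi <- s * sqrt((n - 1) / stats::qchisq(a, n - 1))
  tibble::tibble(sem = s, sem_lo = lo, sem_hi = hi)
}

#' Within-subject coefficient of variation (percent)
#'
#' Same formula as the SEM applied to log-transformed values, back-transformed
#' to a percentage: `s = SD(ln test1 - ln test2) / sqrt(2)`,
#' `CV = 100 (e^s - 1)`.
#'
#' @inheritParams icc_consistency
#' @return Tibble with `cv_pct`, `cv_lo`, `cv_hi`.
#' @export
cv_tr <- function(test1, test2, conf_level = 0.95) {
  if (any(test1 <= 0 | test2 <= 0)) stop("CV requires strictly positive values")
  r <- sem_tr(log(test1), log(test2), conf_level = conf_level)
  tibble::tibble(
    cv_pct = 100 * (exp(r$sem) - 1),
    cv_lo = 100 * (exp(r$sem_lo) - 1),
    cv_hi = 100 * (exp(r$sem_hi) - 1)
  )
}

#' Minimal difference (smallest detectable change)
#'
#' `MD = SEM x 1.96 x sqrt(2)`: the smallest change that exceeds measurement
#' error with 95% confidence.
#'
#' @param sem_value Non-negative SEM.
#' @return MD on the scale of the measurement.
#' @export
md <- function(sem_value) {
  if (any(sem_value < 0)) stop("SEM must be non-negative")
  sem_value * 1.96 * sqrt(2)
}

#' Heteroscedasticity of test-retest error
#'
#' Correlation between the subject mean of the two occasions and the absolute
#' test-retest difference, with a two-sided p-value.
#'
#' @inheritParams icc_consistency
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Tibble with `het_r`, `het_p`.
#' @export
heteroscedasticity <- function(test1, test2, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(test1) == length(test2), length(test1) >= 3L)
  m <- (test1 + test2) / 2
  d <- abs(test1 - test2)
  if (stats::sd(m) == 0 || stats::sd(d) == 0) {
    warning("zero variance in means or absolute differences; correlation undefined")
    return(tibble::tibble(het_r = NA_real_, het_p = NA_real_))
  }
  ct <- suppressWarnings(stats::cor.test(m, d, method = method))
  tibble::tibble(het_r = unname(ct$estimate), het_p = ct$p.value)
}

#' Paired t-test for bias between occasions
#'
#' @inheritParams icc_consistency
#' @param log_transform Test on the log scale (for variables analysed after
#'   log-transformation).
#' @return Two-sided p-value.
#' @export
bias_test <- function(test1, test2, log_transform = FALSE) {
  stopifnot(length(test1) == length(test2), length(test1) >= 2L)
  if (log_transform) {
    test1 <- log(test1); test2 <- log(test2)
  }
  d <- test1 - test2
  scale <- max(abs(d), 1)
  if (stats::sd(d) <= 1e-12 * scale) {
    # (numerically) constant differences: exact equality is perfect
    # agreement, a constant non-zero shift is bias with certainty
    return(if (all(abs(d) <= 1e-12 * scale)) 1 else 0)
  }
  stats::t.test(test1, test2, paired = TRUE)$p.value
}

#' Full reliability report for one variable in one group
#'
#' Decides whether to log-transform (heteroscedasticity p < 0.05 or pooled
#' |skewness| > 1), then assembles ICC (on transformed values when flagged),
#' SEM, CV, MD, bias and heteroscedasticity statistics.
#'
#' @param metrics Subject-level metrics tibble with `subject_id`, `session`
#'   (`test1`/`test2`), `group`, and the variable column.
#' @param variable Name of the variable column.
#' @param group Optional group (`"NS"`/`"CON"`) to restrict to.
#' @param icc_type,het_method Passed through to [icc_consistency()] /
#'   [heteroscedasticity()].
#' @return One-row tibble with all reliability statistics, `n`, and
#'   `log_transformed`.
#' @export
reliability_report <- function(metrics, variable, group = NULL,
                               icc_type = "consistency", het_method = "pearson") {
  df <- metrics
  if (!is.null(group)) df <- dplyr::filter(df, .data$group == !!group)
  wide <- df |>
    dplyr::select("subject_id", "session", dplyr::all_of(variable)) |>
    tidyr::pivot_wider(names_from = "session", values_from = dplyr::all_of(variable))
  if (!all(c("test1", "test2") %in% names(wide))) {
    stop("need sessions test1 and test2 for a reliability report")
  }
  wide <- wide[stats::complete.cases(wide[, c("test1", "test2")]), ]
  if (nrow(wide) < 3L) stop("pairing error: fewer than 3 complete subject pairs")
  x1 <- wide$test1; x2 <- wide$test2
  het <- heteroscedasticity(x1, x2, method = het_method)
  skew <- skewness_g1(c(x1, x2))
  use_log <- (is.finite(het$het_p) && het$het_p < 0.05) || abs(skew) > 1
  icc <- if (use_log && all(c(x1, x2) > 0)) {
    icc_consistency(log(x1), log(x2), type = icc_type)
  } else {
    icc_consistency(x1, x2, type = icc_type)
  }
  s <- sem_tr(x1, x2)
  cv <- cv_tr(x1, x2)
  tibble::tibble(
    variable = variable,
    group = group %||% "all",
    n = nrow(wide),
    test1_mean = mean(x1), test1_sd = stats::sd(x1),
    test2_mean = mean(x2), test2_sd = stats::sd(x2),
    icc, s,
    md = md(s$sem),
    cv,
    bias_p = bias_test(x1, x2, log_transform = use_log && all(c(x1, x2) > 0)),
    het,
    skewness = skew,
    log_transformed = use_log
  )
}

#' Reliability table across variables and groups
#'
#' @inheritParams reliability_report
#' @param variables Character vector of variable columns.
#' @param groups Character vector of groups.
#' @return Tibble with one row per variable x group.
#' @export
reliability_table <- function(metrics,
                              variables = c("peak_speed_deg_s", "rom_deg", "npa",
                                            "ad_ratio", "sid_pct", "cm"),
                              groups = c("CON", "NS"), ...) {
  purrr::map_dfr(variables, function(v) {
    purrr::map_dfr(groups, function(g) reliability_report(metrics, v, group = g, ...))
  })
}
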