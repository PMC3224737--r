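#' Group comparison and discriminant classification
#'
#' Machinery for comparing neck-pain (NS) and control (CON) cohorts on the
#' kinematic variables: age adjustment by pooled linear regression,
#' independent-samples t-tests, Fisher linear discriminant analysis with
#' leave-one-out cross-validation, and forward-stepwise variable selection by
#' Wilks' lambda partial F.
#'
#' @name group-analysis
NULL

#' Age-adjust a variable by pooled linear regression
#'
#' Residuals of an ordinary least-squares fit of the variable on age,
#' computed on the pooled sample (both groups together).
#'
#' @param values Numeric vector.
#' @param ages Numeric vector of the same length.
#' @return Residual vector.
#' @export
age_adjust <- function(values, ages) {
  stopifnot(length(values) == length(ages), length(values) >= 3L)
  if (stats::sd(ages) == 0) stop("constant age: regression rank-deficient")
  stats::resid(stats::lm(values ~ ages))
}

# Variables the analysis age-adjusts (those correlated with age).
.age_adjusted_vars <- c("peak_speed_deg_s", "rom_deg", "npa")

#' Independent-samples comparison of NS and CON
#'
#' Pooled-variance two-sided t-test on raw values, or on age residuals for
#' the variables correlated with age (Peak Speed, ROM, NPA by default).
#'
#' @param ft Feature table: tibble with `group` (`NS`/`CON`), `age_years`,
#'   and the variable column (one row per subject).
#' @param variable Variable column name.
#' @param adjust_for_age Adjust via [age_adjust()] before testing. Default:
#'   only for the age-correlated variables.
#' @return One-row tibble: group means and SDs (raw scale), `t`, `df`, `p`,
#'   `age_adjusted`.
#' @export
compare_groups <- function(ft, variable,
                           adjust_for_age = variable %in% .age_adjusted_vars) {
  stopifnot(all(c("group", variable) %in% names(ft)))
  ft <- ft[is.finite(ft[[variable]]) & ft$group %in% c("NS", "CON"), ]
  y <- ft[[variable]]
  g <- factor(ft$group, levels = c("NS", "CON"))
  if (min(table(g)) < 2L) stop("both groups need at least 2 subjects")
  yt <- if (adjust_for_age) age_adjust(y, ft$age_years) else y
  if (stats::sd(yt) == 0) stop("degenerate: zero pooled variance")
  tt <- stats::t.test(yt[g == "NS"], yt[g == "CON"], var.equal = TRUE)
  tibble::tibble(
    variable = variable,
    ns_mean = mean(y[g == "NS"]), ns_sd = stats::sd(y[g == "NS"]),
    ns_n = sum(g == "NS"),
    con_mean = mean(y[g == "CON"]), con_sd = stats::sd(y[g == "CON"]),
    con_n = sum(g == "CON"),
    t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
    age_adjusted = adjust_for_age
  )
}

# Assemble the (possibly age-adjusted) feature matrix for LDA.
lda_design <- function(ft, variables, adjust_for_age) {
  X <- sapply(variables, function(v) {
    if (adjust_for_age && v %in% .age_adjusted_vars) {
      age_adjust(ft[[v]], ft$age_years)
    } else {
      ft[[v]]
    }
  })
  X <- as.matrix(X)
  colnames(X) <- variables
  X
}

#' Linear discriminant analysis with leave-one-out cross-validation
#'
#' Fisher LDA with pooled within-group covariance and equal priors.
#' Sensitivity is the proportion of NS subjects classified NS under
#' leave-one-out; specificity the proportion of CON classified CON.
#' Standardized discriminant coefficients (raw coefficients scaled by the
#' pooled within-group SD of each variable) and per-variable one-way F
#' statistics are reported.
#'
#' @param ft Feature table (see [compare_groups()]); complete cases only.
#' @param variables Character vector of feature columns.
#' @param prior Class prior probabilities `c(NS, CON)`.
#' @param adjust_for_age Age-adjust the age-correlated variables first.
#' @return A `discriminant_result` object (see [tidy.discriminant_result()]).
#' @export
lda_loo <- function(ft, variables, prior = c(0.5, 0.5), adjust_for_age = TRUE) {
  stopifnot(length(variables) >= 1L, all(variables %in% names(ft)))
  keep <- stats::complete.cases(ft[, c("group", variables)]) & ft$group %in% c("NS", "CON")
  ft <- ft[keep, ]
  g <- factor(ft$group, levels = c("NS", "CON"))
  if (min(table(g)) <= length(variables) + 1L) {
    stop("need more subjects per group than variables + 1")
  }
  X <- lda_design(ft, variables, adjust_for_age)
  # pooled within-group covariance; reject collinear feature sets up front
  Xc <- X
  for (lev in levels(g)) {
    Xc[g == lev, ] <- scale(X[g == lev, , drop = FALSE], scale = FALSE)
  }
  Sw <- crossprod(Xc) / (nrow(X) - 2L)
  if (length(variables) > 1L && kappa(Sw, exact = TRUE) > 1e10) {
    stop("singular pooled covariance (collinear variables): ",
         paste(variables, collapse = ", "))
  }
  fit <- MASS::lda(X, grouping = g, prior = prior)
  loo <- MASS::lda(X, grouping = g, prior = prior, CV = TRUE)$class
  sens <- mean(loo[g == "NS"] == "NS")
  spec <- mean(loo[g == "CON"] == "CON")
  std_coef <- fit$scaling[, 1L] * sqrt(diag(Sw))
  f_per_var <- vapply(variables, function(v) {
    summary(stats::aov(X[, v] ~ g))[[1L]]$`F value`[1L]
  }, numeric(1L))
  structure(
    list(
      variables = variables, coefficients = fit$scaling[, 1L],
      std_coefficients = std_coef, sensitivity = sens, specificity = spec,
      f_per_variable = f_per_var, n_ns = sum(g == "NS"), n_con = sum(g == "CON"),
      prior = prior, fit = fit
    ),
    class = "discriminant_result"
  )
}

# Wilks' lambda for a feature subset: det(W) / det(T).
wilks_lambda <- function(X, g) {
  if (ncol(X) == 0L) return(1)
  Tm <- crossprod(scale(X, scale = FALSE))
  W <- matrix(0, ncol(X), ncol(X))
  for (lev in levels(g)) {
    W <- W + crossprod(scale(X[g == lev, , drop = FALSE], scale = FALSE))
  }
  det(W) / det(Tm)
}

#' Stepwise linear discriminant analysis (Wilks' lambda)
#'
#' Forward selection with backward removal: at each step the candidate
#' maximising the partial F for entry (change in Wilks' lambda) enters if its
#' F exceeds `f_enter`; previously entered variables with partial removal F
#' below `f_remove` are dropped. The final subset is refit and evaluated with
#' [lda_loo()].
#'
#' @inheritParams lda_loo
#' @param f_enter,f_remove Partial-F thresholds for entry and removal.
#' @return A `discriminant_result` for the selected subset; an empty-model
#'   result (no variables, NA sensitivity) if nothing passes `f_enter`.
#' @export
stepwise_lda <- function(ft, variables, f_enter = 3.84, f_remove = 2.71,
                         prior = c(0.5, 0.5), adjust_for_age = TRUE) {
  keep <- stats::complete.cases(ft[, c("group", variables)]) & ft$group %in% c("NS", "CON")
  ft <- ft[keep, ]
  g <- factor(ft$group, levels = c("NS", "CON"))
  X <- lda_design(ft, variables, adjust_for_age)
  n <- nrow(X); ngrp <- 2L
  partial_f <- function(lam_small, lam_big, p_small) {
    # F for the change small -> small+1 variables
    (n - ngrp - p_small) / (ngrp - 1) * (lam_small / lam_big - 1)
  }
  selected <- character(0)
  repeat {
    changed <- FALSE
    lam_cur <- wilks_lambda(X[, selected, drop = FALSE], g)
    # entry
    cand <- setdiff(variables, selected)
    if (length(cand) > 0L) {
      fs <- vapply(cand, function(v) {
        lam_new <- wilks_lambda(X[, c(selected, v), drop = FALSE], g)
        if (!is.finite(lam_new) || lam_new <= 0) return(0)
        partial_f(lam_cur, lam_new, length(selected))
      }, numeric(1L))
      if (max(fs) > f_enter) {
        selected <- c(selected, cand[which.max(fs)])
        changed <- TRUE
      }
    }
    # removal
    if (length(selected) > 1L) {
      lam_full <- wilks_lambda(X[, selected, drop = FALSE], g)
      fr <- vapply(selected, function(v) {
        rest <- setdiff(selected, v)
        lam_rest <- wilks_lambda(X[, rest, drop = FALSE], g)
        partial_f(lam_rest, lam_full, length(rest))
      }, numeric(1L))
      if (min(fr) < f_remove) {
        selected <- setdiff(selected, selected[which.min(fr)])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (length(selected) == 0L) {
    return(structure(
      list(
        variables = character(0), coefficients = numeric(0),
        std_coefficients = numeric(0), sensitivity = NA_real_,
        specificity = NA_real_, f_per_variable = numeric(0),
        n_ns = sum(g == "NS"), n_con = sum(g == "CON"), prior = prior, fit = NULL
      ),
      class = "discriminant_result"
    ))
  }
  res <- lda_loo(ft, selected, prior = prior, adjust_for_age = adjust_for_age)
  # report selection-order partial F of the final subset
  res$selection_order <- selected
  res
}

#' Peak-speed comparison of low-back-pain subgroups within NS
#'
#' Compares NS subjects with concurrent low-back pain against NS subjects
#' without, and NS-without-LBP against CON.
#'
#' @param ft Feature table with `group`, `low_back_pain` (logical, required
#'   for all NS rows) and the variable column.
#' @param variable Variable to compare (default peak speed).
#' @return Tibble with one row per contrast: subgroup means, SDs, n, t, p.
#' @export
subgroup_compare <- function(ft, variable = "peak_speed_deg_s") {
  ns <- ft[ft$group == "NS", ]
  if (any(is.na(ns$low_back_pain))) stop("low_back_pain flag required for all NS subjects")
  lbp <- ns[[variable]][ns$low_back_pain]
  nolbp <- ns[[variable]][!ns$low_back_pain]
  con <- ft[[variable]][ft$group == "CON"]
  if (length(lbp) < 2L || length(nolbp) < 2L) stop("subgroup error: too few subjects")
  t1 <- stats::t.test(lbp, nolbp, var.equal = TRUE)
  t2 <- stats::t.test(nolbp, con, var.equal = TRUE)
  tibble::tibble(
    contrast = c("NS+LBP vs NS-LBP", "NS-LBP vs CON"),
    mean_a = c(mean(lbp), mean(nolbp)), sd_a = c(stats::sd(lbp), stats::sd(nolbp)),
    n_a = c(length(lbp), length(nolbp)),
    mean_b = c(mean(nolbp), mean(con)), sd_b = c(stats::sd(nolbp), stats::sd(con)),
    n_b = c(length(nolbp), length(con)),
    t = c(unname(t1$statistic), unname(t2$statistic)),
    p = c(t1$p.value, t2$p.value)
  )
}

#' @export
print.discriminant_result <- function(x, ...) {
  if (length(x$variables) == 0L) {
    cat("<discriminant_result> empty model (no variable passed the entry threshold)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<discriminant_result> %s | sensitivity %.1f%%, specificity %.1f%% (leave-one-out, n = %d NS / %d CON)\n",
    paste(x$variables, collapse = " + "),
    100 * x$sensitivity, 100 * x$specificity, x$n_ns, x$n_con
  ))
  invisible(x)
}

#' Tidy a discriminant result
#'
#' @param x A `discriminant_result`.
#' @param ... Unused.
#' @return Tibble with one row per selected variable: raw and standardized
#'   coefficients and per-variable F.
#' @method tidy discriminant_result
#' @export
tidy.discriminant_result <- function(x, ...) {
  tibble::tibble(
    variable = x$variables,
    coefficient = unname(x$coefficients),
    std_coefficient = unname(x$std_coefficients),
    f = unname(x$f_per_variable)
  )
}

#' Model-level summary of a discriminant result
#'
#' @param x A `discriminant_result`.
#' @param ... Unused.
#' @return One-row tibble: sensitivity, specificity, group sizes.
#' @method glance discriminant_result
#' @export
glance.discriminant_result <- function(x, ...) {
  tibble::tibble(
    n_variables = length(x$variables),
    sensitivity = x$sensitivity, specificity = x$specificity,
    n_ns = x$n_ns, n_con = x$n_con
  )
}
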