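#' Orthogonal partial least squares (O-PLS) association modelling
#'
#' Regression of a single response (peak speed) on a wide block of
#' questionnaire predictors. Predictor variation orthogonal to the response is
#' removed first (orthogonal components), then a one-component PLS model is
#' fitted. The model is summarised by R2Y (explained variation), Q2
#' (cross-validated predicted variation) and per-predictor VIP values
#' (variable importance in the projection); a model is called significant when
#' Q2 > 0.05, and a predictor when VIP > 1 with a confidence interval whose
#' lower bound stays above 0.5. Missing predictor cells are handled by the
#' iterative-weights convention (dot products over present cells only).
#'
#' @name opls
NULL

# Column projection with NA handling: w_j = sum_i X_ij u_i / sum_i u_i^2
# over present cells.
na_proj_cols <- function(X, u) {
  P <- !is.na(X)
  Xz <- X
  Xz[!P] <- 0
  num <- crossprod(Xz, u)
  den <- crossprod(P, u^2)
  as.numeric(num / pmax(den, .Machine$double.eps))
}

# Row projection: t_i = sum_j X_ij w_j / sum_j w_j^2 over present cells.
na_proj_rows <- function(X, w) {
  P <- !is.na(X)
  Xz <- X
  Xz[!P] <- 0
  num <- Xz %*% w
  den <- P %*% (w^2)
  as.numeric(num / pmax(den, .Machine$double.eps))
}

# Core O-PLS fit on already-scaled data. Returns weights/loadings needed for
# prediction.
opls_core <- function(X, y, n_ortho) {
  w <- na_proj_cols(X, y)
  w <- w / sqrt(sum(w^2))
  w_ortho <- list(); p_ortho <- list(); t_ortho <- list()
  Xf <- X
  for (a in seq_len(n_ortho)) {
    tt <- na_proj_rows(Xf, w)
    p <- na_proj_cols(Xf, tt)
    wo <- p - sum(w * p) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-10) break
    wo <- wo / nwo
    to <- na_proj_rows(Xf, wo)
    po <- na_proj_cols(Xf, to)
    upd <- tcrossprod(to, po)
    Xf <- Xf - ifelse(is.na(Xf), NA, upd)
    w_ortho[[a]] <- wo; p_ortho[[a]] <- po; t_ortho[[a]] <- to
  }
  t_pred <- na_proj_rows(Xf, w)
  cc <- sum(t_pred * y) / sum(t_pred^2)
  p_pred <- na_proj_cols(Xf, t_pred)
  list(w = w, c = cc, p = p_pred, w_ortho = w_ortho, p_ortho = p_ortho,
       t = t_pred, t_ortho = t_ortho)
}

# Predict scaled y for new scaled rows.
opls_predict_core <- function(core, Xnew) {
  Xf <- Xnew
  for (a in seq_along(core$w_ortho)) {
    to <- na_proj_rows(Xf, core$w_ortho[[a]])
    upd <- tcrossprod(to, core$p_ortho[[a]])
    Xf <- Xf - ifelse(is.na(Xf), NA, upd)
  }
  core$c * na_proj_rows(Xf, core$w)
}

vip_from_weights <- function(w) sqrt(length(w)) * abs(w) / sqrt(sum(w^2))

#' Fit an O-PLS model
#'
#' Columns are mean-centred and scaled to unit variance (the response is
#' centred and scaled too; R2Y and Q2 are scale-free). Q2 = 1 - PRESS/SS(y)
#' from fold-wise refits with a seeded fold assignment; VIP confidence
#' intervals are jack-knife intervals over the fold-deleted refits.
#'
#' @param X Numeric matrix or data frame of predictors (n x p, NAs allowed).
#' @param y Numeric response of length n (no NAs).
#' @param n_ortho Number of orthogonal components to remove (default 1).
#' @param cv_folds Number of cross-validation folds (default 7).
#' @param seed Integer seed for the fold assignment.
#' @param conf_level Level of the jack-knife VIP intervals.
#' @return An `opls_model`; see [tidy.opls_model()] and [glance.opls_model()].
#' @export
fit_opls <- function(X, y, n_ortho = 1, cv_folds = 7, seed = 1, conf_level = 0.95) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, p >= 1L, all(is.finite(y)))
  if (n < cv_folds) stop("need at least as many observations as CV folds")
  mu <- colMeans(X, na.rm = TRUE)
  sdev <- apply(X, 2L, stats::sd, na.rm = TRUE)
  if (any(!is.finite(sdev)) || any(sdev == 0)) {
    bad <- colnames(X)[which(!is.finite(sdev) | sdev == 0)]
    stop("constant or empty predictor column(s): ", paste(bad, collapse = ", "))
  }
  Xs <- sweep(sweep(X, 2L, mu), 2L, sdev, "/")
  y_mu <- mean(y); y_sd <- stats::sd(y)
  if (y_sd == 0) stop("constant response")
  ys <- (y - y_mu) / y_sd
  core <- opls_core(Xs, ys, n_ortho)
  yhat <- core$c * core$t
  r2y <- 1 - sum((ys - yhat)^2) / sum(ys^2)
  # seeded fold assignment
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  folds <- sample(rep(seq_len(cv_folds), length.out = n))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  press <- 0
  vip_folds <- matrix(NA_real_, cv_folds, p)
  for (f in seq_len(cv_folds)) {
    tr <- folds != f
    core_f <- opls_core(Xs[tr, , drop = FALSE], ys[tr], n_ortho)
    pred <- opls_predict_core(core_f, Xs[!tr, , drop = FALSE])
    press <- press + sum((ys[!tr] - pred)^2)
    vip_folds[f, ] <- vip_from_weights(core_f$w)
  }
  q2 <- 1 - press / sum(ys^2)
  vip <- vip_from_weights(core$w)
  # jack-knife SE over fold-deleted fits, centred on the full-model VIP
  vbar <- colMeans(vip_folds)
  se <- sqrt((cv_folds - 1) / cv_folds * colSums(sweep(vip_folds, 2L, vbar)^2))
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, cv_folds - 1L)
  structure(
    list(
      predictor_names = colnames(X),
      w = stats::setNames(core$w, colnames(X)), p = core$p, c = core$c,
      w_ortho = core$w_ortho, p_ortho = core$p_ortho,
      t_scores = core$t, t_ortho_scores = core$t_ortho,
      r2y = r2y, q2 = q2,
      vip = stats::setNames(vip, colnames(X)),
      vip_lo = stats::setNames(vip - tcrit * se, colnames(X)),
      vip_hi = stats::setNames(vip + tcrit * se, colnames(X)),
      n_ortho = length(core$w_ortho), cv_folds = cv_folds, seed = seed,
      n = n, p_dim = p,
      scaling = list(x_center = mu, x_scale = sdev, y_center = y_mu, y_scale = y_sd)
    ),
    class = "opls_model"
  )
}

#' VIP values of a fitted O-PLS model
#'
#' For a one-predictive-component model `VIP_j = sqrt(p) |w_j| / ||w||`; the
#' mean squared VIP over predictors is exactly 1.
#'
#' @param model A fitted `opls_model`.
#' @return Tibble with `predictor`, `vip`, `vip_lo`, `vip_hi`.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "opls_model"))
  if (sum(model$w^2) < 1e-24) stop("degenerate model: zero explained sum of squares")
  tibble::tibble(
    predictor = model$predictor_names,
    vip = unname(model$vip),
    vip_lo = unname(model$vip_lo),
    vip_hi = unname(model$vip_hi)
  )
}

#' Significant predictors of an O-PLS model
#'
#' Empty when the model itself is not significant (Q2 <= 0.05); otherwise the
#' predictors with VIP > 1 whose confidence interval stays above 0.5, in
#' descending VIP order.
#'
#' @param model A fitted `opls_model`.
#' @param q2_min Model significance threshold on Q2.
#' @param vip_min VIP threshold.
#' @param ci_floor Lower-bound requirement on the VIP interval.
#' @return Tibble of significant predictors (possibly zero rows).
#' @export
significant_predictors <- function(model, q2_min = 0.05, vip_min = 1, ci_floor = 0.5) {
  stopifnot(inherits(model, "opls_model"))
  v <- vip(model)
  if (model$q2 <= q2_min) return(v[0, ])
  v |>
    dplyr::filter(.data$vip > vip_min, .data$vip_lo > ci_floor) |>
    dplyr::arrange(dplyr::desc(.data$vip))
}

#' Fit the peak-speed association model from analysis tables
#'
#' Convenience wrapper: assembles the predictor block from a subject-level
#' table, log-transforms skewed strictly-positive predictors and response
#' (|skewness| > 1), and fits [fit_opls()].
#'
#' @param data Subject-level tibble holding response and predictors.
#' @param response Response column name (default `peak_speed_deg_s`).
#' @param predictors Character vector of predictor columns.
#' @param ... Passed to [fit_opls()].
#' @return An `opls_model`; the applied log-transforms are recorded in
#'   `$log_transformed`.
#' @export
opls_association <- function(data, response = "peak_speed_deg_s", predictors, ...) {
  stopifnot(all(c(response, predictors) %in% names(data)))
  X <- as.matrix(data[, predictors])
  y <- data[[response]]
  logged <- character(0)
  for (j in seq_len(ncol(X))) {
    xj <- X[, j]
    if (all(xj > 0, na.rm = TRUE) && isTRUE(abs(skewness_g1(xj)) > 1)) {
      X[, j] <- log(xj)
      logged <- c(logged, predictors[j])
    }
  }
  if (all(y > 0) && isTRUE(abs(skewness_g1(y)) > 1)) {
    y <- log(y)
    logged <- c(logged, response)
  }
  m <- fit_opls(X, y, ...)
  m$log_transformed <- logged
  m
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf(
    "<opls_model> n = %d, p = %d | %d orthogonal component(s) | R2Y = %.3f, Q2 = %.3f\n",
    x$n, x$p_dim, x$n_ortho, x$r2y, x$q2
  ))
  invisible(x)
}

#' Tidy an O-PLS model
#'
#' @param x An `opls_model`.
#' @param ... Unused.
#' @return Tibble with one row per predictor: weight, VIP and its interval,
#'   and the significance flag of [significant_predictors()].
#' @method tidy opls_model
#' @export
tidy.opls_model <- function(x, ...) {
  sig <- significant_predictors(x)
  vip(x) |>
    dplyr::mutate(
      weight = unname(x$w),
      significant = .data$predictor %in% sig$predictor
    ) |>
    dplyr::arrange(dplyr::desc(.data$vip))
}

#' Model-level summary of an O-PLS model
#'
#' @param x An `opls_model`.
#' @param ... Unused.
#' @return One-row tibble: `r2y`, `q2`, `n_ortho`, `n`, `p`, `significant`.
#' @method glance opls_model
#' @export
glance.opls_model <- function(x, ...) {
  tibble::tibble(
    r2y = x$r2y, q2 = x$q2, n_ortho = x$n_ortho,
    n = x$n, p = x$p_dim, significant = x$q2 > 0.05
  )
}
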