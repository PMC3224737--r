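test_that("O-PLS recovers a noiseless single-predictor response", {
  set.seed(3)
  X <- matrix(rnorm(100 * 10), 100)
  colnames(X) <- paste0("p", 1:10)
  y <- 2 * X[, 3]
  m <- fit_opls(X, y, n_ortho = 2, seed = 5)
  expect_gt(m$r2y, 0.999)
  expect_gt(m$q2, 0.95)
  sig <- significant_predictors(m)
  expect_equal(sig$predictor[1], "p3")
})

test_that("R2Y is invariant to joint row permutation and bounded by construction", {
  set.seed(4)
  X <- matrix(rnorm(60 * 8), 60)
  y <- X[, 1] + rnorm(60)
  m <- fit_opls(X, y, seed = 1)
  ord <- sample(60)
  m_p <- fit_opls(X[ord, ], y[ord], seed = 1)
  expect_equal(m_p$r2y, m$r2y, tolerance = 1e-12)
  expect_gte(m$r2y, 0)
  expect_lte(m$r2y, 1)
  expect_lte(m$q2, m$r2y + 1e-9)
})

test_that("VIP normalisation identities hold", {
  set.seed(5)
  X <- matrix(rnorm(80 * 7), 80)
  y <- rnorm(80)
  m <- fit_opls(X, y, seed = 2)
  expect_equal(mean(m$vip^2), 1, tolerance = 1e-9)

  # single predictor: VIP exactly one
  m1 <- fit_opls(matrix(rnorm(50), 50, 1), rnorm(50), seed = 3)
  expect_equal(unname(m1$vip), 1, tolerance = 1e-12)

  # duplicated predictors contribute equally
  x <- rnorm(60)
  X2 <- cbind(a = x, b = x, c = rnorm(60))
  m2 <- fit_opls(X2, x + rnorm(60, 0, 0.2), seed = 4)
  expect_equal(unname(m2$vip["a"]), unname(m2$vip["b"]), tolerance = 1e-9)

  # VIP ordering is unchanged by predictor rescaling (unit-variance scaling)
  set.seed(6)
  X3 <- matrix(rnorm(70 * 6), 70)
  y3 <- X3[, 2] + rnorm(70)
  m3a <- fit_opls(X3, y3, seed = 7)
  m3b <- fit_opls(sweep(X3, 2, c(1, 100, 0.01, 5, 2, 7), "*"), y3, seed = 7)
  expect_equal(unname(m3b$vip), unname(m3a$vip), tolerance = 1e-9)
})

test_that("orthogonal correction never hurts the training-score correlation", {
  set.seed(8)
  for (i in 1:10) {
    X <- matrix(rnorm(60 * 12), 60)
    y <- X %*% rnorm(12, 0, 0.4) + rnorm(60)
    ys <- as.numeric(scale(y))
    Xs <- scale(X)
    m0 <- cervkin:::opls_core(Xs, ys, n_ortho = 0)
    m1 <- cervkin:::opls_core(Xs, ys, n_ortho = 1)
    expect_gte(abs(cor(m1$t, ys)), abs(cor(m0$t, ys)) - 1e-9)
  }
})

test_that("the model-significance rule silences null models", {
  set.seed(9)
  q2s <- vapply(1:10, function(i) {
    X <- matrix(rnorm(100 * 44), 100)
    m <- fit_opls(X, rnorm(100), seed = i)
    expect_equal(nrow(significant_predictors(m)), 0L)
    m$q2
  }, numeric(1))
  expect_lte(median(q2s), 0.05)
})

test_that("exactly the strong predictors are selected on a clean block", {
  hits <- vapply(1:25, function(s) {
    set.seed(s)
    n <- 200
    zp <- rnorm(n)
    X <- sapply(1:10, function(j) {
      if (j <= 3) {
        e <- as.numeric(scale(resid(lm(rnorm(n) ~ zp))))
        0.5 * as.numeric(scale(zp)) + sqrt(1 - 0.25) * e
      } else {
        rnorm(n)
      }
    })
    colnames(X) <- paste0("p", 1:10)
    m <- fit_opls(X, zp, seed = s)
    setequal(significant_predictors(m)$predictor, paste0("p", 1:3))
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("weak predictors with intervals reaching below 0.5 are excluded", {
  set.seed(12)
  n <- 150
  zp <- rnorm(n)
  X <- cbind(
    strong = 0.6 * zp + 0.8 * rnorm(n),
    weak = 0.15 * zp + 0.99 * rnorm(n),
    n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n)
  )
  m <- fit_opls(X, zp, seed = 12)
  v <- vip(m)
  sig <- significant_predictors(m)
  excluded <- v[!(v$vip > 1 & v$vip_lo > 0.5), ]
  expect_true(!any(excluded$predictor %in% sig$predictor))
  expect_true("strong" %in% sig$predictor || m$q2 <= 0.05)
})

test_that("missing predictor cells are tolerated", {
  set.seed(13)
  X <- matrix(rnorm(90 * 12), 90)
  colnames(X) <- paste0("p", 1:12)
  y <- X[, 1] + rnorm(90, 0, 0.5)
  X[sample(length(X), 50)] <- NA
  m <- fit_opls(X, y, seed = 13)
  expect_true(is.finite(m$r2y) && is.finite(m$q2))
  expect_gt(m$r2y, 0.2)
  expect_equal(significant_predictors(m)$predictor[1], "p1")
})

test_that("constant columns and undersized samples are rejected", {
  X <- cbind(a = rnorm(20), b = rep(3, 20))
  expect_error(fit_opls(X, rnorm(20), seed = 1), "\\bb\\b")
  expect_error(fit_opls(matrix(rnorm(10), 5, 2), rnorm(5), cv_folds = 7, seed = 1),
               "folds")
})

test_that("one-component PLS weights agree with an established PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(21)
  X <- matrix(rnorm(80 * 6), 80)
  colnames(X) <- paste0("p", 1:6)
  y <- X[, 2] - 0.5 * X[, 5] + rnorm(80, 0, 0.5)
  # no orthogonal components: the predictive weight is the PLS1 weight
  m <- fit_opls(X, y, n_ortho = 0, seed = 1)
  ref <- mixOmics::pls(X, y, ncomp = 1, mode = "regression")
  w_ref <- ref$loadings$X[, 1]
  w_ref <- w_ref / sqrt(sum(w_ref^2))
  agree <- abs(sum(w_ref * m$w))
  expect_gt(agree, 0.999)
})

test_that("association wrapper applies the skewness log rule", {
  set.seed(22)
  n <- 120
  d <- tibble::tibble(
    peak_speed_deg_s = rnorm(n, 250, 60),
    skewed = exp(rnorm(n, 1, 0.9)),
    plain = rnorm(n, 10, 2)
  )
  m <- opls_association(d, predictors = c("skewed", "plain"), seed = 2)
  expect_true("skewed" %in% m$log_transformed)
  expect_false("plain" %in% m$log_transformed)
})

test_that("tidy and glance expose the model summary", {
  set.seed(23)
  X <- matrix(rnorm(60 * 5), 60)
  colnames(X) <- paste0("p", 1:5)
  m <- fit_opls(X, X[, 1] + rnorm(60), seed = 3)
  td <- tidy(m)
  expect_named(td, c("predictor", "vip", "vip_lo", "vip_hi", "weight", "significant"))
  expect_equal(td$predictor[1], names(sort(m$vip, decreasing = TRUE))[1])
  gl <- glance(m)
  expect_named(gl, c("r2y", "q2", "n_ortho", "n", "p", "significant"))
})
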