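# metric-level feature table for the discrimination machinery
sim_feature_table <- function(n_ns = 118, n_con = 49, ns_mean = 226, con_mean = 348,
                              ns_sd = 88, con_sd = 92, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    subject_id = c(sprintf("ns%d", 1:n_ns), sprintf("con%d", 1:n_con)),
    group = rep(c("NS", "CON"), c(n_ns, n_con)),
    age_years = c(rnorm(n_ns, 50, 9), rnorm(n_con, 46, 10)),
    peak_speed_deg_s = c(rnorm(n_ns, ns_mean, ns_sd), rnorm(n_con, con_mean, con_sd)),
    low_back_pain = c(runif(n_ns) < 0.5, rep(NA, n_con))
  )
}

test_that("age adjustment leaves residuals orthogonal to age and matches OLS", {
  set.seed(6)
  age <- runif(50, 25, 65)
  y <- 2 * age + rnorm(50, 0, 5)
  r <- age_adjust(y, age)
  expect_lt(abs(cor(r, age)), 1e-12)
  # normal-equations oracle
  X <- cbind(1, age)
  beta <- solve(crossprod(X), crossprod(X, y))
  expect_equal(r, as.numeric(y - X %*% beta), ignore_attr = TRUE, tolerance = 1e-10)
  # uncorrelated values: residuals ~ centered values
  y2 <- rnorm(50, 100, 1e-6) + 0 * age
  expect_equal(age_adjust(y2, age), y2 - mean(y2), ignore_attr = TRUE,
               tolerance = 1e-3)
  expect_error(age_adjust(y, rep(40, 50)), "constant age")
})

test_that("group comparison reproduces the published effect and is antisymmetric", {
  ft <- sim_feature_table(seed = 3)
  res <- compare_groups(ft, "peak_speed_deg_s")
  expect_lt(res$p, 0.01)
  expect_lt(res$t, 0)          # NS slower
  expect_true(res$age_adjusted)

  swapped <- ft
  swapped$group <- ifelse(ft$group == "NS", "CON", "NS")
  res_sw <- compare_groups(swapped, "peak_speed_deg_s", adjust_for_age = FALSE)
  res_raw <- compare_groups(ft, "peak_speed_deg_s", adjust_for_age = FALSE)
  expect_equal(res_sw$t, -res_raw$t, tolerance = 1e-12)

  # published group parameters give p < 0.01 in (almost) every replicate
  ps <- vapply(1:20, function(s) {
    compare_groups(sim_feature_table(seed = 100 + s), "peak_speed_deg_s")$p
  }, numeric(1))
  expect_gte(mean(ps < 0.01), 0.99)
})

test_that("LDA separates well-separated classes and is affine-invariant", {
  set.seed(5)
  n <- 100
  ft <- tibble::tibble(
    subject_id = as.character(1:(2 * n)),
    group = rep(c("NS", "CON"), each = n),
    age_years = rnorm(2 * n, 48, 9),
    x = c(rnorm(n, 0, 1), rnorm(n, 6, 1)),
    z = rnorm(2 * n)
  )
  r <- lda_loo(ft, c("x", "z"), adjust_for_age = FALSE)
  expect_gte(r$sensitivity, 0.99)
  expect_gte(r$specificity, 0.99)

  ft2 <- ft
  ft2$x <- 100 + 42 * ft$x
  r2 <- lda_loo(ft2, c("x", "z"), adjust_for_age = FALSE)
  expect_equal(r2$sensitivity, r$sensitivity)
  expect_equal(r2$specificity, r$specificity)

  ft3 <- ft
  ft3$dup <- ft$x
  expect_error(lda_loo(ft3, c("x", "dup"), adjust_for_age = FALSE), "collinear")
})

test_that("LDA on identical distributions stays at chance", {
  set.seed(9)
  tot <- replicate(20, {
    n <- 60
    ft <- tibble::tibble(
      subject_id = as.character(1:(2 * n)),
      group = rep(c("NS", "CON"), each = n),
      age_years = rnorm(2 * n, 48, 9),
      x = rnorm(2 * n)
    )
    r <- lda_loo(ft, "x", adjust_for_age = FALSE)
    r$sensitivity + r$specificity
  })
  expect_equal(mean(tot), 1, tolerance = 0.1)
})

test_that("stepwise selection keeps informative variables and drops noise", {
  set.seed(14)
  runs <- replicate(30, {
    n <- 150
    ft <- tibble::tibble(
      subject_id = as.character(1:(2 * n)),
      group = rep(c("NS", "CON"), each = n),
      age_years = rnorm(2 * n, 48, 9),
      a = c(rnorm(n, 0), rnorm(n, 1.5)),
      b = rnorm(2 * n), c = rnorm(2 * n), d = rnorm(2 * n),
      e = rnorm(2 * n), f = rnorm(2 * n)
    )
    sel <- stepwise_lda(ft, letters[1:6], adjust_for_age = FALSE)$variables
    c(first_is_a = sel[1] == "a", n_extra = length(setdiff(sel, "a")))
  })
  # the informative variable always enters first; spurious entries occur at
  # the rate implied by taking the max partial F over five null candidates
  # against the 3.84 entry threshold (~1 - 0.95^5 per step), no more
  expect_equal(mean(runs["first_is_a", ]), 1)
  expect_lte(mean(runs["n_extra", ]), 0.5)
  expect_gte(mean(runs["n_extra", ] == 0), 0.6)

  ft <- sim_feature_table(seed = 2)
  ft$noise <- rnorm(nrow(ft))
  empty <- stepwise_lda(ft, c("peak_speed_deg_s", "noise"), f_enter = Inf)
  expect_length(empty$variables, 0)

  # duplicated informative column: exactly one twin enters
  set.seed(15)
  n <- 150
  ft2 <- tibble::tibble(
    subject_id = as.character(1:(2 * n)),
    group = rep(c("NS", "CON"), each = n),
    age_years = rnorm(2 * n, 48, 9),
    a = c(rnorm(n, 0), rnorm(n, 2))
  )
  ft2$a2 <- ft2$a
  sel2 <- stepwise_lda(ft2, c("a", "a2"), adjust_for_age = FALSE)$variables
  expect_length(sel2, 1)

  # zero thresholds admit every non-collinear variable
  set.seed(16)
  ft3 <- tibble::tibble(
    subject_id = as.character(1:60), group = rep(c("NS", "CON"), each = 30),
    age_years = rnorm(60, 48, 9),
    a = c(rnorm(30), rnorm(30, 1)), b = rnorm(60), c = rnorm(60)
  )
  sel3 <- stepwise_lda(ft3, c("a", "b", "c"), f_enter = 0, f_remove = 0,
                       adjust_for_age = FALSE)$variables
  expect_setequal(sel3, c("a", "b", "c"))
})

test_that("low-back-pain subgroup comparison reproduces the published contrast", {
  # published subgroup parameters: 209 +/- 76 (n = 62) vs 245 +/- 96 (n = 56)
  set.seed(18)
  ps <- replicate(100, {
    ft <- tibble::tibble(
      subject_id = as.character(1:167),
      group = rep(c("NS", "CON"), c(118, 49)),
      low_back_pain = c(rep(c(TRUE, FALSE), c(62, 56)), rep(NA, 49)),
      peak_speed_deg_s = c(rnorm(62, 209, 76), rnorm(56, 245, 96),
                           rnorm(49, 348, 92))
    )
    subgroup_compare(ft)$p[1]
  })
  expect_gt(mean(ps < 0.05), 0.5)

  # null subgroups: p roughly uniform
  set.seed(19)
  ps0 <- replicate(200, {
    ft <- tibble::tibble(
      subject_id = as.character(1:130),
      group = rep(c("NS", "CON"), c(120, 10)),
      low_back_pain = c(rep(c(TRUE, FALSE), each = 60), rep(NA, 10)),
      peak_speed_deg_s = c(rnorm(120, 226, 88), rnorm(10, 348, 92))
    )
    subgroup_compare(ft)$p[1]
  })
  expect_gt(stats::ks.test(ps0, "punif")$p.value, 0.01)

  ft_bad <- tibble::tibble(
    subject_id = as.character(1:10), group = "NS",
    low_back_pain = c(TRUE, rep(FALSE, 9)),
    peak_speed_deg_s = rnorm(10, 226, 88)
  )
  expect_error(subgroup_compare(ft_bad), "too few")
})

test_that("tidy and glance summarise discriminant results", {
  ft <- sim_feature_table(seed = 21)
  r <- lda_loo(ft, "peak_speed_deg_s")
  td <- tidy(r)
  expect_named(td, c("variable", "coefficient", "std_coefficient", "f"))
  gl <- glance(r)
  expect_true(gl$sensitivity >= 0 && gl$sensitivity <= 1)
  expect_equal(gl$n_ns, 118)
})
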