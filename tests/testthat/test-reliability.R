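test_that("consistency ICC ignores fixed offsets and matches the ANOVA oracle", {
  x <- c(12, 15, 19, 25, 31, 8)
  r <- icc_consistency(x, x + 7)
  expect_equal(r$icc, 1, tolerance = 1e-12)

  # 4x2 fixture against an aov-based oracle
  t1 <- c(1, 2, 3, 4); t2 <- c(4, 3, 2, 1)
  got <- suppressWarnings(icc_consistency(t1, t2))$icc
  d <- data.frame(
    y = c(t1, t2),
    subj = factor(rep(1:4, 2)),
    occ = factor(rep(1:2, each = 4))
  )
  ms <- summary(stats::aov(y ~ subj + occ, data = d))[[1]]$`Mean Sq`
  oracle <- (ms[1] - ms[3]) / (ms[1] + ms[3])
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_equal(got, -1, tolerance = 1e-12)

  # independent columns: ICC near zero at large n
  set.seed(101)
  r0 <- icc_consistency(rnorm(10000), rnorm(10000))
  expect_gt(r0$icc, -0.05)
  expect_lt(r0$icc, 0.05)
  expect_error(icc_consistency(1:2, 2:1), "at least 3")
})

test_that("agreement ICC penalises fixed offsets where consistency does not", {
  set.seed(8)
  x <- rnorm(30, 50, 10)
  y <- x + 8 + rnorm(30, 0, 2)
  cons <- icc_consistency(x, y, type = "consistency")$icc
  agr <- icc_consistency(x, y, type = "agreement")$icc
  expect_gt(cons, agr)
})

test_that("SEM follows the difference-SD formula with chi-square intervals", {
  x <- c(100, 120, 140)
  expect_equal(sem_tr(x, x)$sem, 0)
  d <- c(-58, 0, 58)            # sample SD exactly 58
  expect_equal(stats::sd(d), 58)
  r <- sem_tr(x, x - d)
  expect_equal(r$sem, 58 / sqrt(2), tolerance = 1e-12)
  expect_equal(round(r$sem, 2), 41.01)
  r2 <- sem_tr(2 * x, 2 * (x - d))
  expect_equal(r2$sem, 2 * r$sem, tolerance = 1e-12)
  expect_lt(r$sem_lo, r$sem); expect_gt(r$sem_hi, r$sem)
})

test_that("CV is zero under constant multiplicative bias and tracks lognormal noise", {
  x <- c(10, 20, 40, 80)
  expect_equal(cv_tr(x, x)$cv_pct, 0)
  expect_equal(cv_tr(x, 1.10 * x)$cv_pct, 0, tolerance = 1e-12)
  expect_error(cv_tr(c(-1, 2, 3), c(1, 2, 3)), "positive")

  # Monte-Carlo oracle: multiplicative lognormal error of known sigma
  set.seed(55)
  sigma <- 0.15
  base <- exp(rnorm(10000, 5, 0.5))
  t1 <- base * exp(rnorm(10000, 0, sigma))
  t2 <- base * exp(rnorm(10000, 0, sigma))
  got <- cv_tr(t1, t2)$cv_pct
  # SD(log t1 - log t2) = sigma * sqrt(2), so s = sigma and CV = 100(e^sigma - 1)
  expect_equal(got, 100 * (exp(sigma) - 1), tolerance = 0.05)
})

test_that("minimal difference is exactly SEM x 1.96 x sqrt(2)", {
  expect_equal(md(0), 0)
  expect_equal(md(10), 10 * 1.96 * sqrt(2))
  expect_error(md(-1), "non-negative")
})

test_that("heteroscedasticity statistic detects magnitude-dependent error", {
  set.seed(77)
  m <- runif(10000, 10, 100)
  r0 <- heteroscedasticity(m + rnorm(10000), m - rnorm(10000))
  expect_lt(abs(r0$het_r), 0.05)

  d <- 0.1 * m
  r1 <- heteroscedasticity(m + d / 2, m - d / 2)
  expect_gt(r1$het_r, 0.99)

  expect_warning(heteroscedasticity(c(2, 2, 2), c(2, 2, 2)), "undefined")
})

test_that("bias test behaves at the boundary cases", {
  x <- c(10, 12, 15, 19)
  expect_equal(bias_test(x, x), 1)
  set.seed(1)
  a <- rnorm(16, 100, 5)
  expect_lt(bias_test(a, a + 50), 1e-3)
})

test_that("reliability_report assembles consistent statistics", {
  set.seed(30)
  n <- 16
  metrics <- tibble::tibble(
    subject_id = rep(sprintf("s%02d", 1:n), 2),
    session = rep(c("test1", "test2"), each = n),
    group = "CON",
    peak_speed_deg_s = c(rnorm(n, 350, 90), rnorm(n, 350, 90))
  )
  rep1 <- reliability_report(metrics, "peak_speed_deg_s", group = "CON")
  expect_equal(rep1$md, rep1$sem * 1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(rep1$n, n)

  dup <- metrics
  dup$peak_speed_deg_s[dup$session == "test2"] <-
    dup$peak_speed_deg_s[dup$session == "test1"]
  rep2 <- suppressWarnings(reliability_report(dup, "peak_speed_deg_s", group = "CON"))
  expect_equal(rep2$icc, 1, tolerance = 1e-9)
  expect_equal(rep2$sem, 0)
  expect_equal(rep2$md, 0)

  expect_error(
    reliability_report(metrics[1:10, ], "peak_speed_deg_s", group = "CON"),
    "test1 and test2|pairing"
  )
})

test_that("simulated control-like retest data lands in the published ICC band", {
  # generating model for peak speed in controls: between-subject SD ~ 96,
  # within-subject (retest) error = SEM 41 per occasion
  set.seed(202)
  n <- 16
  hits <- replicate(100, {
    subj <- rnorm(n, 355, sqrt(96^2 - 41^2))
    t1 <- subj + rnorm(n, 0, 41)
    t2 <- subj + rnorm(n, 0, 41)
    icc <- icc_consistency(t1, t2)$icc
    icc >= 0.41 && icc <= 0.91
  })
  expect_gte(mean(hits), 0.8)
})

test_that("reliability_table covers every variable-by-group cell", {
  set.seed(31)
  n <- 12
  grid <- expand.grid(subject = 1:n, session = c("test1", "test2"),
                      group = c("CON", "NS"), stringsAsFactors = FALSE)
  metrics <- tibble::tibble(
    subject_id = paste0(grid$group, grid$subject),
    session = grid$session,
    group = grid$group,
    peak_speed_deg_s = rnorm(nrow(grid), 300, 80),
    rom_deg = rnorm(nrow(grid), 57, 8)
  )
  tab <- reliability_table(metrics, variables = c("peak_speed_deg_s", "rom_deg"))
  expect_equal(nrow(tab), 4L)
  expect_true(all(tab$md == tab$sem * 1.96 * sqrt(2)))
  expect_true(all(tab$icc >= -1 & tab$icc <= 1))
})
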