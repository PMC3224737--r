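#' @importFrom rlang .data %||%
#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

# Trapezoidal integral of y over x.
trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)

# Sample skewness g1 = m3 / m2^(3/2).
skewness_g1 <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  mean((x - m)^3) / m2^1.5
}

# Draw from a normal truncated to [lo, hi] by rejection (vectorised, modest n).
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  guard <- 0L
  while (length(bad) > 0L) {
    out[bad] <- stats::rnorm(length(bad), if (length(mean) > 1L) mean[bad] else mean,
                             if (length(sd) > 1L) sd[bad] else sd)
    bad <- which(out < lo | out > hi)
    guard <- guard + 1L
    if (guard > 10000L) stop("truncated-normal bounds unsatisfiable for given mean/sd")
  }
  out
}
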