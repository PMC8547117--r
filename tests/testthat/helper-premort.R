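# Shared fixtures, built in code.

# numeric moments of a skew-normal DP by adaptive quadrature
sn_moments_quadrature <- function(p) {
  m1 <- integrate(function(x) x * dsn_dp(x, p), p$xi - 60 * p$omega,
                  p$xi + 60 * p$omega, rel.tol = 1e-12)$value
  m2 <- integrate(function(x) (x - m1)^2 * dsn_dp(x, p),
                  p$xi - 60 * p$omega, p$xi + 60 * p$omega,
                  rel.tol = 1e-12)$value
  m3 <- integrate(function(x) (x - m1)^3 * dsn_dp(x, p),
                  p$xi - 60 * p$omega, p$xi + 60 * p$omega,
                  rel.tol = 1e-12)$value
  list(mean = m1, var = m2, skewness = m3 / m2^1.5)
}

# a small two-year HMD-layout fixture file; returns its path
write_hmd_fixture <- function(years = c(2010L, 2011L),
                              senescent = sn_cp(80, 10, -0.4)) {
  tabs <- lapply(years, function(y) {
    synthetic_lifetable(senescent, population_id = "FIX", year = y)
  })
  path <- tempfile(fileext = ".txt")
  write_hmd_lifetable(tabs, path)
  path
}

# a tiny group for fast hierarchical smoke tests (small n keeps the
# posterior wide, so short chains still mix)
tiny_group <- function(n = 5000L, seed = 99L) {
  sc <- synthetic_scenario(
    "tiny",
    countries = list(
      list(label = "A", alpha = 0.15, premature = sn_cp(60, 10, 0.2),
           n = n),
      list(label = "B", alpha = 0.35, premature = sn_cp(58, 11, 0.25),
           n = n)),
    senescent = sn_cp(85, 6, -0.4), seed = seed)
  simulate_group(sc)
}
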