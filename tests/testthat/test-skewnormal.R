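test_that("dsn_dp reduces to the normal density at lambda = 0", {
  p <- sn_dp(80, 7, 0)
  expect_equal(dsn_dp(80, p), 1 / (7 * sqrt(2 * pi)), tolerance = 1e-14)
  x <- seq(40, 120, by = 0.5)
  expect_lt(max(abs(dsn_dp(x, p) - dnorm(x, 80, 7))), 1e-12)
})

test_that("dsn_dp integrates to one (quadrature oracle)", {
  for (par in list(c(80, 10, -3), c(60, 5, 2), c(70, 0.5, 50),
                   c(90, 30, -50))) {
    p <- sn_dp(par[1], par[2], par[3])
    val <- integrate(function(x) dsn_dp(x, p), par[1] - 40 * par[2],
                     par[1] + 40 * par[2], rel.tol = 1e-10)$value
    expect_equal(val, 1, tolerance = 1e-8)
  }
})

test_that("psn_dp matches the integral of the density", {
  p <- sn_dp(80, 10, -3)
  for (u in c(55, 70, 80, 95)) {
    ref <- integrate(function(x) dsn_dp(x, p), -Inf, u,
                     rel.tol = 1e-12)$value
    expect_equal(psn_dp(u, p), ref, tolerance = 1e-10)
  }
})

test_that("omega must be positive", {
  expect_error(sn_dp(80, -1, 0), "positive")
  expect_error(sn_dp(80, 0, 0), "positive")
  expect_error(sn_cp(80, 0, 0), "positive")
})

test_that("cp_to_dp is exact in the symmetric case and on moments", {
  dp <- cp_to_dp(sn_cp(87, 5, 0))
  expect_equal(dp$xi, 87)
  expect_equal(dp$omega, 5)
  expect_equal(dp$lam, 0)

  # moments of the converted DP, computed by quadrature, must equal the
  # CP values
  dp2 <- cp_to_dp(sn_cp(87, 5, -0.5))
  mom <- sn_moments_quadrature(dp2)
  expect_equal(mom$mean, 87, tolerance = 1e-6)
  expect_equal(mom$var, 25, tolerance = 1e-6)
  expect_equal(mom$skewness, -0.5, tolerance = 1e-6)
})

test_that("cp_to_dp and dp_to_cp are mutual inverses over a dense grid", {
  for (gamma in c(-0.99, -0.9, -0.5, -0.1, 0, 0.05, 0.3, 0.7, 0.9, 0.99)) {
    for (mu in c(-3, 60, 87)) {
      for (sigma in c(0.8, 6, 15)) {
        cp <- sn_cp(mu, sigma, gamma)
        back <- dp_to_cp(cp_to_dp(cp))
        expect_equal(back$mu, mu, tolerance = 1e-8)
        expect_equal(back$sigma, sigma, tolerance = 1e-8)
        expect_equal(back$gamma, gamma, tolerance = 1e-8)
      }
    }
  }
})

test_that("skewness is bounded, odd and increasing in lambda", {
  expect_equal(round(max_abs_skewness(), 3), 0.995)
  expect_lt(abs(dp_to_cp(sn_dp(0, 1, 1e8))$gamma - max_abs_skewness()),
            1e-4)
  expect_lt(abs(dp_to_cp(sn_dp(0, 1, -1e8))$gamma + max_abs_skewness()),
            1e-4)
  lams <- c(-50, -5, -1, -0.2, 0, 0.2, 1, 5, 50)
  g <- vapply(lams, function(l) dp_to_cp(sn_dp(0, 1, l))$gamma, 0)
  expect_true(all(diff(g) > 0))
  expect_equal(g, -rev(g), tolerance = 1e-12)
  expect_true(all(abs(g) < max_abs_skewness()))
  expect_error(sn_cp(0, 1, 0.9953), "bound")
})

test_that("rsn_dp draws are reproducible and have correct moments", {
  p <- sn_dp(80, 10, -3)
  x1 <- rsn_dp(1e5, p, seed = 42)
  x2 <- rsn_dp(1e5, p, seed = 42)
  expect_identical(x1, x2)

  cp <- dp_to_cp(p)
  expect_lt(abs(mean(x1) - cp$mu), 4 * cp$sigma / sqrt(1e5))
  samp_skew <- mean((x1 - mean(x1))^3) / sd(x1)^3
  expect_lt(abs(samp_skew - cp$gamma), 0.03)

  p0 <- sn_dp(80, 10, 0)
  x0 <- rsn_dp(1e5, p0, seed = 7)
  expect_lt(abs(mean(x0) - 80), 4 * 10 / sqrt(1e5))
})

test_that("sn_discretize is a proper, symmetric-when-symmetric pmf", {
  ages <- 5:110
  pr <- sn_discretize(sn_dp(80, 10, -3), ages)
  expect_equal(sum(pr), 1, tolerance = 1e-12)
  expect_true(all(pr >= 0))

  # symmetric case centered on the grid midpoint
  ages2 <- 0:100
  pr2 <- sn_discretize(sn_dp(50.5, 8, 0), ages2)
  expect_lt(max(abs(pr2 - rev(pr2))), 1e-12)

  expect_error(sn_discretize(sn_dp(10000, 1, 0), 5:110), "mass")
})

test_that("sn_discretize matches a Monte-Carlo histogram", {
  p <- sn_dp(80, 10, -3)
  ages <- 5:110
  pr <- sn_discretize(p, ages)
  set.seed(123)
  draws <- floor(rsn_dp(1e6, p))
  draws <- draws[draws >= 5 & draws <= 110]
  emp <- tabulate(factor(draws, levels = ages),
                  nbins = length(ages)) / length(draws)
  se <- sqrt(pr * (1 - pr) / length(draws))
  expect_true(all(abs(emp - pr) <= 3 * se + 1e-12))
})
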