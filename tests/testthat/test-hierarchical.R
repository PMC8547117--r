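make_params <- function() {
  list(alpha = c(0.2, 0.4), mu_m = c(60, 65), sigma_m = c(10, 12),
       gamma_m = c(0.1, -0.2), mu_M = 87.5, sigma_M = 6, gamma_M = -0.5,
       sd_mu_m = 1.5, sd_gamma_m = 0.12)
}

test_that("log_prior matches an independent term-by-term sum", {
  sp <- prior_spec()
  p <- make_params()

  oracle <- sum(dunif(p$alpha, 0, 0.9, log = TRUE)) +
    sum(dnorm(p$mu_m, 60, p$sd_mu_m, log = TRUE) -
          log(pnorm(75, 60, p$sd_mu_m))) +
    sum(dunif(p$sigma_m, 0, 20, log = TRUE)) +
    sum(dnorm(p$gamma_m, 0, p$sd_gamma_m, log = TRUE) -
          log(pnorm(0.995, 0, p$sd_gamma_m) -
                pnorm(-0.8, 0, p$sd_gamma_m))) +
    dnorm(p$mu_M, 87, 2, log = TRUE) +
    dunif(p$sigma_M, 0, 9, log = TRUE) +
    log(dsn_dp(p$gamma_M, sn_dp(-1, 0.5, 1))) -
    log(psn_dp(0.995, sn_dp(-1, 0.5, 1)) -
          psn_dp(-0.995, sn_dp(-1, 0.5, 1))) +
    dunif(p$sd_mu_m, 0, 2.5, log = TRUE) +
    dunif(p$sd_gamma_m, 0, 0.2, log = TRUE)

  expect_equal(log_prior(p, sp), oracle, tolerance = 1e-10)
})

test_that("log_prior is -Inf outside every truncation", {
  sp <- prior_spec()
  base <- make_params()
  bad <- list(
    within(base, alpha[1] <- 0.95),   # above U(0, 0.9)
    within(base, mu_m[2] <- 80),      # above truncation at 75
    within(base, sigma_m[1] <- 25),
    within(base, gamma_m[1] <- -0.9), # below truncation at -0.8
    within(base, gamma_M <- 0.999),
    within(base, sd_mu_m <- 3),
    within(base, sd_gamma_m <- 0.25))
  for (p in bad) expect_identical(log_prior(p, sp), -Inf)
  expect_true(is.finite(log_prior(base, sp)))
})

test_that("log_likelihood is additive over populations", {
  d1 <- generate_density(0.2, sn_cp(60, 10, 0.2), sn_cp(85, 6, -0.4),
                         n = 5000, seed = 1)
  d2 <- generate_density(0.4, sn_cp(58, 11, 0.1), sn_cp(85, 6, -0.4),
                         n = 5000, seed = 2)
  p2 <- list(alpha = c(0.2, 0.4), mu_m = c(60, 58), sigma_m = c(10, 11),
             gamma_m = c(0.2, 0.1), mu_M = 85, sigma_M = 6,
             gamma_M = -0.4, sd_mu_m = 1.5, sd_gamma_m = 0.12)
  p3 <- within(p2, {
    alpha <- c(alpha, 0.4)
    mu_m <- c(mu_m, 58)
    sigma_m <- c(sigma_m, 11)
    gamma_m <- c(gamma_m, 0.1)
  })
  gd2 <- group_data(c("A", "B"), list(d1, d2))
  gd3 <- group_data(c("A", "B", "B2"), list(d1, d2, d2))
  ll_pair <- log_likelihood(p2, gd2)
  ll_trip <- log_likelihood(p3, gd3)
  # duplicating B adds exactly B's contribution once more
  gd_bb <- group_data(c("B", "B2"), list(d2, d2))
  p_bb <- within(p2, {
    alpha <- c(0.4, 0.4)
    mu_m <- c(58, 58)
    sigma_m <- c(11, 11)
    gamma_m <- c(0.1, 0.1)
  })
  ll_b <- log_likelihood(p_bb, gd_bb) / 2
  expect_equal(ll_trip, ll_pair + ll_b, tolerance = 1e-8)
})

test_that("likelihood peaks at the generating alpha on exact data", {
  truth <- list(alpha = 0.3, prem = sn_cp(60, 10, 0.2),
                sen = sn_cp(85, 6, -0.4))
  d <- generate_density(truth$alpha, truth$prem, truth$sen)  # exact probs
  gd <- group_data(c("A", "A2"), list(d, d))
  grid <- seq(0.1, 0.5, by = 0.05)
  ll <- vapply(grid, function(a) {
    p <- list(alpha = c(a, a), mu_m = c(60, 60), sigma_m = c(10, 10),
              gamma_m = c(0.2, 0.2), mu_M = 85, sigma_M = 6,
              gamma_M = -0.4, sd_mu_m = 1.5, sd_gamma_m = 0.12)
    log_likelihood(p, gd)
  }, 0)
  expect_equal(grid[which.max(ll)], 0.3)

  # alpha = 0 forces the senescent curve to explain mid-age deaths: the
  # low-age cells crush the likelihood
  p0 <- list(alpha = c(1e-9, 1e-9), mu_m = c(60, 60),
             sigma_m = c(10, 10), gamma_m = c(0.2, 0.2), mu_M = 85,
             sigma_M = 6, gamma_M = -0.4, sd_mu_m = 1.5,
             sd_gamma_m = 0.12)
  expect_lt(log_likelihood(p0, gd), max(ll) - 1000)
})

test_that("split R-hat behaves at its reference points", {
  set.seed(42)
  r_good <- compute_rhat(matrix(rnorm(4000), ncol = 4))
  expect_gt(r_good, 0.99)
  expect_lt(r_good, 1.01)

  r_bad <- compute_rhat(cbind(rnorm(1000), rnorm(1000, 10)))
  expect_gt(r_bad, 3)

  r_const <- compute_rhat(matrix(1, nrow = 100, ncol = 4))
  expect_equal(as.numeric(r_const), 1)
  expect_true(attr(r_const, "degenerate"))

  expect_error(compute_rhat(matrix(rnorm(100), ncol = 1)), "2 chains")
  expect_error(compute_rhat(matrix(rnorm(4), ncol = 2)), "4 draws")
})

test_that("fits are deterministic given a seed and respect truncations", {
  gd <- tiny_group()
  cfg <- mcmc_config(chains = 2, iter = 200, warmup = 200, seed = 5)
  fit1 <- fit_hierarchical(gd, mcmc = cfg)
  fit2 <- fit_hierarchical(gd, mcmc = cfg)
  expect_identical(fit1$summary, fit2$summary)
  expect_identical(fit1$draws, fit2$draws)

  draws <- fit1$draws
  for (lab in gd$labels) {
    a <- draws[, , paste0("alpha[", lab, "]")]
    expect_true(all(a > 0 & a < 0.9))
    expect_true(all(draws[, , paste0("mu_m[", lab, "]")] <= 75))
    g <- draws[, , paste0("gamma_m[", lab, "]")]
    expect_true(all(g >= -0.8 & g <= 0.995))
  }
  expect_true(all(abs(draws[, , "gamma_M"]) <= 0.995))
  expect_true(all(draws[, , "sd_mu_m"] > 0 & draws[, , "sd_mu_m"] < 2.5))
  expect_true(all(draws[, , "sd_gamma_m"] > 0 &
                    draws[, , "sd_gamma_m"] < 0.2))
})

test_that("identical populations get near-identical posterior weights", {
  d <- generate_density(0.25, sn_cp(59, 10, 0.2), sn_cp(85, 6, -0.4),
                        n = 20000, seed = 31)
  gd <- group_data(c("X", "Y"), list(d, d))
  fit <- fit_hierarchical(gd, mcmc = mcmc_config(chains = 2, iter = 400,
                                                 warmup = 400, seed = 8))
  pp <- premature_prevalence(fit)
  expect_lt(abs(pp$alpha[1] - pp$alpha[2]), 0.02)
  expect_setequal(pp$rank, 1:2)
})

test_that("deliberately unadapted, dispersed chains are flagged", {
  gd <- tiny_group()
  fit <- fit_hierarchical(gd, mcmc = mcmc_config(chains = 2, iter = 12,
                                                 warmup = 0, seed = 2,
                                                 init_jitter = 4))
  pp <- premature_prevalence(fit)
  expect_gt(max(pp$rhat), 1.1)
  expect_false(fit$converged)
})

test_that("group-fit assessment flags a population shifted off its group", {
  # 1e5 deaths per member: at smaller counts the observed-vs-model
  # total-variation distance is dominated by multinomial noise alone
  sen <- sn_cp(85, 6, -0.4)
  ds <- list(
    generate_density(0.15, sn_cp(60, 10, 0.2), sen, n = 1e5, seed = 11),
    generate_density(0.25, sn_cp(58, 11, 0.25), sen, n = 1e5, seed = 12),
    generate_density(0.35, sn_cp(61, 10, 0.15), sen, n = 1e5, seed = 13))
  cfg <- function(seed) mcmc_config(chains = 2, iter = 500, warmup = 500,
                                    seed = seed)

  # members simulated from the group's own model fit cleanly
  gd_clean <- group_data(c("A", "B", "C"), ds)
  fa_clean <- assess_group_fit(fit_hierarchical(gd_clean, mcmc = cfg(6)),
                               seed = 3)
  expect_false(any(fa_clean$flagged))
  expect_lt(max(fa_clean$dissimilarity), 0.02)

  # adding a member whose density is shifted 15 years right of the
  # group gets that member flagged (its smaller death count keeps it
  # from dragging the shared senescent curve with it)
  w <- ds[[1]]$weights
  w_shift <- c(numeric(15), w[1:(length(w) - 15)])
  alien <- death_density(5:110, w_shift / sum(w_shift),
                         effective_n = 2e3)
  gd_bad <- group_data(c("A", "B", "C", "SHIFTED"), c(ds, list(alien)))
  fa_bad <- assess_group_fit(fit_hierarchical(gd_bad, mcmc = cfg(7)),
                             seed = 3)
  expect_true(all(fa_bad$dissimilarity >= 0 & fa_bad$dissimilarity <= 1))
  expect_true(fa_bad$flagged[4])
  expect_gt(fa_bad$dissimilarity[4], 3 * max(fa_bad$dissimilarity[1:3]))
})

test_that("credible intervals are calibrated across replicate groups", {
  # 10 independent three-country groups; 95% intervals for alpha should
  # cover the truth in at least 85% of the 30 country-instances
  set.seed(2026)
  covered <- 0L
  total <- 0L
  for (rep in 1:10) {
    alphas <- round(runif(3, 0.08, 0.45), 3)
    sc <- synthetic_scenario(
      paste0("rep", rep),
      countries = lapply(1:3, function(j) {
        list(label = paste0("C", j), alpha = alphas[j],
             premature = sn_cp(55 + 4 * runif(1), 9 + 3 * runif(1),
                               0.3 * runif(1)),
             n = 1e5)
      }),
      senescent = sn_cp(84 + 4 * runif(1), 5.5 + runif(1),
                        -0.5 + 0.2 * runif(1)),
      seed = 5000L + rep)
    gd <- simulate_group(sc)
    fit <- fit_hierarchical(gd, mcmc = mcmc_config(chains = 2,
                                                   iter = 800,
                                                   warmup = 800,
                                                   seed = 100L + rep))
    pp <- premature_prevalence(fit)
    covered <- covered + sum(pp$lower <= alphas & alphas <= pp$upper)
    total <- total + 3L
  }
  expect_gte(covered / total, 0.85)
})
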