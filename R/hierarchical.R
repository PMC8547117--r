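# Hierarchical Bayesian premature-mortality model: a group of populations
# shares one senescent skew-normal component (centered parametrization)
# while each population has its own premature component and mixture
# weight alpha_j. Fitted by component-wise adaptive random-walk
# Metropolis on unconstrained parameter scales.

#' Group of death densities for the hierarchical model
#'
#' @param labels Character vector of population labels.
#' @param densities List of [death_density()] objects on one common age
#'   grid (minimum age 5 by convention: the model excludes infant and
#'   child mortality).
#' @param group_name Optional group label.
#' @return An object of class `"group_data"`.
#' @examples
#' gd <- simulate_group(preset_scenarios()[["high_longevity"]])
#' @export
group_data <- function(labels, densities, group_name = "group") {
  stopifnot(length(labels) == length(densities), length(densities) >= 2L)
  for (d in densities) stopifnot(inherits(d, "death_density"))
  ref <- densities[[1L]]
  for (d in densities[-1L]) {
    if (!identical(d$ages, ref$ages)) {
      stop("all densities must share one age grid", call. = FALSE)
    }
  }
  structure(list(labels = as.character(labels), densities = densities,
                 group_name = group_name, ages = ref$ages),
            class = "group_data")
}

#' @export
print.group_data <- function(x, ...) {
  cat(sprintf("Group '%s': %d populations, ages %d-%d\n", x$group_name,
              length(x$labels), x$ages[1L], x$ages[length(x$ages)]))
  cat(" ", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Prior specification for the hierarchical model
#'
#' Defaults encode the model's priors and hyper-priors:
#' \deqn{\alpha_j \sim U(0, 0.9), \quad
#'   \mu^m_j \sim N(60, \sigma_{\mu^m}^2)\,T[-\infty, 75], \quad
#'   \sigma^m_j \sim U(0, 20),}
#' \deqn{\gamma^m_j \sim N(0, \sigma_{\gamma^m}^2)\,T[-0.8, 0.995], \quad
#'   \mu^M \sim N(87, 2^2), \quad \sigma^M \sim U(0, 9),}
#' \deqn{\gamma^M \sim SN(-1, 0.5, 1)\,T[-0.995, 0.995], \quad
#'   \sigma_{\mu^m} \sim U(0, 2.5), \quad \sigma_{\gamma^m} \sim U(0, 0.2).}
#' The truncations double as identification constraints: the premature
#' mean cannot exceed 75 while the senescent mean is centered at 87, so
#' the two components cannot swap labels during sampling. Truncated-prior
#' normalizing constants are included in the log prior; for the
#' country-level means and skewnesses they depend on sampled
#' hyper-parameters, so they matter.
#'
#' `mu_M_sd` defaults to 2, reading the senescent-mean prior's second
#' parameter as a variance of 4; set `mu_M_sd = 4` to read it as a
#' standard deviation instead. The `SN(-1, 0.5, 1)` skewness prior is
#' interpreted in the direct parametrization.
#'
#' @param alpha_low,alpha_high Uniform bounds on the mixture weights.
#' @param mu_m_center Center of the premature-mean prior (years).
#' @param mu_m_upper Upper truncation of the premature mean (years).
#' @param sigma_m_low,sigma_m_high Uniform bounds on premature sd.
#' @param gamma_m_low,gamma_m_high Truncation of premature skewness.
#' @param mu_M_mean,mu_M_sd Normal prior on the senescent mean.
#' @param sigma_M_low,sigma_M_high Uniform bounds on senescent sd.
#' @param gamma_M_xi,gamma_M_omega,gamma_M_lam Direct-parametrization
#'   skew-normal prior on the senescent skewness.
#' @param gamma_M_low,gamma_M_high Truncation of senescent skewness.
#' @param hyper_sd_mu_m_high Upper bound of the uniform hyper-prior on
#'   the sd of country premature means.
#' @param hyper_sd_gamma_m_high Upper bound for the sd of country
#'   premature skewnesses.
#' @return An object of class `"prior_spec"`.
#' @export
prior_spec <- function(alpha_low = 0, alpha_high = 0.9,
                       mu_m_center = 60, mu_m_upper = 75,
                       sigma_m_low = 0, sigma_m_high = 20,
                       gamma_m_low = -0.8, gamma_m_high = 0.995,
                       mu_M_mean = 87, mu_M_sd = 2,
                       sigma_M_low = 0, sigma_M_high = 9,
                       gamma_M_xi = -1, gamma_M_omega = 0.5,
                       gamma_M_lam = 1,
                       gamma_M_low = -0.995, gamma_M_high = 0.995,
                       hyper_sd_mu_m_high = 2.5,
                       hyper_sd_gamma_m_high = 0.2) {
  sp <- list(alpha_low = alpha_low, alpha_high = alpha_high,
             mu_m_center = mu_m_center, mu_m_upper = mu_m_upper,
             sigma_m_low = sigma_m_low, sigma_m_high = sigma_m_high,
             gamma_m_low = gamma_m_low, gamma_m_high = gamma_m_high,
             mu_M_mean = mu_M_mean, mu_M_sd = mu_M_sd,
             sigma_M_low = sigma_M_low, sigma_M_high = sigma_M_high,
             gamma_M_xi = gamma_M_xi, gamma_M_omega = gamma_M_omega,
             gamma_M_lam = gamma_M_lam,
             gamma_M_low = gamma_M_low, gamma_M_high = gamma_M_high,
             hyper_sd_mu_m_high = hyper_sd_mu_m_high,
             hyper_sd_gamma_m_high = hyper_sd_gamma_m_high)
  stopifnot(alpha_low < alpha_high, sigma_m_low < sigma_m_high,
            gamma_m_low < gamma_m_high, sigma_M_low < sigma_M_high,
            gamma_M_low < gamma_M_high, mu_M_sd > 0, gamma_M_omega > 0,
            hyper_sd_mu_m_high > 0, hyper_sd_gamma_m_high > 0,
            gamma_m_high < max_abs_skewness(),
            gamma_M_high < max_abs_skewness())
  structure(sp, class = "prior_spec")
}

#' MCMC settings
#'
#' @param chains Number of chains (default 4).
#' @param iter Post-warmup iterations per chain (default 1000).
#' @param warmup Warmup (adaptation) iterations per chain (default 1000).
#' @param seed Integer seed; every source of randomness in the fit is
#'   derived from it, so a fit is reproducible exactly.
#' @param init_jitter Scale of the chain-specific jitter applied to the
#'   moment-based initial values on the unconstrained scale.
#' @return An object of class `"mcmc_config"`.
#' @export
mcmc_config <- function(chains = 4L, iter = 1000L, warmup = 1000L,
                        seed = 1L, init_jitter = 0.3) {
  stopifnot(chains >= 1L, iter >= 1L, warmup >= 0L)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), seed = as.integer(seed),
                 init_jitter = init_jitter),
            class = "mcmc_config")
}

# --- log prior ---------------------------------------------------------

# numeric core; params as component vectors. Returns -Inf off support.
.log_prior_num <- function(alpha, mu_m, sigma_m, gamma_m, mu_M, sigma_M,
                           gamma_M, sd_mu_m, sd_gamma_m, sp) {
  J <- length(alpha)
  if (any(alpha <= sp$alpha_low) || any(alpha >= sp$alpha_high) ||
      any(mu_m > sp$mu_m_upper) ||
      any(sigma_m <= sp$sigma_m_low) || any(sigma_m >= sp$sigma_m_high) ||
      any(gamma_m < sp$gamma_m_low) || any(gamma_m > sp$gamma_m_high) ||
      sigma_M <= sp$sigma_M_low || sigma_M >= sp$sigma_M_high ||
      gamma_M < sp$gamma_M_low || gamma_M > sp$gamma_M_high ||
      sd_mu_m <= 0 || sd_mu_m >= sp$hyper_sd_mu_m_high ||
      sd_gamma_m <= 0 || sd_gamma_m >= sp$hyper_sd_gamma_m_high) {
    return(-Inf)
  }
  lp <- -J * log(sp$alpha_high - sp$alpha_low) -
    J * log(sp$sigma_m_high - sp$sigma_m_low) -
    log(sp$sigma_M_high - sp$sigma_M_low) -
    log(sp$hyper_sd_mu_m_high) - log(sp$hyper_sd_gamma_m_high)
  # mu_m_j ~ N(center, sd_mu_m^2) truncated above at mu_m_upper
  lp <- lp + sum(stats::dnorm(mu_m, sp$mu_m_center, sd_mu_m, log = TRUE)) -
    J * stats::pnorm(sp$mu_m_upper, sp$mu_m_center, sd_mu_m, log.p = TRUE)
  # gamma_m_j ~ N(0, sd_gamma_m^2) truncated to [gamma_m_low, gamma_m_high]
  zg <- stats::pnorm(sp$gamma_m_high, 0, sd_gamma_m) -
    stats::pnorm(sp$gamma_m_low, 0, sd_gamma_m)
  lp <- lp + sum(stats::dnorm(gamma_m, 0, sd_gamma_m, log = TRUE)) -
    J * log(zg)
  # shared senescent parameters
  lp <- lp + stats::dnorm(mu_M, sp$mu_M_mean, sp$mu_M_sd, log = TRUE)
  zM <- (gamma_M - sp$gamma_M_xi) / sp$gamma_M_omega
  dsn <- log(2 / sp$gamma_M_omega) + stats::dnorm(zM, log = TRUE) +
    stats::pnorm(sp$gamma_M_lam * zM, log.p = TRUE)
  zc <- .psn_num(c(sp$gamma_M_low, sp$gamma_M_high), sp$gamma_M_xi,
                 sp$gamma_M_omega, sp$gamma_M_lam)
  lp + dsn - log(zc[2L] - zc[1L])
}

.params_parts <- function(params) {
  need <- c("alpha", "mu_m", "sigma_m", "gamma_m", "mu_M", "sigma_M",
            "gamma_M", "sd_mu_m", "sd_gamma_m")
  if (!is.list(params) || !all(need %in% names(params))) {
    stop("'params' must be a named list with components ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  J <- length(params$alpha)
  stopifnot(length(params$mu_m) == J, length(params$sigma_m) == J,
            length(params$gamma_m) == J)
  params
}

#' Log prior density of the hierarchical model
#'
#' Sum of the log prior terms of [prior_spec()], including the
#' normalizing constants of the truncated distributions. Points outside
#' the support return `-Inf` (not an error).
#'
#' @param params Named list with components `alpha`, `mu_m`, `sigma_m`,
#'   `gamma_m` (numeric vectors, one entry per population) and scalars
#'   `mu_M`, `sigma_M`, `gamma_M`, `sd_mu_m`, `sd_gamma_m`.
#' @param spec A [prior_spec()].
#' @return Log density (scalar, possibly `-Inf`).
#' @examples
#' p <- list(alpha = c(0.2, 0.3), mu_m = c(60, 62), sigma_m = c(10, 11),
#'           gamma_m = c(0, 0.1), mu_M = 87, sigma_M = 6, gamma_M = -0.5,
#'           sd_mu_m = 1.5, sd_gamma_m = 0.1)
#' log_prior(p, prior_spec())
#' @export
log_prior <- function(params, spec = prior_spec()) {
  p <- .params_parts(params)
  .log_prior_num(p$alpha, p$mu_m, p$sigma_m, p$gamma_m, p$mu_M,
                 p$sigma_M, p$gamma_M, p$sd_mu_m, p$sd_gamma_m, spec)
}

# --- log likelihood ----------------------------------------------------

# Precompute the parts of the data the likelihood loops over.
.likelihood_data <- function(data) {
  ages <- data$ages
  J <- length(data$densities)
  idx <- vector("list", J)
  wn <- vector("list", J)
  n <- numeric(J)
  for (j in seq_len(J)) {
    d <- data$densities[[j]]
    idx[[j]] <- which(d$weights > 0)
    n[j] <- d$effective_n
    wn[[j]] <- d$weights[idx[[j]]] * n[j]
  }
  list(ages = ages, J = J, idx = idx, wn = wn, n = n)
}

# multinomial log likelihood (up to the constant multinomial coefficient)
# for one country given unnormalized component cells.
.ll_country <- function(alpha, cells_m, cells_M, idx, wn, n) {
  mix <- alpha * cells_m + (1 - alpha) * cells_M
  tot <- sum(mix)
  if (!is.finite(tot) || tot <= 0) return(-Inf)
  sum(wn * log(mix[idx])) - n * log(tot)
}

#' Log likelihood of the hierarchical model
#'
#' Multinomial log likelihood (up to a constant) of the group's death
#' distributions under the mixture: for each population `j`, model cell
#' probabilities are the renormalized unit-bin masses of
#' `alpha_j * SN(premature_j) + (1 - alpha_j) * SN(senescent)` on the
#' common age grid (all components in centered parametrization), and the
#' contribution is `effective_n_j * sum_x w_j(x) log p_j(x)`.
#'
#' @inheritParams log_prior
#' @param data A [group_data()].
#' @return Log likelihood (scalar; `-Inf` if a zero model cell meets
#'   positive data weight).
#' @export
log_likelihood <- function(params, data) {
  stopifnot(inherits(data, "group_data"))
  p <- .params_parts(params)
  ld <- .likelihood_data(data)
  dpM <- .cp_to_dp_num(p$mu_M, p$sigma_M, p$gamma_M)
  cells_M <- .sn_cells_num(dpM[1L], dpM[2L], dpM[3L], ld$ages)
  ll <- 0
  for (j in seq_len(ld$J)) {
    dpm <- .cp_to_dp_num(p$mu_m[j], p$sigma_m[j], p$gamma_m[j])
    cells_m <- .sn_cells_num(dpm[1L], dpm[2L], dpm[3L], ld$ages)
    ll <- ll + .ll_country(p$alpha[j], cells_m, cells_M, ld$idx[[j]],
                           ld$wn[[j]], ld$n[j])
    if (!is.finite(ll)) return(-Inf)
  }
  ll
}

# --- sampler -----------------------------------------------------------

# Moment-based initial values shared by all chains (before jitter).
.init_values <- function(data, sp, senescent_fixed = NULL) {
  J <- length(data$densities)
  pooled <- pool_group(data$densities)
  mode_age <- pooled$ages[which.max(pooled$weights)]
  alpha0 <- numeric(J)
  for (j in seq_len(J)) {
    d <- data$densities[[j]]
    alpha0[j] <- min(0.85, max(0.02,
                               sum(d$weights[d$ages < mode_age - 12])))
  }
  list(alpha = alpha0,
       mu_m = rep(min(mode_age - 20, sp$mu_m_upper - 2), J),
       sigma_m = rep(10, J),
       gamma_m = rep(0.05, J),
       mu_M = if (is.null(senescent_fixed)) min(max(mode_age, 70), 100)
              else senescent_fixed$mu,
       sigma_M = if (is.null(senescent_fixed))
         min(6, sp$sigma_M_high * 0.8) else senescent_fixed$sigma,
       gamma_M = if (is.null(senescent_fixed)) -0.3
                 else senescent_fixed$gamma,
       sd_mu_m = 1.2, sd_gamma_m = 0.1)
}

#' Fit the hierarchical premature-mortality model
#'
#' Samples the joint posterior of the group model: each population `j`
#' has its own premature skew-normal component (centered parameters
#' `mu_m[j]`, `sigma_m[j]`, `gamma_m[j]`) and mixture weight `alpha[j]`,
#' while one senescent component (`mu_M`, `sigma_M`, `gamma_M`) is shared
#' by the whole group; `sd_mu_m` and `sd_gamma_m` are the hierarchical
#' spreads of the country premature means and skewnesses. The likelihood
#' is multinomial over the discretized age grid with per-population
#' pseudo-counts `effective_n`.
#'
#' Sampling uses component-wise adaptive random-walk Metropolis on
#' unconstrained transformed parameters (log/logit-type transforms with
#' Jacobian corrections); proposal scales adapt toward a 44% acceptance
#' rate during warmup and are frozen afterwards. Chains are initialized
#' from moment-based starting values with chain-specific jitter. Given
#' `mcmc$seed`, the fit is exactly reproducible.
#'
#' Split R-hat is computed for every parameter; if any `alpha[j]` has
#' R-hat above 1.1 the fit is flagged (`converged = FALSE`) but still
#' returned.
#'
#' @param data A [group_data()].
#' @param prior A [prior_spec()].
#' @param mcmc An [mcmc_config()].
#' @param senescent Optional [sn_cp()]: hold the shared senescent
#'   component fixed at these values instead of estimating it jointly
#'   (the "fixed benchmark" mode, e.g. a reference country's senescent
#'   curve estimated beforehand with [fit_relative()]). Default `NULL`
#'   estimates it from the pooled group.
#' @return An object of class `"hier_fit"`: posterior draws (array
#'   `iter x chains x parameters`), per-parameter split R-hat, summary
#'   table, acceptance rates, and the inputs.
#' @examples
#' \donttest{
#' gd <- simulate_group(preset_scenarios()[["high_longevity"]])
#' fit <- fit_hierarchical(gd, mcmc = mcmc_config(chains = 2, iter = 300,
#'                                                warmup = 300, seed = 7))
#' summary(fit)
#' }
#' @export
fit_hierarchical <- function(data, prior = prior_spec(),
                             mcmc = mcmc_config(), senescent = NULL) {
  stopifnot(inherits(data, "group_data"), inherits(prior, "prior_spec"),
            inherits(mcmc, "mcmc_config"))
  if (!is.null(senescent)) stopifnot(inherits(senescent, "sn_cp"))
  J <- length(data$densities)
  ld <- .likelihood_data(data)
  sp <- prior
  fixedM <- !is.null(senescent)

  # parameter table: name, type (for cache invalidation), country index,
  # transform
  eps <- 1e-6  # keep logit/log transforms away from exact bounds
  par_tab <- list()
  add <- function(name, type, j, tr) {
    par_tab[[length(par_tab) + 1L]] <<- list(name = name, type = type,
                                             j = j, tr = tr)
  }
  for (j in seq_len(J)) {
    lab <- data$labels[j]
    add(paste0("alpha[", lab, "]"), "alpha", j,
        .tr("lb_ub", sp$alpha_low + eps, sp$alpha_high - eps))
    add(paste0("mu_m[", lab, "]"), "prem", j, .tr("ub", b = sp$mu_m_upper))
    add(paste0("sigma_m[", lab, "]"), "prem", j,
        .tr("lb_ub", sp$sigma_m_low + eps, sp$sigma_m_high - eps))
    add(paste0("gamma_m[", lab, "]"), "prem", j,
        .tr("lb_ub", sp$gamma_m_low + eps, sp$gamma_m_high - eps))
  }
  if (!fixedM) {
    add("mu_M", "shared", 0L, .tr("id"))
    add("sigma_M", "shared", 0L,
        .tr("lb_ub", sp$sigma_M_low + eps, sp$sigma_M_high - eps))
    add("gamma_M", "shared", 0L,
        .tr("lb_ub", sp$gamma_M_low + eps, sp$gamma_M_high - eps))
  }
  add("sd_mu_m", "hyper", 0L, .tr("lb_ub", eps, sp$hyper_sd_mu_m_high - eps))
  add("sd_gamma_m", "hyper", 0L,
      .tr("lb_ub", 1e-4, sp$hyper_sd_gamma_m_high - eps))
  P <- length(par_tab)
  par_names <- vapply(par_tab, `[[`, "", "name")

  # index helpers into the flat constrained vector x
  ix_alpha <- match(paste0("alpha[", data$labels, "]"), par_names)
  ix_mu_m <- match(paste0("mu_m[", data$labels, "]"), par_names)
  ix_sigma_m <- match(paste0("sigma_m[", data$labels, "]"), par_names)
  ix_gamma_m <- match(paste0("gamma_m[", data$labels, "]"), par_names)
  ix_sd <- match(c("sd_mu_m", "sd_gamma_m"), par_names)

  lprior_x <- function(x) {
    .log_prior_num(x[ix_alpha], x[ix_mu_m], x[ix_sigma_m], x[ix_gamma_m],
                   if (fixedM) senescent$mu else x[par_names == "mu_M"],
                   if (fixedM) senescent$sigma else x[par_names == "sigma_M"],
                   if (fixedM) senescent$gamma else x[par_names == "gamma_M"],
                   x[ix_sd[1L]], x[ix_sd[2L]], sp)
  }
  cells_prem <- function(x, j) {
    dp <- .cp_to_dp_num(x[ix_mu_m[j]], x[ix_sigma_m[j]], x[ix_gamma_m[j]])
    .sn_cells_num(dp[1L], dp[2L], dp[3L], ld$ages)
  }
  cells_sen <- function(x) {
    dp <- if (fixedM) {
      .cp_to_dp_num(senescent$mu, senescent$sigma, senescent$gamma)
    } else {
      .cp_to_dp_num(x[par_names == "mu_M"], x[par_names == "sigma_M"],
                    x[par_names == "gamma_M"])
    }
    .sn_cells_num(dp[1L], dp[2L], dp[3L], ld$ages)
  }

  init <- .init_values(data, sp, if (fixedM) senescent else NULL)
  x0 <- numeric(P)
  x0[ix_alpha] <- init$alpha
  x0[ix_mu_m] <- init$mu_m
  x0[ix_sigma_m] <- init$sigma_m
  x0[ix_gamma_m] <- init$gamma_m
  if (!fixedM) {
    x0[par_names == "mu_M"] <- init$mu_M
    x0[par_names == "sigma_M"] <- init$sigma_M
    x0[par_names == "gamma_M"] <- init$gamma_M
  }
  x0[ix_sd] <- c(init$sd_mu_m, init$sd_gamma_m)
  z0 <- vapply(seq_len(P), function(k) .tr_to_z(x0[k], par_tab[[k]]$tr), 0)

  total_iter <- mcmc$warmup + mcmc$iter
  draws <- array(NA_real_, dim = c(mcmc$iter, mcmc$chains, P),
                 dimnames = list(NULL, NULL, par_names))
  acc_rate <- matrix(0, mcmc$chains, P,
                     dimnames = list(NULL, par_names))

  # blocks for joint proposals along correlated directions: one 4-d block
  # per country plus the shared senescent 3-d block; covariances are
  # learned from warmup draws (second half of warmup only)
  blocks <- lapply(seq_len(J), function(j) {
    list(idx = c(ix_alpha[j], ix_mu_m[j], ix_sigma_m[j], ix_gamma_m[j]),
         type = "country", j = j)
  })
  if (!fixedM) {
    blocks <- c(blocks, list(list(
      idx = which(par_names %in% c("mu_M", "sigma_M", "gamma_M")),
      type = "shared", j = 0L)))
  }
  w_half <- mcmc$warmup %/% 2L

  for (ch in seq_len(mcmc$chains)) {
    set.seed(mcmc$seed + 1009L * ch)
    z <- z0 + stats::rnorm(P, 0, mcmc$init_jitter)
    x <- vapply(seq_len(P), function(k) .tr_to_x(z[k], par_tab[[k]]$tr), 0)
    cm <- lapply(seq_len(J), function(j) cells_prem(x, j))
    cM <- cells_sen(x)
    ll_j <- vapply(seq_len(J), function(j) {
      .ll_country(x[ix_alpha[j]], cm[[j]], cM, ld$idx[[j]], ld$wn[[j]],
                  ld$n[j])
    }, 0)
    lp <- lprior_x(x)
    ljac <- vapply(seq_len(P), function(k) .tr_ljac(z[k], par_tab[[k]]$tr), 0)
    if (!is.finite(lp + sum(ll_j))) {
      # fall back to the unjittered start, which is always in support
      z <- z0
      x <- x0
      cm <- lapply(seq_len(J), function(j) cells_prem(x, j))
      cM <- cells_sen(x)
      ll_j <- vapply(seq_len(J), function(j) {
        .ll_country(x[ix_alpha[j]], cm[[j]], cM, ld$idx[[j]], ld$wn[[j]],
                    ld$n[j])
      }, 0)
      lp <- lprior_x(x)
      ljac <- vapply(seq_len(P), function(k) .tr_ljac(z[k], par_tab[[k]]$tr),
                     0)
    }
    ls <- rep(log(0.25), P)  # log proposal sd on the z scale
    n_acc <- numeric(P)
    zbuf <- matrix(NA_real_, max(1L, mcmc$warmup), P)  # warmup draws for cov
    nbuf <- 0L
    blk_chol <- vector("list", length(blocks))
    blk_ls <- vapply(blocks, function(b) log(2.38 / sqrt(length(b$idx))), 0)
    for (t in seq_len(total_iter)) {
      for (k in seq_len(P)) {
        tr <- par_tab[[k]]$tr
        type <- par_tab[[k]]$type
        jj <- par_tab[[k]]$j
        z_new <- z[k] + exp(ls[k]) * stats::rnorm(1L)
        x_new_k <- .tr_to_x(z_new, tr)
        x_prop <- x
        x_prop[k] <- x_new_k
        lp_new <- lprior_x(x_prop)
        a_prob <- 0
        if (is.finite(lp_new)) {
          if (type == "alpha") {
            ll_new_j <- .ll_country(x_new_k, cm[[jj]], cM, ld$idx[[jj]],
                                    ld$wn[[jj]], ld$n[jj])
            dll <- ll_new_j - ll_j[jj]
          } else if (type == "prem") {
            cm_new <- cells_prem(x_prop, jj)
            ll_new_j <- .ll_country(x_prop[ix_alpha[jj]], cm_new, cM,
                                    ld$idx[[jj]], ld$wn[[jj]], ld$n[jj])
            dll <- ll_new_j - ll_j[jj]
          } else if (type == "shared") {
            cM_new <- cells_sen(x_prop)
            ll_new <- vapply(seq_len(J), function(j) {
              .ll_country(x_prop[ix_alpha[j]], cm[[j]], cM_new,
                          ld$idx[[j]], ld$wn[[j]], ld$n[j])
            }, 0)
            dll <- sum(ll_new) - sum(ll_j)
          } else {  # hyper: prior only
            dll <- 0
          }
          ljac_new <- .tr_ljac(z_new, tr)
          lr <- (lp_new - lp) + dll + (ljac_new - ljac[k])
          a_prob <- if (is.finite(lr)) min(1, exp(lr)) else 0
          if (stats::runif(1L) < a_prob) {
            z[k] <- z_new
            x[k] <- x_new_k
            lp <- lp_new
            ljac[k] <- ljac_new
            if (type == "alpha") {
              ll_j[jj] <- ll_new_j
            } else if (type == "prem") {
              cm[[jj]] <- cm_new
              ll_j[jj] <- ll_new_j
            } else if (type == "shared") {
              cM <- cM_new
              ll_j <- ll_new
            }
            if (t > mcmc$warmup) n_acc[k] <- n_acc[k] + 1
          }
        }
        if (t <= mcmc$warmup) {
          ls[k] <- ls[k] + (a_prob - 0.44) * min(0.25, 3 / sqrt(t))
        }
      }
      # learn block covariances from warmup draws, then make joint
      # proposals along the learned directions
      if (t <= mcmc$warmup && t > w_half %/% 2L) {
        nbuf <- nbuf + 1L
        zbuf[nbuf, ] <- z
        if (t >= w_half && nbuf >= 25L &&
            (t %% 100L == 0L || t == w_half || t == mcmc$warmup)) {
          zc <- zbuf[seq_len(nbuf), , drop = FALSE]
          for (b in seq_along(blocks)) {
            S <- stats::cov(zc[, blocks[[b]]$idx, drop = FALSE])
            S <- S + diag(1e-10 + 1e-6 * diag(S), nrow(S))
            R <- tryCatch(chol(S), error = function(e) NULL)
            if (!is.null(R)) blk_chol[[b]] <- R
          }
        }
      }
      if (t > w_half) {
        for (b in seq_along(blocks)) {
          if (is.null(blk_chol[[b]])) next
          blk <- blocks[[b]]
          idx <- blk$idx
          d <- length(idx)
          z_prop_b <- z[idx] + exp(blk_ls[b]) *
            drop(crossprod(blk_chol[[b]], stats::rnorm(d)))
          x_prop <- x
          x_prop[idx] <- vapply(seq_len(d), function(i) {
            .tr_to_x(z_prop_b[i], par_tab[[idx[i]]]$tr)
          }, 0)
          lp_new <- lprior_x(x_prop)
          a_prob <- 0
          if (is.finite(lp_new)) {
            if (blk$type == "country") {
              jj <- blk$j
              cm_new <- cells_prem(x_prop, jj)
              ll_new_j <- .ll_country(x_prop[ix_alpha[jj]], cm_new, cM,
                                      ld$idx[[jj]], ld$wn[[jj]], ld$n[jj])
              dll <- ll_new_j - ll_j[jj]
            } else {
              cM_new <- cells_sen(x_prop)
              ll_new <- vapply(seq_len(J), function(j2) {
                .ll_country(x_prop[ix_alpha[j2]], cm[[j2]], cM_new,
                            ld$idx[[j2]], ld$wn[[j2]], ld$n[j2])
              }, 0)
              dll <- sum(ll_new) - sum(ll_j)
            }
            ljac_new_b <- vapply(seq_len(d), function(i) {
              .tr_ljac(z_prop_b[i], par_tab[[idx[i]]]$tr)
            }, 0)
            lr <- (lp_new - lp) + dll + sum(ljac_new_b) - sum(ljac[idx])
            a_prob <- if (is.finite(lr)) min(1, exp(lr)) else 0
            if (stats::runif(1L) < a_prob) {
              z[idx] <- z_prop_b
              x[idx] <- x_prop[idx]
              ljac[idx] <- ljac_new_b
              lp <- lp_new
              if (blk$type == "country") {
                cm[[blk$j]] <- cm_new
                ll_j[blk$j] <- ll_new_j
              } else {
                cM <- cM_new
                ll_j <- ll_new
              }
            }
          }
          if (t <= mcmc$warmup) {
            blk_ls[b] <- blk_ls[b] + (a_prob - 0.25) * min(0.25, 3 / sqrt(t))
          }
        }
      }
      if (t > mcmc$warmup) draws[t - mcmc$warmup, ch, ] <- x
    }
    acc_rate[ch, ] <- n_acc / mcmc$iter
  }

  rhat <- vapply(seq_len(P), function(k) {
    as.numeric(compute_rhat(draws[, , k, drop = TRUE]))
  }, 0)
  names(rhat) <- par_names
  flat <- matrix(draws, ncol = P, dimnames = list(NULL, par_names))
  smry <- data.frame(
    parameter = par_names,
    mean = colMeans(flat),
    sd = apply(flat, 2L, stats::sd),
    q2.5 = apply(flat, 2L, stats::quantile, probs = 0.025, names = FALSE),
    q97.5 = apply(flat, 2L, stats::quantile, probs = 0.975, names = FALSE),
    rhat = rhat, row.names = NULL)

  structure(list(draws = draws, rhat = rhat, summary = smry,
                 acc_rate = acc_rate, data = data, prior = sp, mcmc = mcmc,
                 senescent_fixed = senescent,
                 converged = all(rhat[ix_alpha] <= 1.1, na.rm = TRUE),
                 par_names = par_names, labels = data$labels),
            class = "hier_fit")
}

#' @export
print.hier_fit <- function(x, ...) {
  cat(sprintf("Hierarchical premature-mortality fit: group '%s' (%d populations)\n",
              x$data$group_name, length(x$labels)))
  cat(sprintf("  %d chains x %d iterations (+%d warmup)%s\n",
              x$mcmc$chains, x$mcmc$iter, x$mcmc$warmup,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(premature_prevalence(x), digits = 3)
  invisible(x)
}

#' @export
summary.hier_fit <- function(object, ...) {
  out <- object$summary
  class(out) <- c("summary.hier_fit", "data.frame")
  attr(out, "converged") <- object$converged
  out
}

#' @export
print.summary.hier_fit <- function(x, ...) {
  cat("Posterior summary (mean, central 95% interval, split R-hat):\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  if (!attr(x, "converged")) {
    cat("warning: R-hat above 1.1 on a mixture weight; chains have not mixed\n")
  }
  invisible(x)
}

#' @export
coef.hier_fit <- function(object, ...) {
  stats::setNames(object$summary$mean, object$summary$parameter)
}

#' Posterior-mean model cell probabilities per population
#'
#' @param object A `"hier_fit"`.
#' @param ... Unused.
#' @return Matrix `length(ages) x J` of model cell probabilities at the
#'   posterior mean parameters.
#' @export
fitted.hier_fit <- function(object, ...) {
  cf <- coef(object)
  J <- length(object$labels)
  sen <- if (is.null(object$senescent_fixed)) {
    sn_cp(cf[["mu_M"]], cf[["sigma_M"]], cf[["gamma_M"]])
  } else object$senescent_fixed
  out <- vapply(seq_len(J), function(j) {
    lab <- object$labels[j]
    mixture_cell_probs(cf[[paste0("alpha[", lab, "]")]],
                       sn_cp(cf[[paste0("mu_m[", lab, "]")]],
                             cf[[paste0("sigma_m[", lab, "]")]],
                             cf[[paste0("gamma_m[", lab, "]")]]),
                       sen, ages = object$data$ages)
  }, numeric(length(object$data$ages)))
  colnames(out) <- object$labels
  out
}

#' @export
plot.hier_fit <- function(x, ...) {
  probs <- fitted(x)
  J <- length(x$labels)
  old <- graphics::par(mfrow = grDevices::n2mfrow(J),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (j in seq_len(J)) {
    d <- x$data$densities[[j]]
    graphics::plot(d$ages, d$weights, type = "h", col = "grey60",
                   xlab = "age", ylab = "share of deaths",
                   main = x$labels[j], ...)
    graphics::lines(d$ages, probs[, j], col = "firebrick", lwd = 2)
  }
  invisible(x)
}

# --- diagnostics -------------------------------------------------------

#' Split R-hat convergence diagnostic
#'
#' The potential scale reduction factor computed on split chains: each
#' chain is halved, and with `W` the mean within-(half-)chain variance
#' and `B` the between-half-chain variance of means,
#' \eqn{\hat R = \sqrt{((n-1)/n\,W + B/n)/W}} for half-length `n`.
#' Values near 1 indicate the chains have mixed; above roughly 1.1 they
#' have not.
#'
#' @param draws Matrix `iterations x chains`, or a list of equal-length
#'   chain vectors.
#' @return R-hat (scalar). For chains with zero total variance (a
#'   degenerate, constant parameter) the value is 1 by convention, with
#'   attribute `degenerate = TRUE`.
#' @examples
#' set.seed(1)
#' compute_rhat(matrix(rnorm(4000), ncol = 4))        # ~1
#' compute_rhat(cbind(rnorm(1000), rnorm(1000, 10)))  # >> 1
#' @export
compute_rhat <- function(draws) {
  if (is.list(draws)) draws <- do.call(cbind, draws)
  draws <- as.matrix(draws)
  if (ncol(draws) < 2L) {
    stop("R-hat requires at least 2 chains", call. = FALSE)
  }
  if (nrow(draws) < 4L) {
    stop("R-hat requires at least 4 draws per chain", call. = FALSE)
  }
  n2 <- nrow(draws) %/% 2L
  halves <- cbind(draws[seq_len(n2), , drop = FALSE],
                  draws[seq.int(nrow(draws) - n2 + 1L, nrow(draws)), ,
                        drop = FALSE])
  mns <- colMeans(halves)
  W <- mean(apply(halves, 2L, stats::var))
  B <- n2 * stats::var(mns)
  if (!is.finite(W) || (W < 1e-300 && B < 1e-300)) {
    return(structure(1, degenerate = TRUE))
  }
  if (W < 1e-300) return(Inf)
  sqrt(((n2 - 1) / n2 * W + B / n2) / W)
}

#' Premature-mortality prevalence table
#'
#' Per population: posterior mean of the mixture weight `alpha`, central
#' 95% credible interval, split R-hat, and within-group rank (rank 1 =
#' smallest `alpha`).
#'
#' @param fit A `"hier_fit"`.
#' @return Data frame with one row per population.
#' @export
premature_prevalence <- function(fit) {
  stopifnot(inherits(fit, "hier_fit"))
  anames <- paste0("alpha[", fit$labels, "]")
  s <- fit$summary[match(anames, fit$summary$parameter), ]
  out <- data.frame(population = fit$labels,
                    alpha = s$mean, lower = s$q2.5, upper = s$q97.5,
                    rhat = s$rhat,
                    rank = rank(s$mean, ties.method = "first"))
  rownames(out) <- NULL
  out
}

#' Assess how well each population fits its group
#'
#' For each population: the dissimilarity index (half the total absolute
#' difference, i.e. total-variation distance) between the posterior-mean
#' model cell probabilities and the observed death distribution, and a
#' posterior-predictive p-value from multinomial replicates (for each
#' sampled draw, replicate data of size `effective_n` from that draw's
#' model probabilities and compare the replicate's dissimilarity with the
#' observed one). Populations whose dissimilarity exceeds `threshold`
#' are flagged as poorly grouped: their mortality profile is too far
#' from what the shared senescent component can accommodate.
#'
#' @param fit A `"hier_fit"`.
#' @param threshold Dissimilarity above which a population is flagged
#'   (default 0.05).
#' @param n_rep Number of posterior-predictive replicates (default 200).
#' @param seed Seed for the replicates.
#' @return Data frame: population, dissimilarity, ppp, flagged.
#' @export
assess_group_fit <- function(fit, threshold = 0.05, n_rep = 200L,
                             seed = 1L) {
  stopifnot(inherits(fit, "hier_fit"))
  set.seed(seed)
  data <- fit$data
  J <- length(fit$labels)
  probs_mean <- fitted(fit)
  flat <- matrix(fit$draws, ncol = dim(fit$draws)[3L],
                 dimnames = list(NULL, fit$par_names))
  pick <- sample.int(nrow(flat), n_rep, replace = n_rep > nrow(flat))
  dissim <- numeric(J)
  ppp <- numeric(J)
  for (j in seq_len(J)) {
    d <- data$densities[[j]]
    lab <- fit$labels[j]
    dissim[j] <- 0.5 * sum(abs(probs_mean[, j] - d$weights))
    n <- max(1L, round(d$effective_n))
    exceed <- 0L
    for (r in seq_len(n_rep)) {
      th <- flat[pick[r], ]
      sen <- if (is.null(fit$senescent_fixed)) {
        sn_cp(th[["mu_M"]], th[["sigma_M"]], th[["gamma_M"]])
      } else fit$senescent_fixed
      pr <- mixture_cell_probs(th[[paste0("alpha[", lab, "]")]],
                               sn_cp(th[[paste0("mu_m[", lab, "]")]],
                                     th[[paste0("sigma_m[", lab, "]")]],
                                     th[[paste0("gamma_m[", lab, "]")]]),
                               sen, ages = data$ages)
      rep_w <- as.numeric(stats::rmultinom(1L, n, pr)) / n
      stat_rep <- 0.5 * sum(abs(rep_w - pr))
      stat_obs <- 0.5 * sum(abs(d$weights - pr))
      if (stat_rep >= stat_obs) exceed <- exceed + 1L
    }
    ppp[j] <- exceed / n_rep
  }
  data.frame(population = fit$labels, dissimilarity = dissim, ppp = ppp,
             flagged = dissim > threshold)
}
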