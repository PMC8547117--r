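# Synthetic life tables and group scenarios generated from known mixture
# parameters, so model fitting can be validated without external data.

#' Cell probabilities of a premature/senescent mixture on an age grid
#'
#' Discretizes the two-component mixture `alpha * premature +
#' (1 - alpha) * senescent` onto unit age bins by CDF differences and
#' renormalizes over the grid. This is the model density both the
#' hierarchical and the single-population fits compare with observed
#' life-table death distributions, and the density the synthetic generator
#' samples from.
#'
#' @param alpha Premature mixture weight in `[0, 1)`.
#' @param premature,senescent `"sn_cp"` (centered) or `"sn_dp"` (direct)
#'   parameter objects for the two components.
#' @param ages Integer age grid (default `5:110`).
#' @return Probability vector over `ages` summing to 1.
#' @examples
#' pr <- mixture_cell_probs(0.2, sn_cp(60, 10, 0.3), sn_cp(87, 6, -0.5))
#' sum(pr)
#' @export
mixture_cell_probs <- function(alpha, premature, senescent, ages = 5:110) {
  stopifnot(alpha >= 0, alpha < 1)
  dpm <- .as_dp_num(premature)
  dpM <- .as_dp_num(senescent)
  cells <- alpha * .sn_cells_num(dpm[1L], dpm[2L], dpm[3L], ages) +
    (1 - alpha) * .sn_cells_num(dpM[1L], dpM[2L], dpM[3L], ages)
  tot <- sum(cells)
  if (!is.finite(tot) || tot < 1e-6) {
    stop("mixture carries less than 1e-6 mass on the age grid", call. = FALSE)
  }
  cells / tot
}

.as_dp_num <- function(p) {
  if (inherits(p, "sn_dp")) c(p$xi, p$omega, p$lam)
  else if (inherits(p, "sn_cp")) .cp_to_dp_num(p$mu, p$sigma, p$gamma)
  else stop("expected an 'sn_cp' or 'sn_dp' object", call. = FALSE)
}

#' Synthetic group scenario
#'
#' Bundles the true generative parameters of a group of populations: one
#' shared senescent component (centered parametrization) and, per country,
#' a premature component, a mixture weight `alpha` and a death count `n`.
#' Used by [simulate_group()] and checked by parameter-recovery tests.
#'
#' @param group_name Character label for the group.
#' @param countries List; each element a list with `label` (character),
#'   `alpha` (in (0, 0.9)), `premature` (an [sn_cp()] with mean at most
#'   75), and optionally `n` (deaths; `NULL` means exact cell
#'   probabilities, no sampling noise).
#' @param senescent Shared senescent component, an [sn_cp()].
#' @param radix Life-table radix (default 100000).
#' @param seed Integer seed used when sampling the group.
#' @param min_age,open_age Age-grid limits (defaults 5 and 110).
#' @return An object of class `"synthetic_scenario"`.
#' @export
synthetic_scenario <- function(group_name, countries, senescent,
                               radix = 100000, seed = 1L,
                               min_age = 5L, open_age = 110L) {
  stopifnot(inherits(senescent, "sn_cp"), length(countries) >= 1L,
            min_age < open_age, radix > 0)
  for (co in countries) {
    stopifnot(is.character(co$label), inherits(co$premature, "sn_cp"))
    if (co$alpha <= 0 || co$alpha >= 0.9) {
      stop("country alpha must lie in (0, 0.9)", call. = FALSE)
    }
    if (co$premature$mu > 75) {
      stop("premature component mean must not exceed 75", call. = FALSE)
    }
  }
  structure(list(group_name = group_name, countries = countries,
                 senescent = senescent, radix = radix,
                 seed = as.integer(seed), min_age = as.integer(min_age),
                 open_age = as.integer(open_age)),
            class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf("Synthetic scenario '%s': %d countries, senescent mean %.1f\n",
              x$group_name, length(x$countries), x$senescent$mu))
  for (co in x$countries) {
    cat(sprintf("  %-10s alpha = %.3f, premature mean = %.1f\n",
                co$label, co$alpha, co$premature$mu))
  }
  invisible(x)
}

#' Generate one country's age-at-death distribution
#'
#' Computes the exact mixture cell probabilities on the scenario age grid
#' and, when a death count `n` is given, replaces them by a multinomial
#' draw of size `n` (normalized). With `n = NULL` the weights are the
#' exact probabilities.
#'
#' @param alpha Premature mixture weight.
#' @param premature,senescent Component parameters ([sn_cp()] or
#'   [sn_dp()]).
#' @param n Number of deaths to sample, or `NULL` for exact probabilities.
#' @param ages Integer age grid.
#' @param seed Optional integer seed.
#' @return A [death_density()] with `effective_n = n` (or the grid's exact
#'   probabilities with `effective_n = 1e5` when `n` is `NULL`).
#' @examples
#' d <- generate_density(0.25, sn_cp(60, 10, 0.3), sn_cp(87, 6, -0.5),
#'                       n = 1000, seed = 42)
#' @export
generate_density <- function(alpha, premature, senescent, n = NULL,
                             ages = 5:110, seed = NULL) {
  probs <- mixture_cell_probs(alpha, premature, senescent, ages)
  if (is.null(n)) {
    return(death_density(ages, probs, effective_n = 1e5))
  }
  if (!is.null(seed)) set.seed(seed)
  counts <- as.numeric(stats::rmultinom(1L, size = n, prob = probs))
  death_density(ages, counts / n, effective_n = n)
}

#' Simulate a whole group from a scenario
#'
#' Draws every country of a [synthetic_scenario()] (seeded per country
#' from the scenario seed) and returns a [group_data()] ready for
#' [fit_hierarchical()], with the true parameters attached as attribute
#' `"truth"` (a data frame with `label`, `alpha_true` and the premature
#' CP parameters).
#'
#' @param scenario A [synthetic_scenario()].
#' @return A `"group_data"` object.
#' @examples
#' sc <- preset_scenarios()[["high_longevity"]]
#' gd <- simulate_group(sc)
#' @export
simulate_group <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  ages <- seq.int(scenario$min_age, scenario$open_age)
  densities <- vector("list", length(scenario$countries))
  labels <- character(length(scenario$countries))
  for (i in seq_along(scenario$countries)) {
    co <- scenario$countries[[i]]
    labels[i] <- co$label
    sen <- if (is.null(co$senescent)) scenario$senescent else co$senescent
    densities[[i]] <- generate_density(
      co$alpha, co$premature, sen,
      n = if (is.null(co$n)) NULL else co$n, ages = ages,
      seed = scenario$seed + 1000L * i)
  }
  gd <- group_data(labels, densities, group_name = scenario$group_name)
  attr(gd, "truth") <- data.frame(
    label = labels,
    alpha_true = vapply(scenario$countries, `[[`, 0, "alpha"),
    mu_m = vapply(scenario$countries, function(co) co$premature$mu, 0),
    sigma_m = vapply(scenario$countries, function(co) co$premature$sigma, 0),
    gamma_m = vapply(scenario$countries, function(co) co$premature$gamma, 0))
  gd
}

# Largest-remainder rounding: integer vector summing to `total`.
.round_to_total <- function(x, total) {
  fl <- floor(x)
  rem <- x - fl
  short <- as.integer(round(total - sum(fl)))
  if (short > 0) {
    idx <- order(rem, decreasing = TRUE)[seq_len(short)]
    fl[idx] <- fl[idx] + 1
  }
  fl
}

#' Build a full synthetic life table from mixture parameters
#'
#' Constructs a [lifetable()] on ages `0..open_age` whose `dx` column
#' follows the three-component structure: an optional infant/child share
#' `eta` placed by the half-normal infant component, and the remaining
#' mass split between a premature and a senescent skew-normal. Deaths are
#' scaled to the radix with largest-remainder rounding so they sum to the
#' radix exactly; `lx` is derived by cumulative deaths, `Lx = lx - dx/2`
#' and `mx = dx/Lx`.
#'
#' @param senescent Senescent component ([sn_cp()] or [sn_dp()]).
#' @param premature Optional premature component; `NULL` for none.
#' @param alpha Premature weight among non-infant deaths.
#' @param eta Infant mixture weight (default 0).
#' @param infant_scale Age scale of the infant half-normal, years.
#' @param population_id,year Metadata for the table.
#' @param radix Cohort size (default 100000).
#' @param open_age Terminal age (default 110).
#' @param n Deaths to sample before scaling, or `NULL` for exact
#'   probabilities.
#' @param seed Optional integer seed (used when `n` is given).
#' @return A `"lifetable"` object.
#' @examples
#' tab <- synthetic_lifetable(sn_cp(80, 10, -0.4), seed = 1)
#' @export
synthetic_lifetable <- function(senescent, premature = NULL, alpha = 0,
                                eta = 0, infant_scale = 1,
                                population_id = "SYN", year = 2010L,
                                radix = 100000, open_age = 110L,
                                n = NULL, seed = NULL) {
  ages <- 0:open_age
  if (is.null(premature)) {
    stopifnot(alpha == 0)
    premature <- senescent
  }
  adult <- mixture_cell_probs(alpha, premature, senescent, ages)
  if (eta > 0) {
    infp <- diff(2 * stats::pnorm(c(ages, open_age + 1) / infant_scale) - 1)
    probs <- eta * infp / sum(infp) + (1 - eta) * adult
  } else {
    probs <- adult
  }
  if (!is.null(n)) {
    if (!is.null(seed)) set.seed(seed)
    counts <- as.numeric(stats::rmultinom(1L, size = n, prob = probs))
    probs <- counts / n
  }
  dx <- .round_to_total(probs * radix, radix)
  lx <- radix - cumsum(c(0, dx[-length(dx)]))
  Lx <- lx - dx / 2
  mx <- ifelse(Lx > 0, dx / Lx, 0)
  lifetable(population_id, year, ages, dx, lx, Lx, mx, radix = radix)
}

#' Write a life table in HMD 1x1 layout
#'
#' Emits a text file that [read_hmd_lifetable()] parses back: title line,
#' blank line, `Year Age mx qx ax lx dx Lx Tx ex` header, one
#' whitespace-separated row per age, `"110+"` for the open interval.
#' Several tables (e.g. different years of one population) can be written
#' into one file by passing a list.
#'
#' @param table A [lifetable()] or a list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @examples
#' tab <- synthetic_lifetable(sn_cp(80, 10, -0.4))
#' f <- tempfile(fileext = ".txt")
#' write_hmd_lifetable(tab, f)
#' @export
write_hmd_lifetable <- function(table, path) {
  tables <- if (inherits(table, "lifetable")) list(table) else table
  for (tb in tables) stopifnot(inherits(tb, "lifetable"))
  hdr <- c(sprintf("%s, Life tables (period 1x1)", tables[[1L]]$population_id),
           "",
           sprintf("  %-6s %6s %10s %10s %6s %10s %10s %12s %14s %8s",
                   "Year", "Age", "mx", "qx", "ax", "lx", "dx", "Lx",
                   "Tx", "ex"))
  rows <- unlist(lapply(tables, function(tb) {
    nn <- length(tb$ages)
    age_lab <- c(as.character(tb$ages[-nn]), paste0(tb$open_age, "+"))
    qx <- ifelse(tb$lx > 0, pmin(1, tb$dx / tb$lx), 0)
    Tx <- rev(cumsum(rev(tb$Lx)))
    ex <- ifelse(tb$lx > 0, Tx / tb$lx, 0)
    sprintf("  %-6d %6s %10.6f %10.6f %6.2f %10.1f %10.1f %12.1f %14.1f %8.2f",
            tb$year, age_lab, tb$mx, qx, 0.5, tb$lx, tb$dx, tb$Lx, Tx, ex)
  }))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Preset synthetic scenarios
#'
#' Three fixed scenarios used throughout validation:
#' \describe{
#'   \item{`high_longevity`}{Four countries sharing a senescent component
#'     with mean 87, sd 6, skewness -0.5; premature weights 0.05-0.30.}
#'   \item{`medium_longevity`}{Same structure with senescent mean 80,
#'     sd 7.}
#'   \item{`france_vs_usa`}{Two countries: one with a right-shifted,
#'     compressed senescent curve and a small premature bump; one with a
#'     left-shifted, dispersed senescent curve and a large premature
#'     bump. Because the hierarchical model assumes a single shared
#'     senescent curve, this preset is fit one population at a time with
#'     the relative model.}
#' }
#' Deaths per country default to 100000 and seeds are fixed, so presets
#' regenerate identically.
#'
#' @return Named list of [synthetic_scenario()] objects.
#' @examples
#' names(preset_scenarios())
#' @export
preset_scenarios <- function() {
  country <- function(label, alpha, mu, sigma, gamma, n = 100000L,
                      senescent = NULL) {
    list(label = label, alpha = alpha, premature = sn_cp(mu, sigma, gamma),
         n = n, senescent = senescent)
  }
  list(
    high_longevity = synthetic_scenario(
      "high_longevity",
      countries = list(country("HL-A", 0.05, 58, 11, 0.30),
                       country("HL-B", 0.12, 60, 10, 0.20),
                       country("HL-C", 0.20, 62, 10, 0.10),
                       country("HL-D", 0.30, 59, 12, 0.25)),
      senescent = sn_cp(87, 6, -0.5), seed = 20260101L),
    medium_longevity = synthetic_scenario(
      "medium_longevity",
      countries = list(country("ML-A", 0.08, 55, 11, 0.30),
                       country("ML-B", 0.15, 57, 10, 0.20),
                       country("ML-C", 0.25, 56, 11, 0.15),
                       country("ML-D", 0.35, 54, 12, 0.25)),
      senescent = sn_cp(80, 7, -0.4), seed = 20260202L),
    france_vs_usa = synthetic_scenario(
      "france_vs_usa",
      countries = list(
        country("FRA-like", 0.08, 62, 8, 0.10,
                senescent = sn_cp(89, 4.5, -0.5)),
        country("USA-like", 0.28, 58, 12, 0.25,
                senescent = sn_cp(82, 8, -0.3))),
      senescent = sn_cp(87, 6, -0.5), seed = 20260303L))
}
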