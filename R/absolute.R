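# Absolute (threshold-based) premature-mortality measures: banded death
# rates, the fraction of deaths below an age threshold, and potential
# years of life lost (PYLL) against a standard life expectancy.

#' Banded life-table death rate
#'
#' The stationary-population death rate over an inclusive age band,
#' computed inside the life table as total deaths over total person-years,
#' \eqn{\sum_{x=l}^{u} d_x / \sum_{x=l}^{u} L_x}. Because life tables are
#' already standardized with respect to age structure, no external
#' standard population is involved. With `lower = 30, upper = 64` this is
#' the adult mortality rate commonly used as an absolute
#' premature-mortality measure.
#'
#' @param table A [lifetable()].
#' @param lower,upper Inclusive age band (defaults 30 and 64).
#' @return Deaths per person-year (a small positive number).
#' @examples
#' tab <- synthetic_lifetable(sn_cp(80, 10, -0.4))
#' banded_death_rate(tab, 30, 64)
#' @export
banded_death_rate <- function(table, lower = 30L, upper = 64L) {
  stopifnot(inherits(table, "lifetable"), lower < upper)
  if (lower < table$ages[1L] || upper > table$open_age) {
    stop("age band outside the table's range", call. = FALSE)
  }
  sel <- table$ages >= lower & table$ages <= upper
  py <- sum(table$Lx[sel])
  if (py <= 0) stop("no person-years lived in the age band", call. = FALSE)
  sum(table$dx[sel]) / py
}

#' Fraction of deaths below an age threshold
#'
#' The share of the death distribution at ages strictly below `threshold`
#' — the classic absolute definition in which every death under a fixed
#' age (65, 70 or 75 are typical) counts as premature. Comparing
#' thresholds on the same populations exposes how rankings can reverse
#' with the choice of cut-off.
#'
#' @param density A [death_density()].
#' @param threshold Age threshold in years.
#' @return Proportion in `[0, 1]`, non-decreasing in `threshold`.
#' @examples
#' d <- death_density(5:110, mixture_cell_probs(0.2, sn_cp(60, 10, 0.3),
#'                                              sn_cp(87, 6, -0.5)))
#' premature_fraction_below(d, 65)
#' @export
premature_fraction_below <- function(density, threshold) {
  stopifnot(inherits(density, "death_density"))
  sum(density$weights[density$ages < threshold])
}

#' Potential years of life lost
#'
#' Multiplies deaths at each age by the years remaining to a standard
#' life expectancy (SLE): \eqn{\sum_x d_x \max(0, \mathrm{SLE} - (x +
#' a))}, with `a` the within-interval timing of deaths (default
#' mid-interval, 0.5 years). Deaths at ages at or above the SLE contribute
#' nothing. Common SLE choices are 86.01 (GBD 2010) and 91.93 (WHO Global
#' Health Estimates). The result is on the scale of the life-table cohort
#' (radix), i.e. years lost per `radix` newborns.
#'
#' @param table A [lifetable()].
#' @param sle Standard life expectancy in years (default 86.01).
#' @param ax_offset Mean age at death within the single-year interval
#'   (default 0.5).
#' @return Total potential years of life lost (years).
#' @examples
#' tab <- synthetic_lifetable(sn_cp(80, 10, -0.4))
#' pyll(tab)
#' pyll(tab, sle = 91.93)
#' @export
pyll <- function(table, sle = 86.01, ax_offset = 0.5) {
  stopifnot(inherits(table, "lifetable"), sle > 0)
  sum(table$dx * pmax(0, sle - (table$ages + ax_offset)))
}

#' Absolute measures for a set of life tables
#'
#' Convenience wrapper computing, per table: the banded death rate, the
#' fraction of deaths below each threshold, and PYLL.
#'
#' @param tables A [lifetable()] or list of them.
#' @param thresholds Age thresholds for the below-threshold fractions.
#' @param sle Standard life expectancy for PYLL.
#' @param band Length-2 integer vector, inclusive band for the death rate.
#' @return A data frame with one row per table.
#' @export
absolute_measures <- function(tables, thresholds = c(65, 70, 75),
                              sle = 86.01, band = c(30L, 64L)) {
  if (inherits(tables, "lifetable")) tables <- list(tables)
  rows <- lapply(tables, function(tb) {
    dd <- to_death_density(tb, min_age = tb$ages[1L])
    fr <- vapply(thresholds, function(th) premature_fraction_below(dd, th), 0)
    names(fr) <- paste0("frac_below_", thresholds)
    cbind(data.frame(population = tb$population_id, year = tb$year,
                     m_band = banded_death_rate(tb, band[1L], band[2L]),
                     pyll = pyll(tb, sle)),
          as.data.frame(as.list(fr)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
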