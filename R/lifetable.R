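# Life-table input: HMD 1x1 period layout, age-at-death distributions,
# and pooling of countries into a group-level "super-country".

#' Life-table object
#'
#' A single population-year period life table on a single-year age grid
#' `0..open_age`, with the open interval's deaths assigned to the terminal
#' age. The `dx` column (life-table deaths, radix-scaled) is the input to
#' all premature-mortality measures in this package: unlike observed death
#' counts, life-table deaths are standardized with respect to the
#' population's age structure.
#'
#' @param population_id Character label (e.g. country code).
#' @param year Integer calendar year.
#' @param ages Integer vector `0:open_age` (step 1).
#' @param dx Life-table deaths at each age; sums to `radix` (within the
#'   0.5 rounding slack of published tables).
#' @param lx Survivors at exact age; `lx[1] == radix`, non-increasing.
#' @param Lx Person-years lived in each age interval.
#' @param mx Central death rate in each age interval.
#' @param radix Starting cohort size (conventionally 100000).
#' @return An object of class `"lifetable"`.
#' @seealso [read_hmd_lifetable()], [to_death_density()]
#' @export
lifetable <- function(population_id, year, ages, dx, lx, Lx, mx,
                      radix = 100000) {
  n <- length(ages)
  stopifnot(length(dx) == n, length(lx) == n, length(Lx) == n,
            length(mx) == n, radix > 0)
  if (n < 2L || ages[1L] != 0L || any(diff(ages) != 1L)) {
    stop("'ages' must be 0..open_age in steps of 1", call. = FALSE)
  }
  if (abs(sum(dx) - radix) > 0.5) {
    stop(sprintf("sum(dx) = %.2f differs from radix %g by more than 0.5",
                 sum(dx), radix), call. = FALSE)
  }
  if (abs(lx[1L] - radix) > 0.5) {
    stop("lx[1] must equal the radix", call. = FALSE)
  }
  if (any(diff(lx) > 1e-6)) {
    stop("lx must be non-increasing in age", call. = FALSE)
  }
  structure(
    list(population_id = as.character(population_id),
         year = as.integer(year), ages = as.integer(ages),
         dx = as.numeric(dx), lx = as.numeric(lx), Lx = as.numeric(Lx),
         mx = as.numeric(mx), radix = radix,
         open_age = as.integer(ages[n])),
    class = "lifetable")
}

#' @export
print.lifetable <- function(x, ...) {
  cat(sprintf("Life table: %s %d, ages 0-%d+ (radix %g)\n",
              x$population_id, x$year, x$open_age, x$radix))
  cat(sprintf("  sum(dx) = %.1f, e0 = %.2f\n", sum(x$dx),
              sum(x$Lx) / x$radix))
  invisible(x)
}

#' @export
as.data.frame.lifetable <- function(x, ...) {
  data.frame(age = x$ages, dx = x$dx, lx = x$lx, Lx = x$Lx, mx = x$mx)
}

.hmd_columns <- c("Year", "Age", "mx", "qx", "ax", "lx", "dx", "Lx",
                  "Tx", "ex")

#' Read an HMD-layout 1x1 period life table
#'
#' Parses a text file in the Human Mortality Database 1x1 period life-table
#' layout (title line, blank line, header row `Year Age mx qx ax lx dx Lx
#' Tx ex`, whitespace-separated data rows; age `"110+"` for the open
#' interval) and returns the requested year as a [lifetable()]. The open
#' interval is represented as the single terminal age.
#'
#' @param path Path to the life-table file.
#' @param year Calendar year to extract.
#' @return A `"lifetable"` object.
#' @examples
#' tab <- synthetic_lifetable(sn_cp(80, 10, -0.4), seed = 1)
#' f <- tempfile(fileext = ".txt")
#' write_hmd_lifetable(tab, f)
#' read_hmd_lifetable(f, tab$year)
#' @export
read_hmd_lifetable <- function(path, year) {
  if (!file.exists(path)) {
    stop("life-table file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^\\s*Year\\s+Age\\s", lines)[1L]
  if (is.na(hdr)) {
    stop("not an HMD 1x1 life-table layout (no 'Year Age ...' header row): ",
         path, call. = FALSE)
  }
  pop_id <- sub(",.*$", "", trimws(lines[1L]))
  body_idx <- seq.int(hdr + 1L, length(lines))
  body <- trimws(lines[body_idx])
  keep <- nzchar(body)
  body <- body[keep]
  body_idx <- body_idx[keep]
  toks <- strsplit(body, "\\s+")
  nfield <- lengths(toks)
  if (any(nfield != 10L)) {
    bad <- which(nfield != 10L)[1L]
    stop(sprintf("malformed life-table row at line %d: expected 10 columns, found %d",
                 body_idx[bad], nfield[bad]), call. = FALSE)
  }
  m <- matrix(unlist(toks), ncol = 10L, byrow = TRUE)
  colnames(m) <- .hmd_columns
  yr <- as.integer(m[, "Year"])
  sel <- yr == as.integer(year)
  if (!any(sel)) {
    stop(sprintf("year not found: %d (file has %d-%d)", as.integer(year),
                 min(yr), max(yr)), call. = FALSE)
  }
  m <- m[sel, , drop = FALSE]
  open <- grepl("\\+$", m[, "Age"])
  ages <- as.integer(sub("\\+$", "", m[, "Age"]))
  num <- function(col) suppressWarnings(as.numeric(gsub(",", "", m[, col])))
  lx <- num("lx")
  lifetable(population_id = pop_id, year = year, ages = ages,
            dx = num("dx"), lx = lx, Lx = num("Lx"), mx = num("mx"),
            radix = lx[1L])
}

#' Age-at-death distribution (death density)
#'
#' A normalized distribution of life-table deaths over a single-year age
#' grid starting at `min_age`. The default `min_age = 5` discards infant
#' and child mortality, so the density describes only deaths above age 5 —
#' the support on which the premature/senescent mixture models operate.
#' `effective_n` is the pseudo-count used by the multinomial likelihood
#' (by default the radix-scaled death count above `min_age`).
#'
#' @param ages Integer grid starting at `min_age`, step 1.
#' @param weights Nonnegative proportions summing to 1.
#' @param min_age Minimum age of the grid.
#' @param effective_n Positive pseudo-count (multinomial sample size).
#' @return An object of class `"death_density"`.
#' @export
death_density <- function(ages, weights, min_age = ages[1L],
                          effective_n = 1e5) {
  stopifnot(length(ages) == length(weights), effective_n > 0)
  if (ages[1L] != min_age) stop("ages[1] must equal min_age", call. = FALSE)
  if (any(diff(ages) != 1L)) stop("ages must step by 1", call. = FALSE)
  if (any(weights < 0)) stop("weights must be nonnegative", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("weights must sum to 1 (within 1e-9)", call. = FALSE)
  }
  structure(list(ages = as.integer(ages), weights = as.numeric(weights),
                 min_age = as.integer(min_age),
                 effective_n = as.numeric(effective_n)),
            class = "death_density")
}

#' @export
print.death_density <- function(x, ...) {
  mode_age <- x$ages[which.max(x$weights)]
  cat(sprintf("Death density: ages %d-%d, modal age %d, effective n %.0f\n",
              x$ages[1L], x$ages[length(x$ages)], mode_age, x$effective_n))
  invisible(x)
}

#' @export
as.data.frame.death_density <- function(x, ...) {
  data.frame(age = x$ages, weight = x$weights)
}

#' Extract the age-at-death distribution from a life table
#'
#' Normalizes the `dx` column over ages at or above `min_age`. With the
#' default `min_age = 5` the result is the distribution of deaths above
#' age 5, excluding infant and child mortality.
#'
#' @param table A [lifetable()].
#' @param min_age Lowest age retained (default 5).
#' @param effective_n Multinomial pseudo-count; defaults to the life-table
#'   death count above `min_age`.
#' @return A [death_density()].
#' @examples
#' tab <- synthetic_lifetable(sn_cp(80, 10, -0.4), seed = 1)
#' d <- to_death_density(tab)
#' sum(d$weights)  # 1
#' @export
to_death_density <- function(table, min_age = 5L, effective_n = NULL) {
  stopifnot(inherits(table, "lifetable"))
  if (min_age < table$ages[1L] || min_age >= table$open_age) {
    stop("min_age outside the table's age range", call. = FALSE)
  }
  sel <- table$ages >= min_age
  dx <- table$dx[sel]
  tot <- sum(dx)
  if (tot <= 0) {
    stop("all dx above min_age are zero; no death distribution", call. = FALSE)
  }
  death_density(ages = table$ages[sel], weights = dx / tot,
                min_age = as.integer(min_age),
                effective_n = if (is.null(effective_n)) tot else effective_n)
}

#' Pool countries into a "super-country" death density
#'
#' Averages the member densities age by age with equal country weights and
#' renormalizes, giving the group-level reference distribution used when a
#' pooled benchmark for senescent mortality is wanted. The pooled
#' `effective_n` is the sum of the members'.
#'
#' @param densities List of [death_density()] objects on a common grid.
#' @return A [death_density()].
#' @examples
#' d1 <- death_density(5:10, rep(1/6, 6), effective_n = 10)
#' d2 <- death_density(5:10, c(0, 0, 0, 0, 0, 1), effective_n = 20)
#' pool_group(list(d1, d2))
#' @export
pool_group <- function(densities) {
  stopifnot(is.list(densities), length(densities) >= 1L)
  for (d in densities) stopifnot(inherits(d, "death_density"))
  ref <- densities[[1L]]
  for (d in densities[-1L]) {
    if (!identical(d$ages, ref$ages) || d$min_age != ref$min_age) {
      stop("all densities must share the same age grid and min_age",
           call. = FALSE)
    }
  }
  w <- rowMeans(vapply(densities, `[[`, numeric(length(ref$ages)), "weights"))
  death_density(ages = ref$ages, weights = w / sum(w),
                min_age = ref$min_age,
                effective_n = sum(vapply(densities, `[[`, 0, "effective_n")))
}

#' Write a death density as CSV
#'
#' Two columns, `age` and `weight`.
#'
#' @param density A [death_density()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_density_csv <- function(density, path) {
  stopifnot(inherits(density, "death_density"))
  utils::write.csv(as.data.frame(density), path, row.names = FALSE)
  invisible(path)
}
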