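# Fisher wave-of-advance arithmetic: r = 2*sqrt(g*m) links the frontier speed
# r (km/yr) of an expanding population to its growth rate g (per year) and
# migration parameter m. Values propagate unrounded through chained
# computations; rounding belongs to the reporting layer (see print.wave_model).

#' Rate of advance of a population frontier
#'
#' @param distance_km Distance covered, km.
#' @param elapsed_years Elapsed time, years (> 0).
#' @return km per year (unrounded; report to 2 decimals).
#' @examples
#' round(rate_of_advance(5000, 9000), 2) # 0.56
#' @export
rate_of_advance <- function(distance_km, elapsed_years) {
  stopifnot(distance_km >= 0)
  if (elapsed_years <= 0) stop("elapsed time must be positive")
  distance_km / elapsed_years
}

#' Migration rate from Fisher's wave-of-advance relation
#'
#' Inverts r = 2*sqrt(g*m) to m = r^2 / (4g). (Fisher's diffusion parameter is
#' dimensionally km^2/yr; the km/yr figure conventionally quoted is reproduced
#' as printed.)
#'
#' @param r Rate of advance, km/yr.
#' @param g Population growth rate per year (> 0).
#' @return m (unrounded; report to 1 decimal).
#' @examples
#' round(migration_rate(0.56, 0.007), 1) # 11.2
#' @export
migration_rate <- function(r, g) {
  stopifnot(all(r >= 0))
  if (any(g <= 0)) stop("growth rate must be positive")
  r^2 / (4 * g)
}

#' Rate of advance from growth and migration rates
#'
#' Forward direction of Fisher's relation: r = 2*sqrt(g*m); exact inverse of
#' [migration_rate()].
#'
#' @param g Growth rate per year (>= 0).
#' @param m Migration rate (>= 0).
#' @return km per year.
#' @examples
#' advance_from_migration(0.007, 11.2) # 0.56
#' @export
advance_from_migration <- function(g, m) {
  stopifnot(all(g >= 0), all(m >= 0))
  2 * sqrt(g * m)
}

#' Years separating two tree nodes from their mutation gap
#'
#' @param n_mutations Number of mutations separating the nodes (>= 0).
#' @param years_per_mutation Clock calibration (default 3,624 yr/mutation).
#' @return Years (narrative reports round to the nearest thousand).
#' @examples
#' node_gap_years(2) # 7248, "about 7,000"
#' @export
node_gap_years <- function(n_mutations, years_per_mutation = SOARES_YEARS_PER_MUTATION) {
  stopifnot(n_mutations >= 0, years_per_mutation > 0)
  n_mutations * years_per_mutation
}

#' Transform a time gap into a radius at a constant rate of advance
#'
#' @param gap_years Time gap, years.
#' @param r Rate of advance, km/yr (>= 0).
#' @return km (narrative reports round to the nearest thousand).
#' @examples
#' distance_from_gap(7248, 5000 / 9000) # ~4027, "about 4,000"
#' @export
distance_from_gap <- function(gap_years, r) {
  stopifnot(gap_years >= 0, r >= 0)
  gap_years * r
}

#' Full wave-of-advance derivation chain
#'
#' From a coastal distance and the elapsed time between two radiation ages,
#' derives the rate of advance, inverts Fisher's relation for the migration
#' rate at growth rate \code{g}, converts a mutation gap between two nodes
#' into years, and transforms that gap into a geographic radius.
#'
#' Two migration figures are kept: \code{m} from the unrounded rate of advance,
#' and \code{m_reported} from the two-decimal rate (the form conventionally
#' quoted, e.g. 0.56 km/yr with g = 0.007 gives 11.2).
#'
#' @param distance_km Coastal distance, km.
#' @param elapsed_years Elapsed time between the two radiations, years.
#' @param g Growth rate per year.
#' @param n_mutations Mutation gap between the two nodes (default 2).
#' @param years_per_mutation Clock (default 3,624 yr/mutation).
#' @return Object of class \code{wave_model}.
#' @examples
#' fisher_wave(5000, 9000, 0.007)
#' @export
fisher_wave <- function(distance_km, elapsed_years, g, n_mutations = 2,
                        years_per_mutation = SOARES_YEARS_PER_MUTATION) {
  r <- rate_of_advance(distance_km, elapsed_years)
  r_rep <- round(r, 2)
  gap <- node_gap_years(n_mutations, years_per_mutation)
  structure(list(
    distance_km = distance_km, elapsed_years = elapsed_years, g = g,
    r = r, r_reported = r_rep,
    m = migration_rate(r, g), m_reported = migration_rate(r_rep, g),
    n_mutations = n_mutations, years_per_mutation = years_per_mutation,
    gap_years = gap, radius_km = distance_from_gap(gap, r)
  ), class = "wave_model")
}

#' @export
print.wave_model <- function(x, ...) {
  cat("Fisher wave-of-advance derivation\n",
      "  rate of advance  r = ", x$distance_km, " km / ", x$elapsed_years,
      " yr = ", format(round(x$r_reported, 2), nsmall = 2), " km/yr\n",
      "  migration rate   m = r^2/(4g) = ",
      format(round(x$m_reported, 1), nsmall = 1), " (g = ", x$g,
      "/yr; unrounded chain: ", format(round(x$m, 1), nsmall = 1), ")\n",
      "  node gap         ", x$n_mutations, " mutations x ",
      x$years_per_mutation, " yr = ", round(x$gap_years),
      " yr (about ", format(round(x$gap_years, -3), big.mark = ","), ")\n",
      "  radius           ", round(x$radius_km), " km (about ",
      format(round(x$radius_km, -3), big.mark = ","), ")\n", sep = "")
  invisible(x)
}
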