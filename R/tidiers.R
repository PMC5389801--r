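#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a niche analysis into the per-species table
#'
#' @param x a `niche_analysis`.
#' @param ... unused.
#' @return tibble with one row per species: tolerance limits, counts, the
#'   three niche measures, potential extent, test p-values and significance
#'   flags, and an exclusion reason code where a stage was skipped.
#' @method tidy niche_analysis
#' @export
tidy.niche_analysis <- function(x, ...) {
  x$per_species
}

#' One-row summary of a niche analysis
#'
#' @param x a `niche_analysis`.
#' @param ... unused.
#' @return one-row tibble with the global aggregates: species and test
#'   tallies, overall fraction of occurrences inside the fundamental niches,
#'   the existing-on-fundamental fit, and the KS comparison against the
#'   random-interval volume null.
#' @method glance niche_analysis
#' @export
glance.niche_analysis <- function(x, ...) {
  g <- x$global
  tibble::tibble(
    n_species = g$n_species,
    n_tested = g$n_tested,
    n_with_min_points = g$n_with_min_points,
    n_with_realized = g$n_with_realized,
    overall_fraction_inside = g$overall_fraction_inside,
    n_significant_inside = g$n_significant_inside,
    n_significant_inside_min_points = g$n_significant_inside_min_points,
    n_significant_outside = g$n_significant_outside,
    fit_slope = g$fit$slope,
    fit_intercept = g$fit$intercept,
    fit_r_squared = g$fit$r_squared,
    ks_statistic = g$ks$statistic,
    ks_p_value = g$ks$p_value,
    max_potential_area = g$max_potential_area,
    null_volume_mean = g$null_volume_mean
  )
}
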