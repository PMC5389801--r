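#' Read a species tolerance table
#'
#' Physiological tolerance intervals are the fundamental-niche proxy: the set
#' of temperatures between a species' critical/lethal lower and upper limits.
#'
#' @param path CSV with header `species,t_min,t_max` (degrees C); a 2D table
#'   adds `u_min,u_max` for the second climate axis.
#' @return validated tibble.
#' @export
read_tolerances <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("tolerance file not found: %s", path),
          class = "nichebounds_io_error")
  }
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_tolerances(tibble::as_tibble(tab))
}

validate_tolerances <- function(tol) {
  need <- c("species", "t_min", "t_max")
  if (!all(need %in% names(tol))) {
    abort("tolerance table must have columns species, t_min, t_max.",
          class = "nichebounds_format_error")
  }
  check_interval(tol$t_min, tol$t_max)
  if (all(c("u_min", "u_max") %in% names(tol))) {
    check_interval(tol$u_min, tol$u_max)
  }
  tol
}

check_interval <- function(t_min, t_max) {
  if (any(!is.finite(t_min)) || any(!is.finite(t_max))) {
    abort("tolerance limits must be finite.",
          class = "nichebounds_validation_error")
  }
  if (any(t_min >= t_max)) {
    abort("tolerance intervals require t_min < t_max.",
          class = "nichebounds_validation_error")
  }
  invisible(TRUE)
}

#' Fundamental-niche measure
#'
#' The measure of a tolerance-interval fundamental niche is simply its range,
#' `t_max - t_min`, in degrees C.
#'
#' @param t_min,t_max tolerance limits (vectorized).
#' @return numeric vector of interval widths.
#' @export
nf_measure <- function(t_min, t_max) {
  check_interval(t_min, t_max)
  t_max - t_min
}

#' Standardize temperatures to a common fundamental-niche scale
#'
#' Maps a temperature to `(value - t_min) / (t_max - t_min) - 1/2`, so every
#' fundamental niche becomes the interval `[-1/2, +1/2]` and occurrences from
#' different species can share one histogram axis. A value lies inside the
#' tolerance interval exactly when its standardized value lies in
#' `[-0.5, 0.5]`.
#'
#' @param value temperature(s), degrees C.
#' @param t_min,t_max tolerance limits.
#' @return unitless standardized temperature(s).
#' @export
standardize_temperature <- function(value, t_min, t_max) {
  check_interval(t_min, t_max)
  (value - t_min) / (t_max - t_min) - 0.5
}

#' Proportion of available climate inside a tolerance interval
#'
#' Integrates the climate kernel density over `[t_min, t_max]` (clipped to the
#' kernel support): the proportional measure of the existing niche, and the
#' success probability of the binomial random-placement null.
#'
#' @param kernel the climate [env_kernel()].
#' @param t_min,t_max tolerance limits (vectorized over species).
#' @return fraction(s) in `[0, 1]`.
#' @export
existing_proportion <- function(kernel, t_min, t_max) {
  check_interval(t_min, t_max)
  vapply(seq_along(t_min),
         function(i) kernel_mass(kernel, t_min[i], t_max[i]),
         numeric(1))
}

#' Convert an existing-niche proportion to degrees C
#'
#' Two conventions are implemented. `"intersection"` (default) reports the
#' length of the tolerance interval clipped to the available climate range
#' `[min E, max E]` — it reproduces interval-intersection length exactly under
#' a uniform climate and can never exceed the fundamental-niche measure, so
#' the inclusion chain of measures is preserved. `"proportion_range"` reports
#' `proportion * (max E - min E)`.
#'
#' @param proportion kernel mass inside the tolerance interval (vectorized).
#' @param env_range [environment_range()] tibble or `c(lo, hi)`.
#' @param t_min,t_max tolerance limits; required for the `"intersection"`
#'   convention.
#' @param convention `"intersection"` or `"proportion_range"`.
#' @return existing-niche measure(s), degrees C.
#' @export
existing_measure <- function(proportion, env_range, t_min = NULL, t_max = NULL,
                             convention = c("intersection", "proportion_range")) {
  convention <- match.arg(convention)
  if (any(!is.finite(proportion)) || any(proportion < 0) || any(proportion > 1)) {
    abort("`proportion` must lie in [0, 1].", class = "nichebounds_input_error")
  }
  r <- as_range_pair(env_range)
  if (convention == "proportion_range") {
    return(proportion * (r[2L] - r[1L]))
  }
  if (is.null(t_min) || is.null(t_max)) {
    abort("intersection convention needs t_min and t_max.",
          class = "nichebounds_input_error")
  }
  check_interval(t_min, t_max)
  pmax(pmin(t_max, r[2L]) - pmax(t_min, r[1L]), 0)
}

#' Fit a realized-niche kernel to occurrence climates
#'
#' Smooth kernels over the climates at a species' occurrences are a simple
#' realized-niche model; they are only fitted for species with at least
#' `min_points` annotated occurrences (default 5), otherwise `NULL` is
#' returned and the species carries no realized measure.
#'
#' @param values occurrence climate values, degrees C.
#' @param min_points minimum number of values required.
#' @return an [env_kernel()] or `NULL`.
#' @export
fit_realized_kernel <- function(values, min_points = 5L) {
  values <- values[is.finite(values)]
  if (length(values) < min_points) return(NULL)
  if (stats::sd(values) == 0) {
    abort("occurrence climates are constant; realized kernel is degenerate.",
          class = "nichebounds_degenerate_sample")
  }
  # the >= 10 floor of the generic fitter does not apply here: the realized
  # threshold is its own contract
  x <- matrix(values, ncol = 1L)
  h <- bw.nrd0(values)
  k <- fit_environment_kernel_small(x, h)
  k
}

fit_environment_kernel_small <- function(x, h) {
  lo <- min(x) - 4 * h
  hi <- max(x) + 4 * h
  dens <- local({
    centers <- x[, 1L]; hh <- h
    function(at) gauss_mix_density(as.numeric(at), centers, hh)
  })
  env_kernel(dens, c(lo, hi), h, sample_size = nrow(x), sample = x)
}

#' Realized-niche measure by kernel overlap
#'
#' Integrates the minimum of the realized (occurrence) kernel and the climate
#' kernel over the fundamental niche `[t_min, t_max]` and multiplies by the
#' observed range of occurrence temperatures: an estimate, in degrees C, of
#' how much of the available niche space the occurrences actually cover.
#'
#' @param realized species occurrence [env_kernel()].
#' @param climate climate [env_kernel()].
#' @param t_min,t_max tolerance limits.
#' @param occ_range observed occurrence temperature range, degrees C
#'   (see [occurrence_range()]).
#' @return realized-niche measure, degrees C, non-negative.
#' @export
realized_measure <- function(realized, climate, t_min, t_max, occ_range) {
  check_interval(t_min, t_max)
  check_number(occ_range, "occ_range")
  if (occ_range < 0) {
    abort("`occ_range` must be non-negative.", class = "nichebounds_input_error")
  }
  occ_range * kernel_overlap_mass(realized, climate, t_min, t_max)
}

#' Observed occurrence temperature range
#'
#' The span, in degrees C, of a species' occurrence climates. By default only
#' values inside the tolerance interval contribute (`within = TRUE`): the
#' realized measure quantifies the part of the realized niche inside the
#' fundamental niche, and restricting the range keeps one stray record from
#' inflating it. `within = FALSE` uses all values.
#'
#' @param values occurrence climate values, degrees C.
#' @param t_min,t_max tolerance limits (used when `within = TRUE`).
#' @param within restrict to values inside `[t_min, t_max]`?
#' @return max - min of the contributing values; `NA` if none.
#' @export
occurrence_range <- function(values, t_min = NULL, t_max = NULL, within = TRUE) {
  values <- values[is.finite(values)]
  if (within) {
    check_interval(t_min, t_max)
    values <- values[values >= t_min & values <= t_max]
  }
  if (length(values) == 0L) return(NA_real_)
  max(values) - min(values)
}

#' Count occurrences inside the fundamental niche
#'
#' Counts how many occurrence climates fall inside the closed interval
#' `[t_min, t_max]` (tolerance limits are survivable, so the boundary counts
#' as inside).
#'
#' @param values occurrence climate values, degrees C.
#' @param t_min,t_max tolerance limits.
#' @return tibble with `k` (inside) and `n` (total).
#' @export
count_inside <- function(values, t_min, t_max) {
  check_interval(t_min, t_max)
  values <- values[is.finite(values)]
  tibble::tibble(k = sum(values >= t_min & values <= t_max),
                 n = length(values))
}

#' Potential geographic extent of a tolerance interval
#'
#' Hutchinson's duality read in geographic space: the number of grid cells
#' whose climate lies inside the tolerance interval bounds the size of the
#' species' potential distribution; the area is cells times the (equal) cell
#' area.
#'
#' @param field a [climate_field()].
#' @param t_min,t_max tolerance limits (vectorized over species).
#' @return tibble with `cells` and `area_km2` per interval.
#' @export
potential_extent <- function(field, t_min, t_max) {
  stopifnot(inherits(field, "climate_field"))
  check_interval(t_min, t_max)
  v <- field[[attr(field, "value_cols")[1L]]]
  cell_area <- field$area_km2[1L]
  cells <- vapply(seq_along(t_min),
                  function(i) sum(v >= t_min[i] & v <= t_max[i]),
                  integer(1))
  tibble::tibble(cells = cells, area_km2 = cells * cell_area)
}

#' Kernel mass inside a 2D tolerance box
#'
#' Integrates a 2D product-kernel density over an axis-aligned box (clipped to
#' the kernel support) by tensor-grid composite Simpson quadrature. For
#' Gaussian sample kernels the grid evaluation uses the separable per-axis
#' kernel matrices, so large samples stay fast.
#'
#' @param kernel a 2D [env_kernel()].
#' @param box numeric `c(x_lo, x_hi, y_lo, y_hi)` or a one-row data frame with
#'   `t_min, t_max, u_min, u_max`.
#' @param n_intervals Simpson subintervals per axis (even; default 256).
#' @return the box probability mass, clipped to `[0, 1]`.
#' @export
box_proportion_2d <- function(kernel, box, n_intervals = 256L) {
  stopifnot(inherits(kernel, "env_kernel"))
  if (kernel$dim != 2L) {
    abort("box_proportion_2d() expects a 2D kernel.",
          class = "nichebounds_input_error")
  }
  if (is.data.frame(box)) {
    box <- c(box$t_min[1L], box$t_max[1L], box$u_min[1L], box$u_max[1L])
  }
  box <- as.numeric(box)
  check_interval(box[1L], box[2L]); check_interval(box[3L], box[4L])
  a1 <- max(box[1L], kernel$support[1L, 1L])
  b1 <- min(box[2L], kernel$support[1L, 2L])
  a2 <- max(box[3L], kernel$support[2L, 1L])
  b2 <- min(box[4L], kernel$support[2L, 2L])
  if (b1 <= a1 || b2 <= a2) return(0)
  gx <- seq(a1, b1, length.out = n_intervals + 1L)
  gy <- seq(a2, b2, length.out = n_intervals + 1L)
  wx <- simpson_weights(n_intervals) * (b1 - a1) / n_intervals
  wy <- simpson_weights(n_intervals) * (b2 - a2) / n_intervals
  if (!is.null(kernel$sample)) {
    # separable trick: F = A B' / n with per-axis Gaussian matrices
    A <- dnorm(outer(gx, kernel$sample[, 1L], "-"), sd = kernel$bandwidth[1L])
    B <- dnorm(outer(gy, kernel$sample[, 2L], "-"), sd = kernel$bandwidth[2L])
    val <- drop(t(wx) %*% (A %*% t(B)) %*% wy) / nrow(kernel$sample)
  } else {
    grid <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
    f <- matrix(kernel$density(grid), nrow = length(gx))
    val <- drop(t(wx) %*% f %*% wy)
  }
  if (!is.finite(val)) {
    abort("2D box integration failed to produce a finite value.",
          class = "nichebounds_numerical_error")
  }
  min(max(val, 0), 1)
}
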