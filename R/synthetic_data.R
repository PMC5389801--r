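#' Distribution specifications for the virtual-species generator
#'
#' Small serializable descriptions of univariate distributions, so generator
#' configurations can round-trip through YAML/JSON. Supported: `"normal"`
#' (`mean`, `sd`), `"uniform"` (`min`, `max`), `"lognormal"` (`meanlog`,
#' `sdlog`), `"nbinom"` (`mu`, `size`), `"poisson"` (`lambda`), `"fixed"`
#' (`value`).
#'
#' @param dist distribution name.
#' @param ... its parameters.
#' @return a `dist_spec` list.
#' @export
dist_spec <- function(dist, ...) {
  dist <- match.arg(dist, c("normal", "uniform", "lognormal", "nbinom",
                            "poisson", "fixed"))
  structure(list(dist = dist, params = list(...)), class = "dist_spec")
}

draw_from <- function(spec, n) {
  if (!inherits(spec, "dist_spec")) {
    if (is.list(spec) && !is.null(spec$dist)) {
      spec <- do.call(dist_spec, c(list(spec$dist), spec$params %||% spec[-1]))
    } else {
      abort("expected a dist_spec().", class = "nichebounds_config_error")
    }
  }
  p <- spec$params
  switch(spec$dist,
    normal    = rnorm(n, p$mean, p$sd),
    uniform   = runif(n, p$min, p$max),
    lognormal = rlnorm(n, p$meanlog, p$sdlog),
    nbinom    = rnbinom(n, mu = p$mu, size = p$size),
    poisson   = rpois(n, p$lambda),
    fixed     = rep(p$value, n)
  )
}

dist_mean <- function(spec) {
  p <- spec$params
  switch(spec$dist,
    normal    = p$mean,
    uniform   = (p$min + p$max) / 2,
    lognormal = exp(p$meanlog + p$sdlog^2 / 2),
    nbinom    = p$mu,
    poisson   = p$lambda,
    fixed     = p$value
  )
}

#' Virtual-world configuration
#'
#' Describes the synthetic equal-area climate grid the generator builds: the
#' number of cells, the (common) cell area, a normal-mixture model of the
#' climate values, and the lon/lat window on which cell centroids are laid
#' out. The defaults emulate the scale and shape of a global 10^4 km^2
#' equal-area grid of mean annual temperature: 16,712 cells and a bimodal
#' mixture (a cold mode from high latitudes/elevations, a warm tropical
#' mode).
#'
#' @param n_cells number of grid cells (>= 10); default 16712.
#' @param cell_area_km2 common cell area; default 1e4.
#' @param climate_model list with `weights`, `means`, `sds` of a normal
#'   mixture (degrees C); defaults `0.45/0.55`, `-5/22`, `8/5`.
#' @param lon_range,lat_range window for the centroid lattice, decimal
#'   degrees.
#' @param seed integer seed.
#' @return a `world_config` list.
#' @export
world_config <- function(n_cells = 16712L, cell_area_km2 = 1e4,
                         climate_model = list(weights = c(0.45, 0.55),
                                              means = c(-5, 22),
                                              sds = c(8, 5)),
                         lon_range = c(-30, 30), lat_range = c(-60, 60),
                         seed = 1L) {
  if (!is.finite(n_cells) || n_cells < 10L) {
    abort("`n_cells` must be at least 10.", class = "nichebounds_config_error")
  }
  w <- climate_model$weights
  if (is.null(w) || abs(sum(w) - 1) > 1e-8 || any(w < 0) ||
      length(w) != length(climate_model$means) ||
      length(w) != length(climate_model$sds) ||
      any(climate_model$sds <= 0)) {
    abort("climate_model needs matching weights (summing to 1), means and positive sds.",
          class = "nichebounds_config_error")
  }
  structure(list(n_cells = as.integer(n_cells),
                 cell_area_km2 = cell_area_km2,
                 climate_model = climate_model,
                 lon_range = lon_range, lat_range = lat_range,
                 seed = as.integer(seed)),
            class = "world_config")
}

#' Generate a virtual climate world
#'
#' Draws one climate value per cell i.i.d. from the configured normal mixture
#' and places cell centroids on a regular lon/lat lattice spanning the
#' configured window, so great-circle thinning and value extraction are
#' exercised on meaningful geometry. Deterministic given the config seed.
#'
#' @param config a [world_config()].
#' @return a [climate_field()] with `longitude`/`latitude` centroids.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  n <- config$n_cells
  cm <- config$climate_model
  values <- withr::with_seed(derive_seed(config$seed, 1L), {
    comp <- sample.int(length(cm$weights), n, replace = TRUE, prob = cm$weights)
    rnorm(n, mean = cm$means[comp], sd = cm$sds[comp])
  })
  aspect <- diff(config$lon_range) / diff(config$lat_range)
  ny <- max(2L, ceiling(sqrt(n / aspect)))
  nx <- ceiling(n / ny)
  lon <- seq(config$lon_range[1L], config$lon_range[2L], length.out = nx)
  lat <- seq(config$lat_range[1L], config$lat_range[2L], length.out = ny)
  grid <- expand.grid(longitude = lon, latitude = lat)[seq_len(n), ]
  climate_field(tibble::tibble(
    cell_id = paste0("c", seq_len(n)),
    area_km2 = config$cell_area_km2,
    value = values,
    longitude = grid$longitude,
    latitude = grid$latitude
  ))
}

#' Virtual-species configuration
#'
#' Describes how tolerance intervals and occurrence samples are generated:
#' distributions of niche midpoints and widths (emulating a compilation of
#' critical/lethal thermal limits), a per-species occurrence count
#' distribution (emulating skewed record counts in public occurrence
#' databases), and a contamination fraction — the probability that a record
#' is sampled from the whole world without regard to the species' tolerance
#' (georeferencing error, coarse-grain climate mismatch, buffered
#' microclimates).
#'
#' @param n_species number of virtual species; default 105.
#' @param center_distribution [dist_spec()] of niche midpoints (degrees C).
#' @param width_distribution [dist_spec()] of niche widths (degrees C, must be
#'   positive).
#' @param occurrences_per_species [dist_spec()] of record counts (non-negative
#'   integers; draws are floored at 1).
#' @param contamination fraction in `[0, 1]`; default 0.05.
#' @param seed integer seed.
#' @return a `species_config` list.
#' @export
species_config <- function(n_species = 105L,
                           center_distribution = dist_spec("normal", mean = 15, sd = 6),
                           width_distribution = dist_spec("uniform", min = 20, max = 40),
                           occurrences_per_species = dist_spec("nbinom", mu = 134, size = 0.8),
                           contamination = 0.05,
                           seed = 1L) {
  if (!is.finite(n_species) || n_species < 1L) {
    abort("`n_species` must be at least 1.", class = "nichebounds_config_error")
  }
  if (!is.numeric(contamination) || length(contamination) != 1L ||
      !is.finite(contamination) || contamination < 0 || contamination > 1) {
    abort("`contamination` must lie in [0, 1].",
          class = "nichebounds_config_error")
  }
  if (width_distribution$dist == "uniform" && width_distribution$params$min <= 0) {
    abort("width distribution admits non-positive widths.",
          class = "nichebounds_config_error")
  }
  if (width_distribution$dist == "fixed" && width_distribution$params$value <= 0) {
    abort("width distribution admits non-positive widths.",
          class = "nichebounds_config_error")
  }
  if (width_distribution$dist == "normal") {
    abort("width distribution must have strictly positive support (use uniform, lognormal or fixed).",
          class = "nichebounds_config_error")
  }
  structure(list(n_species = as.integer(n_species),
                 center_distribution = center_distribution,
                 width_distribution = width_distribution,
                 occurrences_per_species = occurrences_per_species,
                 contamination = contamination,
                 seed = as.integer(seed)),
            class = "species_config")
}

#' Generate virtual-species tolerance intervals
#'
#' Draws a midpoint and a width per species and returns the tolerance table
#' `[center - width/2, center + width/2]`; every interval satisfies
#' `t_min < t_max` by construction. Deterministic given the config seed.
#'
#' @param config a [species_config()].
#' @param world optional [climate_field()] (kept for signature symmetry; the
#'   intervals do not depend on the world).
#' @return tibble `species, t_min, t_max`.
#' @export
generate_species <- function(config, world = NULL) {
  stopifnot(inherits(config, "species_config"))
  n <- config$n_species
  withr::with_seed(derive_seed(config$seed, 2L), {
    centers <- draw_from(config$center_distribution, n)
    widths <- draw_from(config$width_distribution, n)
    if (any(widths <= 0)) {
      abort("generated a non-positive niche width; tighten the width distribution.",
            class = "nichebounds_config_error")
    }
    tibble::tibble(
      species = sprintf("vsp%04d", seq_len(n)),
      t_min = centers - widths / 2,
      t_max = centers + widths / 2
    )
  })
}

#' Sample virtual occurrences for one species
#'
#' Each record independently: with probability `1 - contamination` it is drawn
#' uniformly from the cells whose climate lies inside the tolerance interval
#' (a species at climatic equilibrium within its fundamental niche); with
#' probability `contamination` it is drawn uniformly from all cells. Records
#' carry the cell centroid coordinates, the cell climate value, and a hidden
#' ground-truth label (`"niche"` vs `"background"`) that only test code
#' reads.
#'
#' @param t_min,t_max the species' tolerance limits.
#' @param world a [climate_field()] with centroids.
#' @param n number of records.
#' @param contamination fraction in `[0, 1]`.
#' @param seed integer seed.
#' @param species species identifier carried into the output.
#' @return tibble `species, longitude, latitude, value, truth`.
#' @export
sample_occurrences <- function(t_min, t_max, world, n, contamination,
                               seed = 1L, species = "virtual") {
  stopifnot(inherits(world, "climate_field"))
  check_interval(t_min, t_max)
  check_fraction(contamination, "contamination")
  if (n == 0L) {
    return(tibble::tibble(species = character(), longitude = numeric(),
                          latitude = numeric(), value = numeric(),
                          truth = character()))
  }
  v <- world[[attr(world, "value_cols")[1L]]]
  inside <- which(v >= t_min & v <= t_max)
  if (length(inside) == 0L && contamination < 1) {
    abort("no world cell lies inside the tolerance interval; niche-directed sampling is infeasible.",
          class = "nichebounds_infeasible_sampling")
  }
  withr::with_seed(seed, {
    free <- runif(n) < contamination
    # a free draw may still need inside cells when contamination < 1
    cell <- integer(n)
    if (any(free)) cell[free] <- sample.int(nrow(world), sum(free), replace = TRUE)
    if (any(!free)) cell[!free] <- inside[sample.int(length(inside), sum(!free),
                                                     replace = TRUE)]
    tibble::tibble(
      species = species,
      longitude = world$longitude[cell],
      latitude = world$latitude[cell],
      value = v[cell],
      truth = ifelse(free, "background", "niche")
    )
  })
}

#' Generate a complete virtual dataset
#'
#' World, tolerance table and occurrence records in one call, with
#' per-species record counts drawn from the configured count distribution and
#' independent per-species sampling streams.
#'
#' @param world_cfg a [world_config()].
#' @param species_cfg a [species_config()].
#' @return list with `world`, `tolerances`, `occurrences`.
#' @export
simulate_dataset <- function(world_cfg = world_config(),
                             species_cfg = species_config()) {
  world <- generate_world(world_cfg)
  tolerances <- generate_species(species_cfg, world)
  counts <- withr::with_seed(derive_seed(species_cfg$seed, 3L), {
    pmax(1L, as.integer(draw_from(species_cfg$occurrences_per_species,
                                  species_cfg$n_species)))
  })
  occ <- purrr::map_dfr(seq_len(nrow(tolerances)), function(i) {
    sample_occurrences(tolerances$t_min[i], tolerances$t_max[i], world,
                       counts[i], species_cfg$contamination,
                       seed = derive_seed(species_cfg$seed, 100L + i),
                       species = tolerances$species[i])
  })
  list(world = world, tolerances = tolerances, occurrences = occ)
}
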