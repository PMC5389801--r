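#' Analysis run configuration
#'
#' Collects inputs and settings for [run_analysis()]. Exactly one climate
#' source (`climate` or `synthetic_world`) and one species source
#' (`tolerances` or `synthetic_species`) must be given; synthetic species
#' imply generated occurrences, real tolerance tables require an
#' `occurrences` source.
#'
#' @param climate path to a climate-cell CSV or a [climate_field()].
#' @param tolerances path to a tolerance CSV or a tibble
#'   (`species,t_min,t_max`).
#' @param occurrences path to an occurrence CSV or a tibble
#'   (`species,longitude,latitude`, optionally `value`).
#' @param synthetic_world a [world_config()].
#' @param synthetic_species a [species_config()].
#' @param thin_radius_km spatial thinning radius; `NULL` skips thinning.
#' @param min_points minimum occurrences for a realized-niche kernel.
#' @param alpha_inside family-wise level of the sequentially corrected
#'   inside-placement tests; default 0.01.
#' @param alpha_outside level divided by the family size for the plain
#'   Bonferroni outside tests; default 0.05.
#' @param measure_convention degrees-C conversion for the existing measure,
#'   `"intersection"` or `"proportion_range"`; see [existing_measure()].
#' @param occ_range_within restrict the observed occurrence range to values
#'   inside the tolerance interval; see [occurrence_range()].
#' @param bandwidth optional explicit climate-kernel bandwidth.
#' @param null_draws draws for the random-interval volume null; default 10000.
#' @param climate_tenths climate CSV stores tenths of degrees C.
#' @param seed master seed for every stochastic stage.
#' @return a `run_config` list.
#' @export
run_config <- function(climate = NULL, tolerances = NULL, occurrences = NULL,
                       synthetic_world = NULL, synthetic_species = NULL,
                       thin_radius_km = 10, min_points = 5L,
                       alpha_inside = 0.01, alpha_outside = 0.05,
                       measure_convention = c("intersection", "proportion_range"),
                       occ_range_within = TRUE, bandwidth = NULL,
                       null_draws = 10000L, climate_tenths = FALSE,
                       seed = 1L) {
  measure_convention <- match.arg(measure_convention)
  if (is.null(climate) == is.null(synthetic_world)) {
    abort("give exactly one of `climate` or `synthetic_world`.",
          class = "nichebounds_config_error")
  }
  if (is.null(tolerances) == is.null(synthetic_species)) {
    abort("give exactly one of `tolerances` or `synthetic_species`.",
          class = "nichebounds_config_error")
  }
  if (!is.null(tolerances) && is.null(occurrences)) {
    abort("real tolerance tables require an `occurrences` source.",
          class = "nichebounds_config_error")
  }
  for (a in c(alpha_inside, alpha_outside)) {
    if (a <= 0 || a >= 1) {
      abort("alpha levels must lie in (0, 1).",
            class = "nichebounds_config_error")
    }
  }
  structure(
    list(climate = climate, tolerances = tolerances, occurrences = occurrences,
         synthetic_world = synthetic_world,
         synthetic_species = synthetic_species,
         thin_radius_km = thin_radius_km, min_points = as.integer(min_points),
         alpha_inside = alpha_inside, alpha_outside = alpha_outside,
         measure_convention = measure_convention,
         occ_range_within = isTRUE(occ_range_within), bandwidth = bandwidth,
         null_draws = as.integer(null_draws),
         climate_tenths = isTRUE(climate_tenths), seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a run configuration from YAML or JSON
#'
#' Scalar settings map directly to [run_config()] arguments; `synthetic_world`
#' and `synthetic_species` blocks are passed to [world_config()] /
#' [species_config()], with distribution entries given as
#' `{dist: ..., <params>}`.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path),
          class = "nichebounds_io_error")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  as_dist <- function(x) {
    if (is.null(x)) return(NULL)
    do.call(dist_spec, c(list(dist = x$dist), x[setdiff(names(x), "dist")]))
  }
  if (!is.null(raw$synthetic_world)) {
    raw$synthetic_world <- do.call(world_config, raw$synthetic_world)
  }
  if (!is.null(raw$synthetic_species)) {
    ss <- raw$synthetic_species
    for (f in c("center_distribution", "width_distribution",
                "occurrences_per_species")) {
      ss[[f]] <- as_dist(ss[[f]])
    }
    raw$synthetic_species <- do.call(species_config, ss[!vapply(ss, is.null, TRUE)])
  }
  do.call(run_config, raw)
}

resolve_world <- function(config) {
  if (!is.null(config$synthetic_world)) return(generate_world(config$synthetic_world))
  if (inherits(config$climate, "climate_field")) return(config$climate)
  if (is.character(config$climate)) {
    return(read_climate_field(config$climate, tenths = config$climate_tenths))
  }
  climate_field(config$climate)
}

resolve_species <- function(config, world) {
  if (!is.null(config$synthetic_species)) {
    sc <- config$synthetic_species
    tol <- generate_species(sc, world)
    counts <- withr::with_seed(derive_seed(sc$seed, 3L), {
      pmax(1L, as.integer(draw_from(sc$occurrences_per_species, sc$n_species)))
    })
    occ <- purrr::map_dfr(seq_len(nrow(tol)), function(i) {
      sample_occurrences(tol$t_min[i], tol$t_max[i], world, counts[i],
                         sc$contamination,
                         seed = derive_seed(sc$seed, 100L + i),
                         species = tol$species[i])
    })
    return(list(tolerances = tol, occurrences = occ))
  }
  tol <- if (is.character(config$tolerances)) {
    read_tolerances(config$tolerances)
  } else {
    validate_tolerances(tibble::as_tibble(config$tolerances))
  }
  occ <- if (is.character(config$occurrences)) {
    read_occurrences(config$occurrences)
  } else {
    validate_occurrences(tibble::as_tibble(config$occurrences))
  }
  list(tolerances = tol, occurrences = occ)
}

#' Run the full niche-inequality analysis
#'
#' End to end: fit the climate kernel to the equal-area grid, thin and
#' annotate occurrences, compute per-species fundamental / existing / realized
#' measures and potential extents, run the binomial placement tests with
#' sequential (Holm) correction and the mirror excess-outside tests, build
#' the random-interval volume null and its KS comparison against observed
#' fundamental-niche volumes, and fit existing on fundamental measures.
#' Species failing a stage stay in the table with missing values and a reason
#' code; nothing is silently dropped.
#'
#' @param config a [run_config()].
#' @return a `niche_analysis` object: `per_species` tibble, `global` summary
#'   list, `standardized` per-record table, `null_volumes`, `provenance`.
#' @examples
#' \donttest{
#' cfg <- run_config(
#'   synthetic_world = world_config(n_cells = 2000, seed = 7),
#'   synthetic_species = species_config(n_species = 20, seed = 7),
#'   thin_radius_km = NULL, seed = 7
#' )
#' res <- run_analysis(cfg)
#' glance(res)
#' }
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  world <- resolve_world(config)
  sp <- resolve_species(config, world)
  tol <- sp$tolerances
  occ <- sp$occurrences

  if (!is.null(config$thin_radius_km) && nrow(occ) > 0L) {
    occ <- thin_occurrences(occ, config$thin_radius_km,
                            seed = derive_seed(config$seed, 5L))
  }
  if (nrow(occ) > 0L && !("value" %in% names(occ))) {
    occ <- extract_values(occ, world)
  }

  vcol <- attr(world, "value_cols")[1L]
  climate_kernel <- fit_environment_kernel(world[[vcol]],
                                           bandwidth = config$bandwidth)
  env_rng <- environment_range(world)

  overlap_any <- any(tol$t_min <= env_rng$hi[1L] & tol$t_max >= env_rng$lo[1L])
  if (!overlap_any) {
    abort("no species' tolerance interval overlaps the available climate.",
          class = "nichebounds_empty_analysis")
  }

  rows <- purrr::map(seq_len(nrow(tol)), function(i) {
    species_summary(tol$species[i], tol$t_min[i], tol$t_max[i],
                    occ$value[occ$species == tol$species[i]],
                    climate_kernel, world, env_rng, config)
  })
  per_species <- dplyr::bind_rows(rows)

  tested <- which(per_species$n > 0L)
  per_species$significant_inside <- NA
  if (length(tested)) {
    per_species$significant_inside[tested] <-
      holm_adjust(per_species$p_value[tested], alpha = config$alpha_inside)
  }
  m_outside <- nrow(tol)
  out <- outside_excess_test(
    k_out = per_species$n - per_species$k,
    n = pmax(per_species$n, 1L),
    p_out = 1 - per_species$p_null,
    alpha_bonf = config$alpha_outside / m_outside
  )
  per_species$p_value_outside <- ifelse(per_species$n > 0L,
                                        out$p_value_outside, NA_real_)
  per_species$significant_outside <- ifelse(per_species$n > 0L,
                                            out$significant_outside, NA)

  null_vol <- nf_volume_null(env_rng, n_draws = config$null_draws,
                             seed = derive_seed(config$seed, 7L))
  ks <- tryCatch(
    ks_compare(log10(per_species$nf_measure), log10(null_vol$delta)),
    error = function(e) tibble::tibble(statistic = NA_real_, p_value = NA_real_)
  )
  fit <- tryCatch(
    linear_fit(per_species$nf_measure, per_species$existing_measure),
    error = function(e) tibble::tibble(slope = NA_real_, intercept = NA_real_,
                                       r_squared = NA_real_, p_value = NA_real_)
  )

  standardized <- per_record_standardized(occ, tol)

  has_min <- per_species$n >= config$min_points
  global <- list(
    n_species = nrow(per_species),
    n_tested = length(tested),
    n_with_min_points = sum(has_min),
    overall_fraction_inside = sum(per_species$k) / max(sum(per_species$n), 1L),
    n_significant_inside = sum(per_species$significant_inside, na.rm = TRUE),
    n_significant_inside_min_points =
      sum(per_species$significant_inside[has_min], na.rm = TRUE),
    n_significant_outside = sum(per_species$significant_outside, na.rm = TRUE),
    n_with_realized = sum(!is.na(per_species$realized_measure)),
    fit = fit,
    ks = ks,
    max_potential_area = max(per_species$potential_area, 0),
    null_volume_mean = mean(null_vol$delta)
  )

  structure(
    list(per_species = per_species, global = global,
         standardized = standardized, null_volumes = null_vol,
         climate_kernel = climate_kernel, environment_range = env_rng,
         provenance = list(
           seed = config$seed,
           measure_convention = config$measure_convention,
           occ_range_within = config$occ_range_within,
           thin_radius_km = config$thin_radius_km,
           min_points = config$min_points,
           alpha_inside = config$alpha_inside,
           alpha_outside = config$alpha_outside,
           outside_family_size = m_outside,
           null_draws = config$null_draws,
           version = as.character(utils::packageVersion("nichebounds"))
         )),
    class = "niche_analysis"
  )
}

species_summary <- function(species, t_min, t_max, values, climate_kernel,
                            world, env_rng, config) {
  values <- values[is.finite(values)]
  n <- length(values)
  p_null <- existing_proportion(climate_kernel, t_min, t_max)
  ext <- potential_extent(world, t_min, t_max)
  cnt <- count_inside(values, t_min, t_max)
  nf <- nf_measure(t_min, t_max)
  ex <- existing_measure(p_null, env_rng, t_min, t_max,
                         convention = config$measure_convention)
  occ_rng <- occurrence_range(values, t_min, t_max,
                              within = config$occ_range_within)
  reason <- NA_character_
  realized <- NA_real_
  if (n == 0L) {
    reason <- "no_occurrences"
  } else if (n < config$min_points) {
    reason <- "too_few_points"
  } else {
    rk <- tryCatch(fit_realized_kernel(values, config$min_points),
                   error = function(e) NULL)
    if (is.null(rk)) {
      reason <- "degenerate_values"
    } else if (is.na(occ_rng)) {
      reason <- "no_values_inside"
    } else {
      realized <- realized_measure(rk, climate_kernel, t_min, t_max, occ_rng)
    }
  }
  p_value <- if (n > 0L) placement_test(cnt$k, n, p_null) else NA_real_
  tibble::tibble(
    species = species, t_min = t_min, t_max = t_max,
    n = n, k = cnt$k, p_null = p_null, p_value = p_value,
    nf_measure = nf, existing_proportion = p_null, existing_measure = ex,
    occ_range = occ_rng, realized_measure = realized,
    potential_cells = ext$cells, potential_area = ext$area_km2,
    exclusion_reason = reason
  )
}

per_record_standardized <- function(occ, tol) {
  if (nrow(occ) == 0L || !("value" %in% names(occ))) {
    return(tibble::tibble(species = character(), value = numeric(),
                          standardized = numeric()))
  }
  occ |>
    dplyr::inner_join(tol, by = "species") |>
    dplyr::filter(is.finite(.data$value)) |>
    dplyr::mutate(standardized = standardize_temperature(.data$value,
                                                         .data$t_min,
                                                         .data$t_max)) |>
    dplyr::select("species", "value", "standardized")
}

#' Write analysis outputs to disk
#'
#' Writes the per-species table, a global JSON summary, and four figure-ready
#' datasets: fundamental vs existing measures, standardized occurrence
#' temperatures (with the common `[-0.5, 0.5]` interval edges), realized vs
#' existing measures, and the observed and null log10 volume samples. Floats
#' are written at 10 significant digits; existing files are refused unless
#' `overwrite = TRUE`.
#'
#' @param report a `niche_analysis`.
#' @param out_dir output directory (created if absent).
#' @param overwrite replace existing files?
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, out_dir, overwrite = FALSE) {
  stopifnot(inherits(report, "niche_analysis"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c(
    "per_species.csv", "global_summary.json",
    "fig_fundamental_vs_existing.csv", "fig_standardized_occurrences.csv",
    "fig_realized_vs_existing.csv", "fig_volume_distributions.csv"
  ))
  existing <- paths[file.exists(paths)]
  if (length(existing) && !overwrite) {
    abort(sprintf("refusing to overwrite existing output (%s); set overwrite = TRUE.",
                  paste(basename(existing), collapse = ", ")),
          class = "nichebounds_io_error")
  }
  sig <- function(df) {
    dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric),
                                    ~ signif(.x, 10)))
  }
  write_csv_plain(sig(report$per_species), paths[1L])

  g <- report$global
  g$fit <- as.list(g$fit)
  g$ks <- as.list(g$ks)
  json <- list(global = rapply(g, function(z)
    if (is.numeric(z)) signif(z, 10) else z, how = "replace"),
    provenance = report$provenance)
  jsonlite::write_json(json, paths[2L], auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)

  write_csv_plain(sig(figure_data(report, "fundamental_existing")), paths[3L])
  write_csv_plain(sig(figure_data(report, "standardized")), paths[4L])
  write_csv_plain(sig(figure_data(report, "realized_existing")), paths[5L])
  write_csv_plain(sig(figure_data(report, "volumes")), paths[6L])
  invisible(paths)
}

# readr::write_csv with fixed eol and no progress, for byte-stable outputs
write_csv_plain <- function(df, path) {
  readr::write_csv(df, path, eol = "\n", progress = FALSE)
}

#' Figure-ready datasets from an analysis
#'
#' @param report a `niche_analysis`.
#' @param which one of `"fundamental_existing"`, `"standardized"`,
#'   `"realized_existing"`, `"volumes"`.
#' @return a tibble ready for plotting.
#' @export
figure_data <- function(report,
                        which = c("fundamental_existing", "standardized",
                                  "realized_existing", "volumes")) {
  which <- match.arg(which)
  ps <- report$per_species
  switch(which,
    fundamental_existing = dplyr::select(ps, "species", "nf_measure",
                                         "existing_measure"),
    standardized = dplyr::mutate(report$standardized,
                                 edge_lo = -0.5, edge_hi = 0.5),
    realized_existing = ps |>
      dplyr::filter(!is.na(.data$realized_measure)) |>
      dplyr::select("species", "existing_measure", "realized_measure"),
    volumes = dplyr::bind_rows(
      tibble::tibble(source = "fundamental",
                     log10_volume = log10(ps$nf_measure)),
      tibble::tibble(source = "null",
                     log10_volume = log10(report$null_volumes$delta))
    )
  )
}

#' @export
print.niche_analysis <- function(x, ...) {
  g <- x$global
  cat("<niche_analysis>\n")
  cat(sprintf("  species: %d (tested: %d, with realized kernel: %d)\n",
              g$n_species, g$n_tested, g$n_with_realized))
  cat(sprintf("  occurrences inside fundamental niche: %.2f%%\n",
              100 * g$overall_fraction_inside))
  cat(sprintf("  significant inside placement (Holm %.3g): %d/%d\n",
              x$provenance$alpha_inside, g$n_significant_inside, g$n_tested))
  if (is.finite(g$fit$slope)) {
    cat(sprintf("  existing ~ fundamental: N* = %.3g + %.3g N_F (r^2 = %.3f)\n",
                g$fit$intercept, g$fit$slope, g$fit$r_squared))
  }
  if (is.finite(g$ks$statistic)) {
    cat(sprintf("  KS vs null volumes: D = %.3f, p = %.3g\n",
                g$ks$statistic, g$ks$p_value))
  }
  invisible(x)
}
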