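test_that("generate_world draws the configured mixture on an equal-area lattice", {
  cfg <- world_config(n_cells = 10000, seed = 3)
  w <- generate_world(cfg)
  expect_s3_class(w, "climate_field")
  expect_equal(nrow(w), 10000L)
  expect_equal(unique(w$area_km2), 1e4)
  expect_true(all(c("longitude", "latitude") %in% names(w)))

  # analytic mixture moments
  cm <- cfg$climate_model
  mix_mean <- sum(cm$weights * cm$means)
  mix_var <- sum(cm$weights * (cm$sds^2 + cm$means^2)) - mix_mean^2
  expect_equal(mean(w$value), mix_mean,
               tolerance = 3 * sqrt(mix_var / 10000) / abs(mix_mean))

  expect_identical(generate_world(cfg)$value, w$value) # determinism
  expect_false(identical(generate_world(world_config(n_cells = 10000,
                                                     seed = 4))$value,
                         w$value))
  expect_error(world_config(n_cells = 5), class = "nichebounds_config_error")
  expect_error(world_config(climate_model = list(weights = c(0.5, 0.4),
                                                 means = c(0, 1),
                                                 sds = c(1, 1))),
               class = "nichebounds_config_error")
})

test_that("generate_species builds valid tolerance intervals", {
  w <- generate_world(world_config(n_cells = 100, seed = 1))
  fixed <- species_config(n_species = 8,
                          center_distribution = dist_spec("fixed", value = 15),
                          width_distribution = dist_spec("fixed", value = 10),
                          seed = 2)
  tol <- generate_species(fixed, w)
  expect_equal(tol$t_min, rep(10, 8))
  expect_equal(tol$t_max, rep(20, 8))

  cfg <- species_config(n_species = 10000,
                        width_distribution = dist_spec("uniform", min = 5,
                                                       max = 25),
                        seed = 5)
  tol <- generate_species(cfg, w)
  widths <- tol$t_max - tol$t_min
  expect_true(all(widths > 5 & widths < 25))
  expect_true(all(tol$t_min < tol$t_max))
  # moment oracle: uniform(5, 25) has mean 15, sd 20/sqrt(12)
  expect_equal(mean(widths), 15,
               tolerance = 3 * (20 / sqrt(12)) / sqrt(10000) / 15)

  expect_error(species_config(width_distribution = dist_spec("uniform",
                                                             min = -1, max = 5)),
               class = "nichebounds_config_error")
  expect_error(species_config(contamination = 1.5),
               class = "nichebounds_config_error")
})

test_that("sample_occurrences respects contamination and ground truth", {
  w <- generate_world(world_config(n_cells = 5000, seed = 6))
  # contamination 0: every value inside, every label "niche"
  occ <- sample_occurrences(0, 25, w, n = 200, contamination = 0, seed = 7)
  expect_equal(nrow(occ), 200L)
  expect_true(all(occ$value >= 0 & occ$value <= 25))
  expect_true(all(occ$truth == "niche"))
  expect_equal(count_inside(occ$value, 0, 25)$k, 200L)

  # contamination 1: fraction inside matches the world's empirical proportion
  occ1 <- sample_occurrences(0, 25, w, n = 4000, contamination = 1, seed = 8)
  p_emp <- mean(w$value >= 0 & w$value <= 25)
  p_hat <- mean(occ1$value >= 0 & occ1$value <= 25)
  expect_equal(p_hat, p_emp,
               tolerance = 3 * sqrt(p_emp * (1 - p_emp) / 4000) / p_emp)
  expect_true(all(occ1$truth == "background"))

  expect_equal(nrow(sample_occurrences(0, 25, w, n = 0, contamination = 0)),
               0L)
  expect_error(sample_occurrences(90, 95, w, n = 5, contamination = 0.5),
               class = "nichebounds_infeasible_sampling")
  expect_identical(sample_occurrences(0, 25, w, 50, 0.3, seed = 9),
                   sample_occurrences(0, 25, w, 50, 0.3, seed = 9))
})

test_that("contamination-free sampling recovers the niche parameters", {
  w <- generate_world(world_config(n_cells = 5000, seed = 10))
  tol <- generate_species(species_config(n_species = 20, contamination = 0,
                                         seed = 11), w)
  for (i in seq_len(nrow(tol))) {
    occ <- sample_occurrences(tol$t_min[i], tol$t_max[i], w, n = 25,
                              contamination = 0,
                              seed = nichebounds:::derive_seed(11, i))
    expect_gte(min(occ$value), tol$t_min[i])
    expect_lte(max(occ$value), tol$t_max[i])
    expect_equal(count_inside(occ$value, tol$t_min[i], tol$t_max[i])$k, 25L)
  }
})

test_that("p-values are uniform-or-conservative under the global null", {
  w <- generate_world(world_config(n_cells = 4000, seed = 12))
  k <- fit_environment_kernel(w$value)
  tol <- generate_species(species_config(n_species = 150, seed = 13), w)
  p <- vapply(seq_len(nrow(tol)), function(i) {
    occ <- sample_occurrences(tol$t_min[i], tol$t_max[i], w, n = 40,
                              contamination = 1,
                              seed = nichebounds:::derive_seed(13, i))
    placement_test(count_inside(occ$value, tol$t_min[i], tol$t_max[i])$k,
                   40, existing_proportion(k, tol$t_min[i], tol$t_max[i]))
  }, numeric(1))
  # stochastically >= uniform: empirical CDF never far above the diagonal
  for (q in c(0.01, 0.05, 0.1, 0.25, 0.5)) {
    expect_lte(mean(p <= q), q + 3 * sqrt(q * (1 - q) / 150) + 0.02)
  }
})

test_that("simulate_dataset wires worlds, species and occurrences together", {
  ds <- simulate_dataset(world_config(n_cells = 1000, seed = 14),
                         species_config(n_species = 6, seed = 14,
                                        occurrences_per_species =
                                          dist_spec("fixed", value = 12)))
  expect_equal(nrow(ds$tolerances), 6L)
  expect_equal(nrow(ds$occurrences), 72L)
  expect_setequal(unique(ds$occurrences$species), ds$tolerances$species)
  expect_true(all(c("value", "truth") %in% names(ds$occurrences)))
})
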