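test_that("nf_measure is the tolerance-interval width", {
  expect_equal(nf_measure(5, 30), 25)
  expect_equal(nf_measure(-2, -1), 1)
  expect_equal(nf_measure(c(0, 10), c(5, 30)), c(5, 20))
  expect_error(nf_measure(10, 10), class = "nichebounds_validation_error")
  expect_error(nf_measure(10, 5), class = "nichebounds_validation_error")
})

test_that("standardization maps every niche onto [-1/2, 1/2]", {
  expect_equal(standardize_temperature(5, 5, 30), -0.5)
  expect_equal(standardize_temperature(30, 5, 30), 0.5)
  expect_equal(standardize_temperature(17.5, 5, 30), 0)
  v <- seq(-10, 45, by = 0.5)
  s <- standardize_temperature(v, 5, 30)
  expect_identical(s >= -0.5 & s <= 0.5, v >= 5 & v <= 30)
})

test_that("existing_proportion reproduces analytic uniform and normal masses", {
  u <- uniform_kernel(0, 10)
  expect_equal(existing_proportion(u, 2, 4), 0.2, tolerance = 1e-9)
  expect_equal(existing_proportion(u, 20, 30), 0) # disjoint from support

  k <- withr::with_seed(31, fit_environment_kernel(rnorm(1e5)))
  expect_equal(existing_proportion(k, -1, 1), pnorm(1) - pnorm(-1),
               tolerance = 0.01)
})

test_that("existing_proportion agrees with Monte Carlo draws from the kernel", {
  x <- withr::with_seed(32, c(rnorm(400, 0, 3), rnorm(600, 15, 4)))
  k <- fit_environment_kernel(x)
  draws <- withr::with_seed(33, {
    centers <- sample(x, 1e6, replace = TRUE)
    centers + rnorm(1e6, sd = k$bandwidth)
  })
  for (iv in list(c(-3, 3), c(5, 20), c(-10, 30))) {
    p_hat <- mean(draws >= iv[1] & draws <= iv[2])
    se <- sqrt(p_hat * (1 - p_hat) / 1e6)
    # allow for the small truncation mass outside +-4 bandwidths
    expect_equal(existing_proportion(k, iv[1], iv[2]), p_hat,
                 tolerance = max(3 * se / p_hat, 2e-4))
  }
})

test_that("existing_measure conventions behave as documented", {
  rng <- c(0, 30)
  expect_equal(existing_measure(1, rng, convention = "proportion_range"), 30)
  expect_equal(existing_measure(0, rng, convention = "proportion_range"), 0)
  # uniform climate on [0,30], tol [10,20]: proportion 1/3 and the
  # intersection length agree at 10 degrees C
  u <- uniform_kernel(0, 30)
  p <- existing_proportion(u, 10, 20)
  expect_equal(p, 1 / 3, tolerance = 1e-9)
  expect_equal(existing_measure(p, rng, convention = "proportion_range"), 10,
               tolerance = 1e-6)
  expect_equal(existing_measure(p, rng, 10, 20, convention = "intersection"), 10)
  # intersection clips to the available range and never exceeds the width
  expect_equal(existing_measure(0.9, rng, -10, 20), 20)
  expect_equal(existing_measure(0.9, rng, 40, 50), 0)
  expect_error(existing_measure(1.2, rng), class = "nichebounds_input_error")
})

test_that("realized kernels honor the minimum-points rule", {
  expect_null(fit_realized_kernel(c(1, 2, 3, 4)))
  k <- fit_realized_kernel(c(1, 2.2, 3.1, 4.5, 6))
  expect_s3_class(k, "env_kernel")
  expect_equal(kernel_mass(k, k$support[1], k$support[2]), 1,
               tolerance = 1e-3)
  expect_error(fit_realized_kernel(rep(5, 5)),
               class = "nichebounds_degenerate_sample")
})

test_that("realized_measure integrates the minimum of the two kernels", {
  u <- uniform_kernel(0, 10)
  expect_equal(realized_measure(u, u, 0, 10, occ_range = 7), 7,
               tolerance = 1e-3)
  expect_equal(realized_measure(uniform_kernel(0, 1), uniform_kernel(5, 6),
                                0, 10, occ_range = 3), 0)
  # unit uniforms offset by half their width overlap in mass 0.5; the band
  # covers the O(h) quadrature error at the density discontinuities
  expect_equal(realized_measure(uniform_kernel(0, 1), uniform_kernel(0.5, 1.5),
                                0, 2, occ_range = 4), 2, tolerance = 5e-3)
  expect_error(realized_measure(u, u, 0, 10, occ_range = -1),
               class = "nichebounds_input_error")
})

test_that("occurrence_range restricts to the niche unless told otherwise", {
  v <- c(-20, 5, 12, 18, 40)
  expect_equal(occurrence_range(v, 0, 20, within = TRUE), 13)
  expect_equal(occurrence_range(v, 0, 20, within = FALSE), 60)
  expect_true(is.na(occurrence_range(c(-5, 50), 0, 20, within = TRUE)))
})

test_that("count_inside uses closed interval bounds", {
  expect_equal(count_inside(c(1, 2, 3), 2, 4), tibble::tibble(k = 2L, n = 3L))
  expect_equal(count_inside(2, 2, 4)$k, 1L) # boundary counts as inside
  expect_equal(count_inside(4, 2, 4)$k, 1L)
  expect_equal(count_inside(numeric(0), 2, 4),
               tibble::tibble(k = 0L, n = 0L))
})

test_that("count_inside matches the standardized-scale membership exactly", {
  v <- withr::with_seed(34, runif(500, -20, 50))
  for (tol in list(c(0, 30), c(-5, 5), c(25, 26))) {
    k <- count_inside(v, tol[1], tol[2])$k
    s <- standardize_temperature(v, tol[1], tol[2])
    expect_identical(k, sum(s >= -0.5 & s <= 0.5))
  }
})

test_that("potential_extent counts cells inside the interval", {
  f <- tiny_field(c(5, 15, 25))
  ext <- potential_extent(f, 10, 20)
  expect_equal(ext$cells, 1L)
  expect_equal(ext$area_km2, 1e4)
  expect_equal(potential_extent(f, -10, 0)$cells, 0L)
  expect_equal(potential_extent(f, -10, 0)$area_km2, 0)
  expect_equal(potential_extent(f, c(10, 0), c(20, 30))$cells, c(1L, 3L))
})

test_that("monotonicity: nested intervals give nested measures and counts", {
  withr::with_seed(35, {
    x <- c(rnorm(500, 0, 5), rnorm(500, 20, 4))
    k <- fit_environment_kernel(x)
    f <- tiny_field(x, area = 1e4)
    for (i in 1:20) {
      c0 <- runif(1, -10, 30); w1 <- runif(1, 1, 10); w2 <- w1 + runif(1, 1, 10)
      expect_lte(existing_proportion(k, c0 - w1, c0 + w1),
                 existing_proportion(k, c0 - w2, c0 + w2) + 1e-9)
      expect_lte(potential_extent(f, c0 - w1, c0 + w1)$cells,
                 potential_extent(f, c0 - w2, c0 + w2)$cells)
      expect_lte(count_inside(x, c0 - w1, c0 + w1)$k,
                 count_inside(x, c0 - w2, c0 + w2)$k)
    }
  })
})

test_that("realized_measure <= existing_measure for within-niche subsamples", {
  withr::with_seed(36, {
    x <- c(rnorm(1000, 0, 6), rnorm(1000, 18, 5))
    climate <- fit_environment_kernel(x)
    rng <- c(min(x), max(x))
    for (i in 1:5) {
      tol <- sort(runif(2, -5, 25)); if (diff(tol) < 2) tol[2] <- tol[1] + 2
      inside <- x[x >= tol[1] & x <= tol[2]]
      occ <- sample(inside, min(60, length(inside)))
      rk <- fit_realized_kernel(occ)
      ex <- existing_measure(existing_proportion(climate, tol[1], tol[2]),
                             rng, tol[1], tol[2])
      rm <- realized_measure(rk, climate, tol[1], tol[2],
                             occurrence_range(occ, tol[1], tol[2]))
      expect_lte(rm, ex + 1e-6)
    }
  })
})

test_that("2D box masses match analytic uniform and product-normal values", {
  u2 <- uniform_kernel_2d(0, 1, 0, 1)
  expect_equal(box_proportion_2d(u2, c(0, 0.5, 0, 0.5)), 0.25,
               tolerance = 1e-6)
  expect_equal(box_proportion_2d(u2, c(5, 6, 5, 6)), 0) # outside support
  k2 <- withr::with_seed(37,
    fit_environment_kernel(cbind(rnorm(4000), rnorm(4000))))
  # absolute band: the KDE mass differs from the exact normal mass by the
  # smoothing-bias term, which the band is sized to cover
  expect_lt(abs(box_proportion_2d(k2, c(-1, 1, -1, 1)) -
                  (pnorm(1) - pnorm(-1))^2), 0.02)
  expect_error(box_proportion_2d(uniform_kernel(0, 1), c(0, 1, 0, 1)),
               class = "nichebounds_input_error")
  # box accepted as a one-row tolerance table
  expect_equal(
    box_proportion_2d(u2, data.frame(t_min = 0, t_max = 1, u_min = 0,
                                     u_max = 0.5)),
    0.5, tolerance = 1e-6)
})

test_that("tolerance tables are validated on read", {
  path <- write_temp_csv(data.frame(species = c("A", "B"),
                                    t_min = c(0, 5), t_max = c(10, 35)))
  tol <- read_tolerances(path)
  expect_equal(tol$t_max - tol$t_min, c(10, 30))
  bad <- write_temp_csv(data.frame(species = "A", t_min = 10, t_max = 5))
  expect_error(read_tolerances(bad), class = "nichebounds_validation_error")
})
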