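#' Binomial random-placement test
#'
#' Under the random-placement null, occurrence environments are drawn at
#' random from the available climate, so the number of occurrences inside a
#' species' tolerance interval is Binomial(n, p_null) with p_null the
#' proportion of the climate kernel inside the interval. The test reports the
#' exact upper tail `P(X >= k)`: the probability that random sampling would
#' give the observed or a greater number of points inside.
#'
#' @param k observed count inside (vectorized).
#' @param n total occurrence count.
#' @param p_null kernel proportion inside the tolerance interval.
#' @return exact upper-tail p-value(s).
#' @export
placement_test <- function(k, n, p_null) {
  ans <- purrr::pmap_dbl(list(k, n, p_null), binom_upper_tail)
  ans
}

binom_upper_tail <- function(k, n, p) {
  if (!is.finite(k) || !is.finite(n) || k < 0 || n < 1 || k > n ||
      k != round(k) || n != round(n)) {
    abort("need integer counts with 0 <= k <= n and n >= 1.",
          class = "nichebounds_input_error")
  }
  if (!is.finite(p) || p < 0 || p > 1) {
    abort("`p_null` must lie in [0, 1].", class = "nichebounds_input_error")
  }
  if (p == 0) {
    # interval holds no available climate: any point inside is impossible
    # under the null
    if (k > 0) {
      warn("p_null is 0 with k > 0; returning p-value 0.")
      return(0)
    }
    return(1)
  }
  if (k == 0) return(1)
  pbinom(k - 1, size = n, prob = p, lower.tail = FALSE)
}

#' Sequential Bonferroni (Holm) significance flags
#'
#' Holm's step-down procedure at family-wise level `alpha`: sort the p-values
#' ascending, reject the i-th smallest while `p(i) <= alpha / (m - i + 1)`,
#' and stop at the first failure. Controls the family-wise error rate at
#' `alpha` with more power than the plain Bonferroni bound.
#'
#' @param p_values numeric vector of p-values.
#' @param alpha family-wise level; default 0.01.
#' @return logical flags in the input order.
#' @export
holm_adjust <- function(p_values, alpha = 0.01) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    abort("p-values must lie in [0, 1].", class = "nichebounds_input_error")
  }
  check_number(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie in (0, 1).", class = "nichebounds_input_error")
  }
  m <- length(p_values)
  if (m == 0L) return(logical(0))
  ord <- order(p_values)
  thresholds <- alpha / (m - seq_len(m) + 1)
  pass <- p_values[ord] <= thresholds
  # step-down: stop at the first failure
  n_reject <- if (all(pass)) m else which(!pass)[1L] - 1L
  flags <- logical(m)
  if (n_reject > 0L) flags[ord[seq_len(n_reject)]] <- TRUE
  flags
}

#' Excess-outside binomial test
#'
#' The mirror test: are there more occurrences *outside* the tolerance
#' interval than random placement predicts? Upper tail of
#' Binomial(n, 1 - p_null) at the outside count, flagged at a fixed
#' Bonferroni-corrected level (the two test families run at the two levels at
#' which they are conventionally reported: sequential correction for the
#' inside family, plain `alpha / m` for the outside family).
#'
#' @param k_out count outside the interval (vectorized).
#' @param n total occurrence count.
#' @param p_out null probability of falling outside (`1 - p_null`).
#' @param alpha_bonf the already-divided per-test level (e.g. `0.05 / m`).
#' @return tibble with `p_value_outside` and `significant_outside`.
#' @export
outside_excess_test <- function(k_out, n, p_out, alpha_bonf) {
  check_number(alpha_bonf, "alpha_bonf")
  p <- purrr::pmap_dbl(list(k_out, n, p_out), binom_upper_tail)
  tibble::tibble(p_value_outside = p, significant_outside = p <= alpha_bonf)
}

#' Random-interval null model for fundamental-niche volumes
#'
#' Draws `n_draws` independent pairs of uniform left and right limits within
#' the available climate range and keeps the widths of the pairs with positive
#' difference (right minus left). The retained widths follow the triangular
#' density `2 (W - d) / W^2` on `(0, W)` and are the null distribution against
#' which the observed tolerance-interval widths are compared.
#'
#' @param env_range [environment_range()] tibble or `c(lo, hi)`.
#' @param n_draws number of limit pairs; default 10000.
#' @param seed integer seed; draws are deterministic given the seed.
#' @return tibble of retained widths `delta` (degrees C), with attributes
#'   `n_draws` and `seed`.
#' @export
nf_volume_null <- function(env_range, n_draws = 10000L, seed = 1L) {
  r <- as_range_pair(env_range)
  if (!is.finite(n_draws) || n_draws < 1) {
    abort("`n_draws` must be at least 1.", class = "nichebounds_input_error")
  }
  if (r[2L] <= r[1L]) {
    abort("environment range has zero width.",
          class = "nichebounds_input_error")
  }
  d <- withr::with_seed(seed, {
    left <- runif(n_draws, r[1L], r[2L])
    right <- runif(n_draws, r[1L], r[2L])
    right - left
  })
  out <- tibble::tibble(delta = d[d > 0])
  attr(out, "n_draws") <- as.integer(n_draws)
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Compares two empirical distributions (conventionally the decimal logarithms
#' of observed and null niche volumes) by the two-sample KS statistic
#' `D = sup |F_a - F_b|` with its asymptotic p-value.
#'
#' @param sample_a,sample_b numeric samples of at least 2 values each.
#' @return tibble with `statistic` and `p_value`.
#' @export
ks_compare <- function(sample_a, sample_b) {
  sample_a <- sample_a[is.finite(sample_a)]
  sample_b <- sample_b[is.finite(sample_b)]
  if (length(sample_a) < 2L || length(sample_b) < 2L) {
    abort("both samples need at least 2 finite values.",
          class = "nichebounds_input_error")
  }
  kt <- suppressWarnings(ks.test(sample_a, sample_b))
  tibble::tibble(statistic = unname(kt$statistic), p_value = kt$p.value)
}

#' Ordinary least-squares fit of existing on fundamental measures
#'
#' Fits `y = intercept + slope * x` and reports the slope test p-value and
#' coefficient of determination, matching the scattergram regression of
#' existing-niche versus fundamental-niche measures.
#'
#' @param x predictor (fundamental-niche measures).
#' @param y response (existing-niche measures).
#' @return tibble with `slope`, `intercept`, `r_squared`, `p_value`.
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    abort("need equal-length x and y with at least 3 points.",
          class = "nichebounds_input_error")
  }
  if (stats::sd(x) == 0) {
    abort("`x` is constant; slope is unidentifiable.",
          class = "nichebounds_degenerate_regressor")
  }
  if (stats::sd(y) == 0) {
    # flat response: the intercept-only fit, stated exactly rather than via
    # the 0/0 variance ratio
    return(tibble::tibble(slope = 0, intercept = y[1L], r_squared = 0,
                          p_value = NA_real_))
  }
  fit <- lm(y ~ x)
  sm <- summary(fit)
  p <- if (nrow(sm$coefficients) < 2L) NA_real_ else sm$coefficients[2L, 4L]
  tibble::tibble(
    slope = unname(coef(fit)[2L]),
    intercept = unname(coef(fit)[1L]),
    r_squared = sm$r.squared,
    p_value = p
  )
}
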