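#' @importFrom rlang abort warn inform %||%
#' @importFrom stats dnorm pnorm pbinom runif rnorm rpois rnbinom rlnorm
#'   ks.test lm coef bw.nrd0 integrate setNames quantile
NULL

# Derive a reproducible 32-bit sub-seed from a master seed and a stream index,
# so independent simulation stages never share an RNG stream.
derive_seed <- function(seed, stream) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(stream) * 2654435761
  as.integer(s %% 2147483629) + 1L
}

check_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name), class = "nichebounds_input_error")
  }
  if (finite && !is.finite(x)) {
    abort(sprintf("`%s` must be finite.", name), class = "nichebounds_input_error")
  }
  invisible(x)
}

check_fraction <- function(x, name) {
  check_number(x, name)
  if (x < 0 || x > 1) {
    abort(sprintf("`%s` must lie in [0, 1], got %g.", name, x),
          class = "nichebounds_input_error")
  }
  invisible(x)
}

# Composite Simpson rule weights on n_intervals (even) subintervals.
simpson_weights <- function(n_intervals) {
  stopifnot(n_intervals %% 2L == 0L)
  w <- rep(c(4, 2), length.out = n_intervals - 1L)
  c(1, w, 1) / 3
}

# \int_a^b f(x) dx by composite Simpson with n_intervals subintervals.
simpson_integrate <- function(f, a, b, n_intervals = 4096L) {
  if (b <= a) return(0)
  x <- seq(a, b, length.out = n_intervals + 1L)
  h <- (b - a) / n_intervals
  sum(simpson_weights(n_intervals) * f(x)) * h
}

# Mean over `centers` of the Gaussian kernel at each point in `x`, chunked so
# the outer() matrix never exceeds ~4e6 doubles. This is the 1D KDE evaluator.
gauss_mix_density <- function(x, centers, h) {
  n <- length(centers)
  out <- numeric(length(x))
  chunk <- max(1L, floor(4e6 / max(length(x), 1L)))
  idx <- 1L
  while (idx <= n) {
    j <- idx:min(idx + chunk - 1L, n)
    out <- out + rowSums(dnorm(outer(x, centers[j], "-"), sd = h))
    idx <- idx + chunk
  }
  out / (n)
}

# Closed-form mass of a 1D Gaussian KDE on [a, b]: mean of per-centre normal
# CDF differences. Used as the fast path; quadrature remains the generic path.
gauss_mix_mass <- function(a, b, centers, h) {
  if (b <= a) return(0)
  mean(pnorm((b - centers) / h) - pnorm((a - centers) / h))
}
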