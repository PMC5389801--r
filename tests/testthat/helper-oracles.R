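# Independent oracles, deliberately written against different primitives than
# the implementation they check.

# Brute-force upper binomial tail by term-by-term summation (log-scale
# binomial coefficients, no pbinom).
binom_tail_oracle <- function(k, n, p) {
  if (k == 0) return(1)
  if (p == 0) return(0)
  if (p == 1) return(1)
  i <- k:n
  sum(exp(lchoose(n, i) + i * log(p) + (n - i) * log1p(-p)))
}

# Literal hand step-down sequential-Bonferroni: walk the sorted p-values and
# reject while the running threshold is met.
holm_oracle <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  reject <- logical(m)
  for (i in seq_len(m)) {
    if (p[ord[i]] <= alpha / (m - i + 1)) reject[ord[i]] <- TRUE else break
  }
  reject
}

# Haversine great-circle distance (km), written out rather than taken from
# geosphere.
haversine_km <- function(lon1, lat1, lon2, lat2, r = 6371) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# Greedy thinning over an explicit visiting order, from pairwise brute force.
greedy_thin_oracle <- function(lon, lat, ord, radius_km) {
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) == 0L ||
        all(haversine_km(lon[i], lat[i], lon[kept], lat[kept]) >= radius_km)) {
      kept <- c(kept, i)
    }
  }
  sort(kept)
}

# Closed-form interval mass of a Gaussian KDE: mean of per-centre normal CDF
# differences (checks the quadrature path).
kde_mass_oracle <- function(a, b, centers, h) {
  mean(pnorm((b - centers) / h) - pnorm((a - centers) / h))
}

# Triangular CDF of |U1 - U2| widths retained as positive differences on a
# range of width w: F(d) = 1 - (1 - d/w)^2.
triangular_cdf <- function(d, w) {
  ifelse(d <= 0, 0, ifelse(d >= w, 1, 1 - (1 - d / w)^2))
}

# Uniform density as a custom env_kernel, the analytic construction used to
# pin integration conventions.
uniform_kernel <- function(lo, hi) {
  env_kernel(function(x) ifelse(x >= lo & x <= hi, 1 / (hi - lo), 0),
             support = c(lo, hi), bandwidth = (hi - lo) / 10)
}

uniform_kernel_2d <- function(lo1, hi1, lo2, hi2) {
  env_kernel(function(p) {
    p <- if (is.null(dim(p))) matrix(p, ncol = 2) else p
    inside <- p[, 1] >= lo1 & p[, 1] <= hi1 & p[, 2] >= lo2 & p[, 2] <= hi2
    ifelse(inside, 1 / ((hi1 - lo1) * (hi2 - lo2)), 0)
  },
  support = rbind(c(lo1, hi1), c(lo2, hi2)),
  bandwidth = c((hi1 - lo1) / 10, (hi2 - lo2) / 10))
}

# Small shared fixtures ------------------------------------------------------

tiny_field <- function(values = c(5, 15, 25), area = 1e4) {
  climate_field(data.frame(cell_id = seq_along(values), area_km2 = area,
                           value = values))
}

write_temp_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  readr::write_csv(df, path, progress = FALSE)
  path
}
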