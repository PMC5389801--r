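#' Read species occurrence records
#'
#' Reads georeferenced occurrence records (WGS84 decimal degrees) and drops
#' rows with out-of-range coordinates, reporting how many were rejected per
#' species. Replaces upstream gazetteer validation with a coordinate-validity
#' check plus an optional user-supplied region mask.
#'
#' @param path CSV with header `species,longitude,latitude`.
#' @param region_mask optional function `(longitude, latitude) -> logical`;
#'   records for which it returns `FALSE` are rejected (e.g. a bounding box or
#'   land mask the user supplies).
#' @return tibble `species, longitude, latitude`, original row order preserved
#'   within species.
#' @export
read_occurrences <- function(path, region_mask = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("occurrence file not found: %s", path),
          class = "nichebounds_io_error")
  }
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("species", "longitude", "latitude")
  if (!all(need %in% names(tab))) {
    abort(sprintf("occurrence file must have columns %s.",
                  paste(need, collapse = ", ")),
          class = "nichebounds_format_error")
  }
  validate_occurrences(tibble::as_tibble(tab[need]), region_mask = region_mask)
}

validate_occurrences <- function(occ, region_mask = NULL) {
  ok <- is.finite(occ$longitude) & is.finite(occ$latitude) &
    occ$longitude >= -180 & occ$longitude <= 180 &
    occ$latitude >= -90 & occ$latitude <= 90 &
    !is.na(occ$species) & nzchar(occ$species)
  if (!is.null(region_mask)) {
    ok <- ok & isTRUE_vec(region_mask(occ$longitude, occ$latitude))
  }
  if (any(!ok)) {
    bad <- occ[!ok, , drop = FALSE]
    counts <- table(bad$species)
    inform(sprintf(
      "rejected %d occurrence record(s) with invalid coordinates (%s).",
      nrow(bad),
      paste(sprintf("%s: %d", names(counts), as.integer(counts)),
            collapse = "; ")))
  }
  occ[ok, , drop = FALSE]
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Spatially thin occurrence records
#'
#' Seeded randomized-greedy thinning: within each species the records are
#' shuffled and a record is retained iff its great-circle distance to every
#' already-retained record is at least `radius_km`. Thinning removes
#' duplicated sampling effort so each retained record contributes roughly
#' independent information about the climates the species occupies.
#'
#' @param occ occurrence tibble (`species, longitude, latitude`, extra columns
#'   carried through).
#' @param radius_km minimum separation in km (spherical Earth, radius
#'   6371 km); default 10.
#' @param seed integer; the shuffle is deterministic given the seed, with an
#'   independent stream per species.
#' @return thinned tibble, a subset of the input rows.
#' @export
thin_occurrences <- function(occ, radius_km = 10, seed = 1L) {
  check_number(radius_km, "radius_km")
  if (radius_km <= 0) {
    abort("`radius_km` must be positive.", class = "nichebounds_input_error")
  }
  stopifnot(is.data.frame(occ))
  species_levels <- sort(unique(occ$species))
  kept <- purrr::map(seq_along(species_levels), function(i) {
    sp <- species_levels[i]
    rows <- which(occ$species == sp)
    sub <- occ[rows, , drop = FALSE]
    ord <- withr::with_seed(derive_seed(seed, i), sample.int(nrow(sub)))
    keep <- greedy_thin(sub$longitude[ord], sub$latitude[ord], radius_km)
    rows[sort(ord[keep])]
  })
  occ[sort(unlist(kept)), , drop = FALSE]
}

# Greedy accept-if-far pass in the given order; returns indices accepted.
greedy_thin <- function(lon, lat, radius_km) {
  n <- length(lon)
  if (n == 0L) return(integer())
  keep <- 1L
  for (i in seq_len(n)[-1L]) {
    d <- geosphere::distHaversine(cbind(lon[i], lat[i]),
                                  cbind(lon[keep], lat[keep]),
                                  r = 6371) # km
    if (all(d >= radius_km)) keep <- c(keep, i)
  }
  keep
}

#' Annotate occurrence records with climate values
#'
#' Assigns each record the climate value of its nearest grid cell (great-circle
#' distance to cell centroids). Records farther than `max_distance_km` from any
#' centroid are outside climate coverage: they are flagged, reported, and
#' excluded from the returned table so downstream counts only see annotated
#' records.
#'
#' @param occ occurrence tibble with `longitude`, `latitude`.
#' @param field a [climate_field()] carrying `longitude`, `latitude` centroid
#'   columns.
#' @param max_distance_km coverage radius around a cell centroid; `Inf`
#'   (default) annotates every record with its nearest cell.
#' @return the input tibble with a `value` column (degrees C; `value1`,
#'   `value2` in the 2D case), rows outside coverage removed.
#' @export
extract_values <- function(occ, field, max_distance_km = Inf) {
  stopifnot(is.data.frame(occ), inherits(field, "climate_field"))
  if (!all(c("longitude", "latitude") %in% names(field))) {
    abort("climate field has no cell centroids (longitude/latitude columns).",
          class = "nichebounds_input_error")
  }
  if (nrow(occ) == 0L) {
    out <- occ
    for (vc in attr(field, "value_cols")) out[[vc]] <- numeric(0)
    return(out)
  }
  nn <- nearest_cell(occ$longitude, occ$latitude,
                     field$longitude, field$latitude)
  covered <- nn$dist_km <= max_distance_km
  if (!any(covered)) {
    warn("no occurrence record falls within climate coverage.",
         class = "nichebounds_empty_annotation")
  } else if (any(!covered)) {
    inform(sprintf("%d record(s) outside climate coverage excluded.",
                   sum(!covered)))
  }
  out <- occ[covered, , drop = FALSE]
  for (vc in attr(field, "value_cols")) {
    out[[vc]] <- field[[vc]][nn$index[covered]]
  }
  out
}

# Nearest centroid by great-circle angle, via unit-vector dot products so the
# full occurrences-by-cells distance matrix is built in bounded chunks.
nearest_cell <- function(lon, lat, cell_lon, cell_lat) {
  to_xyz <- function(lon, lat) {
    lam <- lon * pi / 180; phi <- lat * pi / 180
    cbind(cos(phi) * cos(lam), cos(phi) * sin(lam), sin(phi))
  }
  p <- to_xyz(lon, lat)
  q <- to_xyz(cell_lon, cell_lat)
  n <- nrow(p)
  index <- integer(n); cosang <- numeric(n)
  chunk <- max(1L, floor(4e6 / max(nrow(q), 1L)))
  idx <- 1L
  while (idx <= n) {
    j <- idx:min(idx + chunk - 1L, n)
    m <- p[j, , drop = FALSE] %*% t(q)
    index[j] <- max.col(m, ties.method = "first")
    cosang[j] <- m[cbind(seq_along(j), index[j])]
    idx <- idx + chunk
  }
  list(index = index, dist_km = acos(pmin(pmax(cosang, -1), 1)) * 6371)
}
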