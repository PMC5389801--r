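#' Build a validated equal-area climate field
#'
#' The available environment is represented by an equal-area grid: every cell
#' carries one climate value (degrees C; two value columns for the 2D case) and
#' the same surface area, so the set of cell values is an unweighted sample of
#' the environments available in the region. Equal areas are the contract an
#' equal-area map projection exists to provide, so only the weights are
#' checked; no projection is computed.
#'
#' @param cell_table data frame with columns `cell_id`, `area_km2` and `value`
#'   (or `value1`, `value2` for two climate axes). Optional `longitude` and
#'   `latitude` cell-centroid columns are kept and used by
#'   [extract_values()] and thinning tests.
#' @return a `climate_field`: a tibble with one row per cell, row order
#'   preserved.
#' @examples
#' climate_field(data.frame(cell_id = 1:3, area_km2 = 1e4,
#'                          value = c(5, 15, 25)))
#' @export
climate_field <- function(cell_table) {
  if (!is.data.frame(cell_table) || nrow(cell_table) == 0L) {
    abort("`cell_table` must be a non-empty data frame.",
          class = "nichebounds_input_error")
  }
  value_cols <- intersect(c("value", "value1", "value2"), names(cell_table))
  if ("value" %in% value_cols) value_cols <- "value"
  need <- c("cell_id", "area_km2")
  missing_cols <- setdiff(need, names(cell_table))
  if (length(missing_cols) || length(value_cols) == 0L) {
    abort(paste0("`cell_table` must have columns cell_id, area_km2 and value",
                 " (or value1,value2); missing: ",
                 paste(c(missing_cols,
                         if (!length(value_cols)) "value"), collapse = ", ")),
          class = "nichebounds_format_error")
  }
  tab <- tibble::as_tibble(cell_table)
  if (anyDuplicated(tab$cell_id)) {
    abort("cell_ids must be unique.", class = "nichebounds_validation_error")
  }
  area <- as.numeric(tab$area_km2)
  if (any(!is.finite(area)) || any(area <= 0)) {
    abort("all cell areas must be finite and positive.",
          class = "nichebounds_validation_error")
  }
  if (diff(range(area)) > 1e-9 * max(abs(area))) {
    abort("cells must have equal areas (equal-area grid contract).",
          class = "nichebounds_validation_error")
  }
  for (vc in value_cols) {
    bad <- which(!is.finite(as.numeric(tab[[vc]])))
    if (length(bad)) {
      abort(sprintf("non-finite climate value in column `%s` at cell_id %s.",
                    vc, paste(utils::head(tab$cell_id[bad], 3L), collapse = ", ")),
            class = "nichebounds_validation_error")
    }
  }
  attr(tab, "value_cols") <- value_cols
  class(tab) <- c("climate_field", class(tab))
  tab
}

#' Read a climate field from a CSV cell table
#'
#' @param path CSV with header `cell_id,area_km2,value` (or `value1,value2`),
#'   optionally `longitude,latitude` centroids.
#' @param tenths if `TRUE` the value column(s) are stored in tenths of degrees
#'   C (the Bio1 storage convention) and are rescaled with [scale_bio1()].
#' @return a `climate_field` tibble.
#' @export
read_climate_field <- function(path, tenths = FALSE) {
  if (!file.exists(path)) {
    abort(sprintf("climate file not found: %s", path),
          class = "nichebounds_io_error")
  }
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  vcols <- intersect(c("value", "value1", "value2"), names(tab))
  if (tenths) {
    for (vc in vcols) tab[[vc]] <- scale_bio1(tab[[vc]])
  }
  climate_field(tab)
}

#' Convert Bio1-style stored values to degrees C
#'
#' Bioclimatic mean-temperature layers conventionally store tenths of degrees
#' C as integers; analysis is in degrees C throughout.
#'
#' @param raw numeric, tenths of degrees C.
#' @return `raw / 10`, degrees C.
#' @examples
#' scale_bio1(253)  # 25.3
#' @export
scale_bio1 <- function(raw) {
  if (!is.numeric(raw) || any(!is.finite(raw))) {
    abort("`raw` must be finite numeric (tenths of degrees C).",
          class = "nichebounds_input_error")
  }
  raw / 10
}

#' Range of available climates in a field
#'
#' The `[min, max]` of cell values, one row per climate axis. This interval
#' anchors the conversion of kernel proportions to degrees C and the
#' random-interval null model for fundamental-niche volumes.
#'
#' @param field a [climate_field()].
#' @return tibble with columns `variable`, `lo`, `hi`.
#' @export
environment_range <- function(field) {
  stopifnot(inherits(field, "climate_field"))
  if (nrow(field) == 0L) {
    abort("climate field is empty.", class = "nichebounds_input_error")
  }
  vcols <- attr(field, "value_cols")
  tibble::tibble(
    variable = vcols,
    lo = unname(vapply(vcols, function(v) min(field[[v]]), numeric(1))),
    hi = unname(vapply(vcols, function(v) max(field[[v]]), numeric(1)))
  )
}

# Accept an environment_range() tibble or a plain c(lo, hi).
as_range_pair <- function(env_range) {
  if (is.data.frame(env_range)) {
    c(env_range$lo[1L], env_range$hi[1L])
  } else if (is.numeric(env_range) && length(env_range) == 2L) {
    as.numeric(env_range)
  } else {
    abort("`env_range` must be an environment_range() tibble or c(lo, hi).",
          class = "nichebounds_input_error")
  }
}
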