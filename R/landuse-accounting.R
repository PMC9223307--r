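#' Tabulate land-use areas per zone and year
#'
#' Raster-native accounting: the area of a class is its cell count times
#' the nominal cell area, with nodata (NA) cells excluded and boundary
#' cells belonging wholly to the zone of their centre. Every (zone, year)
#' carries a complete set of the six primary classes (zeros where a class
#' is absent), plus an `"ALL"` zone aggregating the whole grid.
#'
#' @param x An `es_scene` from [generate_scene()], or a single integer
#'   land-use matrix (codes 1-6, NA for nodata).
#' @param zones Optional integer matrix of zone labels, same shape as the
#'   grid. Ignored when `x` is a scene (the scene's zones are used).
#' @param cell_area Cell area in km2 (ignored for scenes, which carry
#'   their own).
#' @param year Year label for a single-matrix input (default `NA`).
#' @return A tibble with columns `zone` (character; `"ALL"` plus zone
#'   labels), `year`, `land_class`, `area_km2`.
#' @export
#' @examples
#' g <- matrix(c(1L, 1L, 2L, 5L), 2, 2)
#' tabulate_areas(g, cell_area = 1, year = 2000)
tabulate_areas <- function(x, zones = NULL, cell_area = 1, year = NA) {
  if (inherits(x, "es_scene")) {
    tabs <- purrr::imap(
      x$landuse,
      function(grid, y) {
        tabulate_one(grid, x$zones, x$config$cell_area, y)
      }
    )
    return(bind_rows(tabs))
  }
  tabulate_one(x, zones, cell_area, year)
}

tabulate_one <- function(grid, zones, cell_area, year) {
  if (!is.null(zones) && !all(dim(zones) == dim(grid))) {
    abort(sprintf(
      "alignment error: land-use grid is %dx%d but zones is %dx%d",
      nrow(grid), ncol(grid), nrow(zones), ncol(zones)
    ))
  }
  lut <- landuse_classes()
  vals <- as.vector(grid)
  keep <- !is.na(vals)
  z <- if (is.null(zones)) rep("ALL", length(vals)) else
    as.character(as.vector(zones))
  df <- tibble(zone = z[keep], code = vals[keep])
  per_zone <- df |>
    count(.data$zone, .data$code) |>
    mutate(area_km2 = .data$n * cell_area)
  whole <- per_zone |>
    group_by(.data$code) |>
    summarise(area_km2 = sum(.data$area_km2), .groups = "drop") |>
    mutate(zone = "ALL")
  out <- bind_rows(whole, if (!is.null(zones)) per_zone) |>
    select("zone", "code", "area_km2")
  # complete: every zone x class, zero-filled
  out <- out |>
    tidyr::complete(
      zone = unique(out$zone), code = lut$code,
      fill = list(area_km2 = 0)
    ) |>
    left_join(lut, by = "code") |>
    mutate(year = year) |>
    select("zone", "year", "land_class", "area_km2") |>
    arrange(.data$zone != "ALL", .data$zone,
            match(.data$land_class, lut$land_class))
  out
}

#' Land-use change between two years
#'
#' Net change per zone and class: `delta = A(to) - A(from)` and
#' `delta_pct = delta / A(from) * 100`, reported rounded half-away-from-
#' zero to 2 decimals as in printed change tables. A class absent in both
#' years changes by 0%; a class appearing from zero area has an undefined
#' percentage (`NA`, flagged) while its km2 change is still reported.
#'
#' @param areas An area tibble from [tabulate_areas()] (or any tibble with
#'   `zone`, `year`, `land_class`, `area_km2`).
#' @param period Length-2 vector `c(year_from, year_to)`; both must be
#'   present in `areas`.
#' @return A tibble with `zone`, `land_class`, `period`, `area_from`,
#'   `area_to`, `delta_km2`, `delta_pct`, `undefined_pct`.
#' @export
#' @examples
#' areas <- yreb_landuse_areas()
#' area_change(areas, c(2000, 2020))
area_change <- function(areas, period) {
  stop_if_missing_cols(areas, c("zone", "year", "land_class", "area_km2"),
                       "areas")
  change_table(areas, "area_km2", period, group = "land_class") |>
    rename(area_from = "from_value", area_to = "to_value",
           delta_km2 = "delta")
}

# Shared change arithmetic for area and ESV tables.
change_table <- function(df, value_col, period, group) {
  if (length(period) != 2) abort("period must be c(year_from, year_to)")
  missing_years <- setdiff(as.character(period), as.character(df$year))
  if (length(missing_years) > 0) {
    abort(sprintf(
      "year(s) not present in table: %s",
      paste(missing_years, collapse = ", ")
    ))
  }
  from <- df |>
    filter(as.character(.data$year) == as.character(period[1])) |>
    group_by(across(all_of(c("zone", group)))) |>
    summarise(from_value = sum(.data[[value_col]]), .groups = "drop")
  to <- df |>
    filter(as.character(.data$year) == as.character(period[2])) |>
    group_by(across(all_of(c("zone", group)))) |>
    summarise(to_value = sum(.data[[value_col]]), .groups = "drop")
  inner_join(from, to, by = c("zone", group)) |>
    mutate(
      period = paste0(period[1], "-", period[2]),
      delta = .data$to_value - .data$from_value,
      delta_pct = round_half_up(pct_change(.data$from_value,
                                           .data$to_value), 2),
      undefined_pct = .data$from_value == 0 & .data$to_value != 0
    )
}
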