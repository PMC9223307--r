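#' Packaged equivalent-factor value coefficients
#'
#' The per-class, per-service ecosystem-service value coefficients
#' (yuan per hectare per year) used by the equivalent-factor method: nine
#' services (gas regulation, climate regulation, water conservation, waste
#' disposal, soil formation and protection, biodiversity conservation,
#' food production, raw material, entertainment) by six primary land
#' classes. Construction land supplies no services (all-zero column).
#' A user-supplied CSV with the same schema may be passed instead.
#'
#' @param path Optional path to a replacement CSV with columns `service`,
#'   `land_class`, `vc_yuan_per_hm2`.
#' @return A tibble with columns `service`, `land_class`,
#'   `vc_yuan_per_hm2`.
#' @export
#' @examples
#' value_coefficients()
value_coefficients <- function(path = NULL) {
  if (is.null(path)) path <- pkg_extdata("value_coefficients.csv")
  vc <- readr::read_csv(path, show_col_types = FALSE)
  stop_if_missing_cols(vc, c("service", "land_class", "vc_yuan_per_hm2"),
                       "value coefficient table")
  if (any(vc$vc_yuan_per_hm2 < 0)) {
    abort("value coefficients must be non-negative")
  }
  vc
}

#' Packaged study-area land-use areas
#'
#' Whole-region areas (km2) of the six primary land classes in 2000,
#' 2005, 2010, 2015 and 2020, as tabulated for the Yangtze River Economic
#' Belt from 1 km classed land-use rasters. Shaped like the output of
#' [tabulate_areas()] (zone `"ALL"`).
#'
#' @param path Optional replacement CSV with columns `year`, `land_class`,
#'   `area_km2`.
#' @return A tibble with columns `zone`, `year`, `land_class`, `area_km2`.
#' @export
#' @examples
#' yreb_landuse_areas()
yreb_landuse_areas <- function(path = NULL) {
  if (is.null(path)) path <- pkg_extdata("yreb_landuse_areas.csv")
  readr::read_csv(path, show_col_types = FALSE) |>
    mutate(zone = "ALL") |>
    select("zone", "year", "land_class", "area_km2")
}

#' Ecosystem-service value by the equivalent-factor method
#'
#' `ESV = sum_k A_k * VC_k`: each class area (converted km2 -> hm2, i.e.
#' x100) times its per-service value coefficient. Values are reported in
#' 10^8 yuan (the "100 million yuan" unit of regional summary tables) at
#' full precision; round only for display.
#'
#' @param areas Area tibble from [tabulate_areas()] /
#'   [yreb_landuse_areas()].
#' @param coeffs Coefficient tibble from [value_coefficients()]. Every
#'   class present in `areas` must have a coefficient row.
#' @return A tibble with columns `zone`, `year`, `land_class`, `service`,
#'   `esv_1e8_yuan`.
#' @seealso [esv_totals()] for class/service/grand marginals,
#'   [esv_change()], [service_composition()].
#' @export
#' @examples
#' esv <- esv_compute(yreb_landuse_areas(), value_coefficients())
#' esv_totals(esv, by = "year")
esv_compute <- function(areas, coeffs = value_coefficients()) {
  stop_if_missing_cols(areas, c("zone", "year", "land_class", "area_km2"),
                       "areas")
  missing_classes <- setdiff(unique(areas$land_class),
                             unique(coeffs$land_class))
  if (length(missing_classes) > 0) {
    abort(sprintf(
      "no value coefficient for land class(es): %s",
      paste(missing_classes, collapse = ", ")
    ))
  }
  areas |>
    inner_join(coeffs, by = "land_class",
               relationship = "many-to-many") |>
    mutate(esv_1e8_yuan =
             .data$area_km2 * 100 * .data$vc_yuan_per_hm2 / 1e8) |>
    select("zone", "year", "land_class", "service", "esv_1e8_yuan")
}

#' Marginal totals of an ESV table
#'
#' @param esv Output of [esv_compute()].
#' @param by Marginal to keep: `"class"` (per zone, year, class),
#'   `"service"` (per zone, year, service) or `"year"` (grand total per
#'   zone and year).
#' @return A tibble with the grouping columns and `esv_1e8_yuan`.
#' @export
esv_totals <- function(esv, by = c("class", "service", "year")) {
  by <- match.arg(by)
  keys <- switch(by,
    class = c("zone", "year", "land_class"),
    service = c("zone", "year", "service"),
    year = c("zone", "year")
  )
  esv |>
    group_by(across(all_of(keys))) |>
    summarise(esv_1e8_yuan = sum(.data$esv_1e8_yuan), .groups = "drop")
}

#' Ecosystem-service value change between two years
#'
#' Same change arithmetic as [area_change()], applied to ESV aggregated by
#' class or by service.
#'
#' @param esv Output of [esv_compute()].
#' @param period `c(year_from, year_to)`.
#' @param by `"class"` or `"service"`.
#' @return A tibble with `zone`, the grouping column, `period`,
#'   `esv_from`, `esv_to`, `delta_1e8_yuan`, `delta_pct`,
#'   `undefined_pct`.
#' @export
#' @examples
#' esv <- esv_compute(yreb_landuse_areas())
#' esv_change(esv, c(2000, 2020), by = "class")
esv_change <- function(esv, period, by = c("class", "service")) {
  by <- match.arg(by)
  group <- if (by == "class") "land_class" else "service"
  change_table(esv, "esv_1e8_yuan", period, group = group) |>
    rename(esv_from = "from_value", esv_to = "to_value",
           delta_1e8_yuan = "delta")
}

#' Service composition of total supply in one year
#'
#' Per-service shares of the grand total (zone `"ALL"` unless specified),
#' in descending order.
#'
#' @param esv Output of [esv_compute()].
#' @param year Year to summarise.
#' @param zone Zone to summarise (default `"ALL"`).
#' @return A tibble with `service`, `esv_1e8_yuan`, `share_pct`, sorted by
#'   decreasing share; shares sum to 100.
#' @export
#' @examples
#' service_composition(esv_compute(yreb_landuse_areas()), 2000)
service_composition <- function(esv, year, zone = "ALL") {
  yr <- year
  zn <- zone
  sub <- esv |>
    filter(as.character(.data$year) == as.character(yr),
           .data$zone == zn)
  if (nrow(sub) == 0) {
    abort(sprintf("no ESV entries for zone '%s', year %s", zn, yr))
  }
  sub |>
    group_by(.data$service) |>
    summarise(esv_1e8_yuan = sum(.data$esv_1e8_yuan), .groups = "drop") |>
    mutate(share_pct = .data$esv_1e8_yuan / sum(.data$esv_1e8_yuan) * 100) |>
    arrange(desc(.data$share_pct))
}
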