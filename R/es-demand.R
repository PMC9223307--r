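#' Night-light composite statistics per zone
#'
#' From an integer DN grid (DMSP convention, 0-63): `I`, the average light
#' intensity of lit pixels (`sum(DN_j * N_j) / (N_t * 63)` over lit pixels
#' `1 <= DN <= 63`); `S`, the lit-pixel share `N_t / N`; and the composite
#' `NLCI = 0.8 I + 0.2 S`. A zone with no lit pixels gets `I = 0`,
#' `S = 0` (a genuine data-gap area, not missing data).
#'
#' @param dn Integer matrix with values in 0-63 (use [rescale_dn()] for
#'   continuous radiance products).
#' @param zones Optional zone-label matrix of the same shape; statistics
#'   are returned per zone plus an `"ALL"` row.
#' @param w_intensity,w_share Weights of `I` and `S` in the composite
#'   (defaults 0.8 and 0.2; must sum to 1).
#' @return A tibble with columns `zone`, `n`, `n_lit`, `I`, `S`, `nlci`.
#' @export
#' @examples
#' dn <- matrix(c(rep(0L, 5), 21L, 21L, 42L, 42L, 63L), 2, 5)
#' light_stats(dn)
light_stats <- function(dn, zones = NULL, w_intensity = 0.8,
                        w_share = 0.2) {
  if (abs(w_intensity + w_share - 1) > 1e-12) {
    abort("composite weights must sum to 1")
  }
  vals <- as.vector(dn)
  ok <- !is.na(vals)
  if (any(vals[ok] < 0 | vals[ok] > 63)) {
    abort(paste(
      "DN values outside [0, 63]; night-light input must be on the",
      "0-63 DN scale (rescale continuous radiance with rescale_dn())"
    ))
  }
  if (any(ok) && any(vals[ok] != floor(vals[ok]))) {
    abort("DN values must be integers")
  }
  if (!is.null(zones) && !all(dim(zones) == dim(dn))) {
    abort("alignment error: zones and DN grid differ in shape")
  }
  z <- if (is.null(zones)) rep("ALL", length(vals)) else
    as.character(as.vector(zones))
  df <- tibble(zone = z[ok], dn = vals[ok])
  one <- function(d) {
    lit <- d[d >= 1 & d <= 63]
    n_lit <- length(lit)
    tibble(
      n = length(d), n_lit = n_lit,
      I = if (n_lit == 0) 0 else sum(lit) / (n_lit * 63),
      S = n_lit / length(d)
    )
  }
  per_zone <- df |>
    group_by(.data$zone) |>
    reframe(one(.data$dn))
  out <- if (is.null(zones)) {
    per_zone
  } else {
    bind_rows(mutate(one(df$dn), zone = "ALL"), per_zone) |>
      select("zone", "n", "n_lit", "I", "S")
  }
  out |>
    mutate(nlci = w_intensity * .data$I + w_share * .data$S)
}

#' Land-use degree per zone
#'
#' The built-up share of a zone: construction-land area divided by total
#' zone area, in percent.
#'
#' @param areas Area tibble from [tabulate_areas()].
#' @return A tibble with columns `zone`, `year`, `degree_pct`.
#' @export
#' @examples
#' g <- matrix(c(5L, 5L, 1L, 1L), 2, 2)
#' landuse_degree(tabulate_areas(g, year = 2000))
landuse_degree <- function(areas) {
  stop_if_missing_cols(areas, c("zone", "year", "land_class", "area_km2"),
                       "areas")
  out <- areas |>
    group_by(.data$zone, .data$year) |>
    summarise(
      total = sum(.data$area_km2),
      built = sum(.data$area_km2[.data$land_class == "construction"]),
      .groups = "drop"
    )
  if (any(out$total == 0)) {
    bad <- out$zone[out$total == 0]
    abort(sprintf("zone(s) with zero area: %s",
                  paste(unique(bad), collapse = ", ")))
  }
  out |>
    mutate(degree_pct = .data$built / .data$total * 100) |>
    select("zone", "year", "degree_pct")
}

#' Ecosystem-service demand index
#'
#' The composite demand index per zone,
#' `X = D * log(P) * log(NLCI)`, with `D` the land-use degree (%), `P`
#' the population density (persons/km2) and `NLCI` the night-light
#' composite. Because `NLCI` lies in `[0, 1]`, it enters rescaled by
#' `nlci_scale` (default 100, a percent-style index), and both log terms
#' are floored at their `*_floor` argument (default 1) so that unlit or
#' unpopulated zones contribute zero rather than negative demand. The
#' index is monotone non-decreasing in each of `D`, `P`, `NLCI` and zero
#' when `D = 0`.
#'
#' @param inputs Tibble with columns `degree_pct`, `pop_density`, `nlci`
#'   (e.g. built by [zone_demand()]); extra columns pass through.
#' @param log_base Base of both logarithms (default 10).
#' @param nlci_scale Multiplier applied to `NLCI` before the log (default
#'   100).
#' @param p_floor,nlci_floor Floors applied inside the logs (default 1).
#' @return `inputs` with a `demand_index` column appended.
#' @export
#' @examples
#' demand_index(tibble::tibble(degree_pct = 50, pop_density = 1000,
#'                             nlci = 0.1))
demand_index <- function(inputs, log_base = 10, nlci_scale = 100,
                         p_floor = 1, nlci_floor = 1) {
  stop_if_missing_cols(inputs, c("degree_pct", "pop_density", "nlci"),
                       "demand inputs")
  with(inputs, {
    if (any(!is.finite(degree_pct) | !is.finite(pop_density) |
              !is.finite(nlci))) {
      abort("demand inputs must be finite")
    }
    if (any(degree_pct < 0) || any(pop_density < 0) || any(nlci < 0)) {
      abort("demand inputs must be non-negative")
    }
  })
  inputs |>
    mutate(demand_index =
             .data$degree_pct *
             log(pmax(.data$pop_density, p_floor), base = log_base) *
             log(pmax(.data$nlci * nlci_scale, nlci_floor),
                 base = log_base))
}

#' Per-zone demand table for a synthetic scene
#'
#' Assembles, for each zone and requested year, the full demand
#' decomposition: land-use degree from the year's land-use grid,
#' population density as zone population over zone area, the night-light
#' triple `(I, S, NLCI)` from the year's DN grid, and the demand index.
#'
#' @param scene An `es_scene`.
#' @param years Years to evaluate (default: all scene years).
#' @inheritParams demand_index
#' @return A tibble with columns `zone`, `year`, `degree_pct`,
#'   `pop_density`, `I`, `S`, `nlci`, `demand_index`.
#' @export
#' @examples
#' scene <- generate_scene(landscape_config(grid_shape = c(30, 30), seed = 2))
#' zone_demand(scene, years = 2000)
zone_demand <- function(scene, years = NULL, log_base = 10,
                        nlci_scale = 100, p_floor = 1, nlci_floor = 1) {
  stopifnot(inherits(scene, "es_scene"))
  if (is.null(years)) years <- scene$config$years
  years <- as.character(years)
  missing_years <- setdiff(years, names(scene$landuse))
  if (length(missing_years) > 0) {
    abort(sprintf("scene has no year(s): %s",
                  paste(missing_years, collapse = ", ")))
  }
  pop <- tibble(
    zone = as.character(as.vector(scene$zones)),
    pop = as.vector(scene$population)
  ) |>
    group_by(.data$zone) |>
    summarise(pop_density = mean(.data$pop), .groups = "drop")

  purrr::map(years, function(y) {
    degree <- tabulate_areas(scene$landuse[[y]], scene$zones,
                             scene$config$cell_area, y) |>
      filter(.data$zone != "ALL") |>
      landuse_degree()
    lights <- light_stats(scene$nightlight[[y]], scene$zones) |>
      filter(.data$zone != "ALL") |>
      select("zone", "I", "S", "nlci")
    degree |>
      inner_join(pop, by = "zone") |>
      inner_join(lights, by = "zone")
  }) |>
    bind_rows() |>
    demand_index(log_base = log_base, nlci_scale = nlci_scale,
                 p_floor = p_floor, nlci_floor = nlci_floor) |>
    select("zone", "year", "degree_pct", "pop_density", "I", "S",
           "nlci", "demand_index") |>
    arrange(.data$year, as.integer(.data$zone))
}
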