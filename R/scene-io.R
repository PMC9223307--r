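#' Read and write grid layers as plain text
#'
#' Grids travel as headerless tab-separated numeric matrices (one row per
#' grid row), a format every GIS and spreadsheet can ingest; the scene
#' configuration travels alongside as YAML so a written scene is fully
#' self-describing.
#'
#' @param grid A numeric or integer matrix.
#' @param path File path.
#' @return `read_grid_tsv()` returns a matrix; writers return the path
#'   invisibly.
#' @export
write_grid_tsv <- function(grid, path) {
  utils::write.table(grid, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_grid_tsv
#' @export
read_grid_tsv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  m
}

#' Write a synthetic scene to a directory
#'
#' One TSV grid per layer (`landuse_<year>.tsv`, `nightlight_<year>.tsv`,
#' `population.tsv`, `zones.tsv`) plus `config.yaml`.
#'
#' @param scene An `es_scene` from [generate_scene()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (y in names(scene$landuse)) {
    write_grid_tsv(scene$landuse[[y]], file.path(dir, paste0("landuse_", y, ".tsv")))
    write_grid_tsv(scene$nightlight[[y]], file.path(dir, paste0("nightlight_", y, ".tsv")))
  }
  write_grid_tsv(scene$population, file.path(dir, "population.tsv"))
  write_grid_tsv(scene$zones, file.path(dir, "zones.tsv"))
  cfg <- scene$config
  cfg$transition_rates <- as.list(as.data.frame(cfg$transition_rates))
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_scene
#' @export
read_scene <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg$transition_rates <- as_tibble(cfg$transition_rates)
  cfg$class_proportions <- unlist(cfg$class_proportions)
  cfg$pop_params$multiplier <- unlist(cfg$pop_params$multiplier)
  cfg$light_params$mean <- unlist(cfg$light_params$mean)
  cfg <- do.call(landscape_config, cfg[setdiff(names(cfg), character())])
  years <- as.character(cfg$years)
  landuse <- lapply(years, function(y) {
    m <- read_grid_tsv(file.path(dir, paste0("landuse_", y, ".tsv")))
    storage.mode(m) <- "integer"
    m
  })
  nightlight <- lapply(years, function(y) {
    m <- read_grid_tsv(file.path(dir, paste0("nightlight_", y, ".tsv")))
    storage.mode(m) <- "integer"
    m
  })
  names(landuse) <- years
  names(nightlight) <- years
  zones <- read_grid_tsv(file.path(dir, "zones.tsv"))
  storage.mode(zones) <- "integer"
  structure(
    list(
      landuse = landuse,
      population = read_grid_tsv(file.path(dir, "population.tsv")),
      nightlight = nightlight, zones = zones, config = cfg
    ),
    class = "es_scene"
  )
}

#' Reclassify raw land-use codes to the six primary classes
#'
#' Source land-use products use provider-specific codes; a user-supplied
#' mapping (CSV with columns `code`, `land_class`) reclassifies a raw grid
#' onto the package's six primary classes. No provider codes are
#' hard-wired.
#'
#' @param grid Integer matrix of raw codes.
#' @param class_map Data frame with columns `code` (raw integer code) and
#'   `land_class` (one of [landuse_classes()] names), or a path to such a
#'   CSV.
#' @param nodata_code Optional raw code treated as missing (`NA` in the
#'   output).
#' @return Integer matrix of primary-class codes 1-6 (NA where nodata).
#' @export
reclassify_landuse <- function(grid, class_map, nodata_code = NULL) {
  if (is.character(class_map)) {
    class_map <- readr::read_csv(class_map, show_col_types = FALSE)
  }
  stop_if_missing_cols(class_map, c("code", "land_class"), "class_map")
  lut <- landuse_classes()
  bad <- setdiff(class_map$land_class, lut$land_class)
  if (length(bad) > 0) {
    abort(sprintf(
      "class_map maps to unknown land class(es): %s",
      paste(bad, collapse = ", ")
    ))
  }
  vals <- as.vector(grid)
  if (!is.null(nodata_code)) vals[vals == nodata_code] <- NA
  out <- lut$code[match(class_map$land_class[match(vals, class_map$code)],
                        lut$land_class)]
  unknown <- !is.na(vals) & is.na(out)
  if (any(unknown)) {
    abort(sprintf(
      "grid contains unmapped code(s): %s",
      paste(sort(unique(vals[unknown])), collapse = ", ")
    ))
  }
  matrix(as.integer(out), nrow(grid), ncol(grid))
}

#' Rescale a continuous night-light raster to DMSP-style DN
#'
#' Clips a continuous radiance grid at a saturation percentile and
#' linearly rescales it to the integer DN range 0-63, so radiance products
#' can be fed to [light_stats()] alongside native DN grids.
#'
#' @param grid Numeric matrix of non-negative radiances.
#' @param saturation Percentile (0-1] mapped to DN 63 (default 0.99);
#'   values above it saturate at 63.
#' @return Integer matrix with values in 0-63.
#' @export
rescale_dn <- function(grid, saturation = 0.99) {
  if (any(grid < 0, na.rm = TRUE)) {
    abort("radiance grid contains negative values")
  }
  hi <- stats::quantile(grid, saturation, na.rm = TRUE, names = FALSE)
  if (hi <= 0) {
    return(matrix(0L, nrow(grid), ncol(grid)))
  }
  dn <- round(pmin(grid / hi, 1) * 63)
  matrix(as.integer(dn), nrow(grid), ncol(grid))
}
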