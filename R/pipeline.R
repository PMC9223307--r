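#' Build and validate a pipeline configuration
#'
#' A pipeline runs either in `"synthetic"` mode (a seeded scene is
#' generated, or read from `scene_dir`, and every stage runs: areas,
#' supply, demand, balance, classification, regression) or in `"tables"`
#' mode (printed area and coefficient tables in, supply-side tables out -
#' no geodata needed).
#'
#' @param x A named list of settings, or the path to a YAML file holding
#'   one. Recognised fields: `mode` ("synthetic"/"tables"); `seed`;
#'   `landscape` (arguments to [landscape_config()]) or `scene_dir`;
#'   `areas_csv`, `coefficients_csv` (tables mode; default: packaged
#'   tables); `demand` (list: `log_base`, `nlci_scale`, `p_floor`,
#'   `nlci_floor`); `balance_mode` ("normalized"/"raw"); `level_k`,
#'   `balance_k`; `regression` (list: `n_zones`, `beta`, `noise_sd`,
#'   `theta_grid`, `boot_reps`).
#' @return An object of class `es_pipeline_config` (a completed list).
#' @export
#' @examples
#' cfg <- pipeline_config(list(mode = "tables"))
pipeline_config <- function(x = list()) {
  if (is.character(x)) x <- yaml::read_yaml(x)
  defaults <- list(
    mode = "synthetic",
    seed = 1L,
    landscape = list(),
    scene_dir = NULL,
    areas_csv = NULL,
    coefficients_csv = NULL,
    demand = list(log_base = 10, nlci_scale = 100, p_floor = 1,
                  nlci_floor = 1),
    balance_mode = "normalized",
    level_k = 5L,
    balance_k = 7L,
    regression = list(
      n_zones = 120L,
      beta = c(0.5, -8, -5, -12, -2, -2, 6, 1, -0.5, -0.3, 0.7),
      noise_sd = 0.1,
      theta_grid = c(0.1, 0.3, 0.5, 0.7, 0.9),
      boot_reps = 100L
    )
  )
  cfg <- utils::modifyList(defaults, x, keep.null = TRUE)
  if (!cfg$mode %in% c("synthetic", "tables")) {
    abort(sprintf("unknown pipeline mode '%s'", cfg$mode))
  }
  if (!cfg$balance_mode %in% c("normalized", "raw")) {
    abort(sprintf("unknown balance mode '%s'", cfg$balance_mode))
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "es_pipeline_config")
}

#' Validate pipeline inputs without running the pipeline
#'
#' Checks referenced files exist and are readable, grids align in shape,
#' DN values sit in the 0-63 range, and land classes are known. Always
#' returns a report (never errors); entries are `"fatal"` or
#' `"warning"`.
#'
#' @param config An [pipeline_config()] object or the list/path it
#'   accepts.
#' @return A tibble with columns `level` and `message`; zero rows means
#'   clean.
#' @export
#' @examples
#' validate_inputs(list(mode = "tables"))
validate_inputs <- function(config) {
  config <- if (inherits(config, "es_pipeline_config")) config else
    pipeline_config(config)
  entries <- list()
  note <- function(level, message) {
    entries[[length(entries) + 1]] <<- tibble(level = level,
                                              message = message)
  }
  check_file <- function(path, what) {
    if (!is.null(path) && !file.exists(path)) {
      note("fatal", sprintf("%s not found: %s", what, path))
      return(FALSE)
    }
    !is.null(path)
  }
  if (config$mode == "tables") {
    if (check_file(config$areas_csv, "area table")) {
      tab <- tryCatch(readr::read_csv(config$areas_csv,
                                      show_col_types = FALSE),
                      error = function(e) NULL)
      if (is.null(tab)) {
        note("fatal", sprintf("area table unreadable: %s",
                              config$areas_csv))
      } else {
        bad <- setdiff(unique(tab$land_class),
                       landuse_classes()$land_class)
        if (length(bad) > 0) {
          note("fatal", sprintf("unknown land class(es) in area table: %s",
                                paste(bad, collapse = ", ")))
        }
      }
    }
    check_file(config$coefficients_csv, "coefficient table")
  } else if (!is.null(config$scene_dir)) {
    if (!dir.exists(config$scene_dir)) {
      note("fatal", sprintf("scene directory not found: %s",
                            config$scene_dir))
    } else {
      scene <- tryCatch(read_scene(config$scene_dir),
                        error = function(e) {
                          note("fatal", sprintf("scene unreadable: %s",
                                                conditionMessage(e)))
                          NULL
                        })
      if (!is.null(scene)) {
        shp <- dim(scene$zones)
        for (y in names(scene$landuse)) {
          if (!all(dim(scene$landuse[[y]]) == shp)) {
            note("fatal", sprintf("land-use grid %s misaligned with zones", y))
          }
          dn <- scene$nightlight[[y]]
          if (any(dn < 0 | dn > 63, na.rm = TRUE)) {
            note("fatal", sprintf(
              "DN values outside [0, 63] in nightlight grid %s", y
            ))
          }
          bad <- setdiff(unique(as.vector(scene$landuse[[y]])), 1:6)
          bad <- bad[!is.na(bad)]
          if (length(bad) > 0) {
            note("fatal", sprintf(
              "unknown land-class code(s) in grid %s: %s", y,
              paste(bad, collapse = ", ")
            ))
          }
        }
        if (!all(dim(scene$population) == shp)) {
          note("fatal", "population grid misaligned with zones")
        }
        if (any(scene$population < 0, na.rm = TRUE)) {
          note("warning", "negative population values present")
        }
      }
    }
  } else {
    ok <- tryCatch({
      do.call(landscape_config,
              c(config$landscape, list(seed = config$seed)))
      TRUE
    }, error = function(e) {
      note("fatal", conditionMessage(e))
      FALSE
    })
    invisible(ok)
  }
  if (length(entries) == 0) {
    return(tibble(level = character(), message = character()))
  }
  bind_rows(entries)
}

#' Run the full assessment pipeline
#'
#' Executes the configured stages and writes one tidy CSV per table
#' family into `out_dir` - `areas.csv`, `area_change.csv`, `esv.csv`,
#' `esv_change.csv`, `service_composition.csv`, `demand.csv`,
#' `balance.csv`, `balance_classes.csv`, `regression.csv` (synthetic
#' mode) - plus `metadata.json` recording every setting, seed and fitted
#' break so any table is regenerable from the sidecar alone. The same
#' configuration and seed always yield byte-identical files. A failing
#' stage aborts with the stage name and leaves a `FAILED` marker next to
#' any partial output.
#'
#' @param config An [pipeline_config()] object or the list/path it
#'   accepts.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of the output tibbles.
#' @export
#' @examples
#' out <- run_pipeline(list(mode = "tables"), tempfile("bundle"))
#' names(out)
run_pipeline <- function(config, out_dir) {
  config <- if (inherits(config, "es_pipeline_config")) config else
    pipeline_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  results <- list()
  meta <- list(config = unclass(config))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(sprintf("stage '%s' failed: %s", name,
                         conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  emit <- function(tbl, file) {
    readr::write_csv(tbl, file.path(out_dir, file))
    tbl
  }

  coeffs <- stage("coefficients",
                  value_coefficients(config$coefficients_csv))

  if (config$mode == "tables") {
    areas <- stage("areas", {
      if (is.null(config$areas_csv)) yreb_landuse_areas()
      else yreb_landuse_areas(config$areas_csv)
    })
  } else {
    scene <- stage("simulate", {
      if (!is.null(config$scene_dir)) read_scene(config$scene_dir)
      else generate_scene(
        do.call(landscape_config,
                c(config$landscape, list(seed = config$seed)))
      )
    })
    areas <- stage("areas", tabulate_areas(scene))
  }
  results$areas <- emit(areas, "areas.csv")

  years <- sort(unique(areas$year))
  full_period <- c(years[1], years[length(years)])
  results$area_change <- emit(
    stage("areas", if (length(years) > 1) area_change(areas, full_period)
          else tibble()),
    "area_change.csv"
  )

  esv <- stage("supply", esv_compute(areas, coeffs))
  results$esv <- emit(esv_totals(esv, by = "class"), "esv.csv")
  results$esv_change <- emit(
    stage("supply", if (length(years) > 1)
      esv_change(esv, full_period, by = "class") else tibble()),
    "esv_change.csv"
  )
  results$service_composition <- emit(
    stage("supply", service_composition(esv, years[1])),
    "service_composition.csv"
  )

  if (config$mode == "synthetic") {
    demand <- stage("demand", do.call(
      zone_demand, c(list(scene = scene), config$demand)
    ))
    results$demand <- emit(demand, "demand.csv")

    supply_zone <- esv_totals(esv, by = "year") |>
      filter(.data$zone != "ALL")
    bal <- stage("balance", balance_index(
      supply_zone, demand, mode = config$balance_mode
    ))
    results$balance <- emit(bal, "balance.csv")

    classed <- stage("classify", classify_balance(
      bal, k = config$balance_k
    ))
    results$balance_classes <- emit(classed, "balance_classes.csv")
    meta$balance_breaks <- lapply(attr(classed, "schemes"),
                                  function(s) s$breaks)

    reg_cfg <- config$regression
    reg_data <- stage("regress", generate_regression_dataset(
      n_zones = reg_cfg$n_zones, beta = reg_cfg$beta,
      noise_sd = reg_cfg$noise_sd, seed = config$seed + 1L
    ))
    qp <- stage("regress", quantile_path(
      reg_data, theta_grid = reg_cfg$theta_grid,
      se = "bootstrap", boot_reps = reg_cfg$boot_reps,
      seed = config$seed + 2L
    ))
    results$regression <- emit(tidy(qp), "regression.csv")
    meta$regression <- list(
      true_beta = attr(reg_data, "beta"),
      crossings = qp$crossings
    )
  }

  meta$files <- sort(setdiff(list.files(out_dir), "metadata.json"))
  jsonlite::write_json(meta, file.path(out_dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}
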