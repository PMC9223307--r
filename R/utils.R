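#' Canonical primary land-use classes
#'
#' The six primary classes used throughout the package, in their
#' conventional reporting order. Codes 1-6 are the integer values stored in
#' land-use grids.
#'
#' @return A tibble with columns `code` (integer) and `land_class`
#'   (character).
#' @export
#' @examples
#' landuse_classes()
landuse_classes <- function() {
  tibble(
    code = 1:6,
    land_class = c(
      "cultivated", "woodland", "grassland",
      "water", "construction", "unused"
    )
  )
}

# Detailed land-use classes used as quantile-regression covariates:
# built-up ("living/production") classes first, ecological classes after.
detailed_classes <- function() {
  c(
    "urban", "rural_settlement", "other_construction",
    "paddy_field", "dry_land",
    "other_forest", "natural_grassland", "canal", "forest", "lake"
  )
}

# Round half away from zero (the convention of printed summary tables;
# base round() is half-to-even).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Percent change with the degenerate-start rule: 0 -> 0 gives 0,
# 0 -> nonzero is undefined (NA, flagged by callers).
pct_change <- function(from, to) {
  dplyr::case_when(
    from == 0 & to == 0 ~ 0,
    from == 0 ~ NA_real_,
    TRUE ~ (to - from) / from * 100
  )
}

stop_if_missing_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# Path to a packaged extdata file, erroring clearly if absent.
pkg_extdata <- function(file) {
  path <- system.file("extdata", file, package = "esdbalance")
  if (!nzchar(path)) {
    abort(sprintf("packaged data file '%s' not found", file))
  }
  path
}
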