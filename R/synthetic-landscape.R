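#' Configure a synthetic landscape
#'
#' Builds the configuration object consumed by [generate_scene()]. The
#' defaults emulate a large subtropical river-basin study area observed at
#' 1 km resolution over five census years: a cultivated/woodland-dominated
#' class mix, a dominant cultivated-to-construction conversion pathway,
#' population density concentrated on built-up land, and DMSP-style
#' night-light digital numbers (integers 0-63) that are brightest over
#' construction land.
#'
#' @param grid_shape Integer vector `c(rows, cols)` of the cell grid.
#' @param cell_area Area of one cell in km2 (default 1, i.e. 1 km grid).
#' @param years Ordered vector of year labels; one land-use and one
#'   night-light grid is produced per year.
#' @param class_proportions Named numeric vector over the six primary
#'   classes (see [landuse_classes()]) giving first-year class shares;
#'   must sum to 1.
#' @param transition_rates Data frame with columns `from`, `to`, `rate`:
#'   per-interval probability that a cell of class `from` converts to
#'   `to`. Unlisted mass is retained (cell keeps its class). Each class's
#'   outflow must sum to at most 1.
#' @param pop_params List with `base` (persons/km2), `multiplier` (named
#'   vector per class) and `sd_log` (log-normal noise sd). Population is
#'   `base * multiplier[class] * exp(N(0, sd_log))`.
#' @param light_params List with `mean` (named DN mean per class) and `sd`
#'   (DN noise sd); draws are rounded and clipped to the integer range
#'   0-63.
#' @param n_zones Number of contiguous zones (county-like reporting
#'   units).
#' @param seed Integer RNG seed; the whole scene is a deterministic
#'   function of the configuration including this seed.
#'
#' @return An object of class `landscape_config` (a validated list).
#' @seealso [generate_scene()]
#' @export
#' @examples
#' cfg <- landscape_config(grid_shape = c(40, 40), n_zones = 6, seed = 1)
#' scene <- generate_scene(cfg)
landscape_config <- function(grid_shape = c(60, 60),
                             cell_area = 1,
                             years = c(2000, 2005, 2010, 2015, 2020),
                             class_proportions = c(
                               cultivated = 0.312, woodland = 0.458,
                               grassland = 0.167, water = 0.028,
                               construction = 0.024, unused = 0.011
                             ),
                             transition_rates = default_transitions(),
                             pop_params = list(
                               base = 80,
                               multiplier = c(
                                 cultivated = 2, woodland = 0.2,
                                 grassland = 0.4, water = 0.1,
                                 construction = 60, unused = 0.05
                               ),
                               sd_log = 0.6
                             ),
                             light_params = list(
                               mean = c(
                                 cultivated = 6, woodland = 1,
                                 grassland = 2, water = 1,
                                 construction = 48, unused = 0
                               ),
                               sd = 5
                             ),
                             n_zones = 9,
                             seed = 1) {
  cfg <- structure(
    list(
      grid_shape = as.integer(grid_shape), cell_area = cell_area,
      years = years, class_proportions = class_proportions,
      transition_rates = transition_rates, pop_params = pop_params,
      light_params = light_params, n_zones = as.integer(n_zones),
      seed = as.integer(seed)
    ),
    class = "landscape_config"
  )
  validate_landscape_config(cfg)
  cfg
}

# Dominant pathway: cultivated -> construction; secondary conversions keep
# the other classes mildly dynamic, as in a rapidly urbanising basin.
default_transitions <- function() {
  tibble(
    from = c("cultivated", "cultivated", "grassland", "grassland", "unused"),
    to = c("construction", "water", "construction", "woodland", "grassland"),
    rate = c(0.015, 0.002, 0.004, 0.003, 0.002)
  )
}

validate_landscape_config <- function(cfg) {
  classes <- landuse_classes()$land_class
  if (length(cfg$grid_shape) != 2 || any(cfg$grid_shape < 1)) {
    abort("configuration error: grid_shape must be two positive integers")
  }
  if (cfg$cell_area <= 0) {
    abort("configuration error: cell_area must be positive")
  }
  if (length(cfg$years) < 1) {
    abort("configuration error: years must be non-empty")
  }
  p <- cfg$class_proportions
  if (!all(names(p) %in% classes)) {
    bad <- setdiff(names(p), classes)
    abort(sprintf(
      "configuration error: unknown class in class_proportions: %s",
      paste(bad, collapse = ", ")
    ))
  }
  if (abs(sum(p) - 1) > 1e-9) {
    abort(sprintf(
      "configuration error: class_proportions sum to %.12f, not 1",
      sum(p)
    ))
  }
  if (any(p < 0)) {
    abort("configuration error: class_proportions must be non-negative")
  }
  tr <- cfg$transition_rates
  stop_if_missing_cols(tr, c("from", "to", "rate"), "transition_rates")
  bad_cls <- setdiff(unique(c(tr$from, tr$to)), classes)
  if (length(bad_cls) > 0) {
    abort(sprintf(
      "configuration error: unknown class in transition_rates: %s",
      paste(bad_cls, collapse = ", ")
    ))
  }
  if (any(tr$rate < 0)) {
    bad <- tr[tr$rate < 0, ]
    abort(sprintf(
      "configuration error: negative transition rate for %s -> %s",
      bad$from[1], bad$to[1]
    ))
  }
  outflow <- tapply(tr$rate, tr$from, sum)
  if (any(outflow > 1 + 1e-12)) {
    bad <- names(outflow)[outflow > 1 + 1e-12]
    abort(sprintf(
      "configuration error: outflow from class '%s' exceeds 1", bad[1]
    ))
  }
  n_cells <- prod(cfg$grid_shape)
  if (cfg$n_zones < 1 || cfg$n_zones > n_cells) {
    abort("configuration error: n_zones must be between 1 and rows*cols")
  }
  invisible(cfg)
}

# 6x6 row-stochastic transition matrix from the long rate table.
transition_matrix <- function(cfg) {
  classes <- landuse_classes()$land_class
  P <- diag(6)
  dimnames(P) <- list(classes, classes)
  tr <- cfg$transition_rates
  for (i in seq_len(nrow(tr))) {
    P[tr$from[i], tr$to[i]] <- P[tr$from[i], tr$to[i]] + tr$rate[i]
    P[tr$from[i], tr$from[i]] <- P[tr$from[i], tr$from[i]] - tr$rate[i]
  }
  P
}

#' Generate a synthetic multi-year scene
#'
#' Simulates, from a seeded configuration: a first-year categorical
#' land-use grid drawn from the configured class shares; per-interval
#' Markov class transitions giving one land-use grid per year; a
#' population-density grid tied to first-year land class; per-year
#' night-light DN grids (integer 0-63) tied to the year's land class; and
#' a partition of the grid into contiguous zones (Voronoi cells of a
#' seeded k-means on cell coordinates).
#'
#' @param config A [landscape_config()] object.
#' @return An object of class `es_scene`: a list with elements `landuse`
#'   (named list of integer matrices, one per year; codes as in
#'   [landuse_classes()]), `population` (numeric matrix, persons/km2),
#'   `nightlight` (named list of integer matrices), `zones` (integer
#'   matrix of zone labels `1..n_zones`) and `config`.
#' @export
#' @examples
#' scene <- generate_scene(landscape_config(grid_shape = c(30, 30), seed = 7))
#' table(scene$landuse[["2000"]])
generate_scene <- function(config) {
  validate_landscape_config(config)
  set.seed(config$seed)
  rows <- config$grid_shape[1]
  cols <- config$grid_shape[2]
  n <- rows * cols
  classes <- landuse_classes()$land_class

  # Contiguous zones: Voronoi cells of k-means centres are convex.
  coords <- cbind(
    row = rep(seq_len(rows), times = cols),
    col = rep(seq_len(cols), each = rows)
  )
  if (config$n_zones == 1) {
    zones <- matrix(1L, rows, cols)
  } else {
    # Lloyd iterations can cycle on a perfectly regular lattice; any
    # fixed point is a valid contiguous partition, so convergence
    # warnings are irrelevant here.
    km <- suppressWarnings(
      kmeans(coords, centers = config$n_zones, nstart = 5,
             iter.max = 100, algorithm = "Lloyd")
    )
    zones <- matrix(as.integer(km$cluster), rows, cols)
  }

  # First-year classes, then per-interval Markov relabelling.
  p0 <- setNames(numeric(6), classes)
  p0[names(config$class_proportions)] <- config$class_proportions
  P <- transition_matrix(config)
  landuse <- vector("list", length(config$years))
  names(landuse) <- as.character(config$years)
  current <- sample.int(6L, n, replace = TRUE, prob = p0)
  landuse[[1]] <- matrix(current, rows, cols)
  if (length(config$years) > 1) {
    for (t in seq(2, length(config$years))) {
      nxt <- current
      for (k in 1:6) {
        idx <- which(current == k)
        if (length(idx) > 0) {
          nxt[idx] <- sample.int(6L, length(idx), replace = TRUE,
                                 prob = P[k, ])
        }
      }
      current <- nxt
      landuse[[t]] <- matrix(current, rows, cols)
    }
  }

  # Population: class-dependent mean with multiplicative log-normal noise.
  mult <- setNames(numeric(6), classes)
  mult[names(config$pop_params$multiplier)] <- config$pop_params$multiplier
  first <- as.vector(landuse[[1]])
  population <- matrix(
    config$pop_params$base * mult[first] *
      rlnorm(n, meanlog = 0, sdlog = config$pop_params$sd_log),
    rows, cols
  )

  # Night light per year: class-mean DN plus noise, rounded into 0-63.
  dn_mean <- setNames(numeric(6), classes)
  dn_mean[names(config$light_params$mean)] <- config$light_params$mean
  nightlight <- lapply(landuse, function(lu) {
    dn <- round(dn_mean[as.vector(lu)] +
                  rnorm(n, sd = config$light_params$sd))
    matrix(as.integer(pmin(pmax(dn, 0), 63)), rows, cols)
  })

  structure(
    list(
      landuse = landuse, population = population,
      nightlight = nightlight, zones = zones, config = config
    ),
    class = "es_scene"
  )
}

#' @export
print.es_scene <- function(x, ...) {
  cat(sprintf(
    "<es_scene> %d x %d cells (%.3g km2/cell), %d year(s), %d zone(s)\n",
    x$config$grid_shape[1], x$config$grid_shape[2], x$config$cell_area,
    length(x$landuse), max(x$zones)
  ))
  invisible(x)
}

#' Generate a zone-level regression dataset with known coefficients
#'
#' Draws per-zone land-use composition on the simplex (10 detailed-class
#' proportions plus an implicit remainder, so the covariates are not
#' collinear with the intercept) and a balance-index response
#' `y = beta0 + x' beta + e`. The noise is Gaussian and may be made
#' heteroscedastic by letting its sd grow linearly with one covariate,
#' which makes that covariate's conditional-quantile slope change across
#' quantiles - the regime quantile regression is designed to detect.
#'
#' @param n_zones Number of zones (rows); at least 30.
#' @param beta Numeric vector of length 11: intercept then one coefficient
#'   per detailed class in the order of `colnames`: urban,
#'   rural_settlement, other_construction, paddy_field, dry_land,
#'   other_forest, natural_grassland, canal, forest, lake.
#' @param noise_sd Baseline noise standard deviation (>= 0).
#' @param seed Integer RNG seed.
#' @param sd_covariate Optional name of one covariate; if given, the noise
#'   sd for row i is `noise_sd + sd_slope * x[i, sd_covariate]`.
#' @param sd_slope Slope of the heteroscedastic sd term (default 0:
#'   homoscedastic).
#'
#' @return A tibble with columns `zone`, `balance_index` and the 10
#'   proportion columns; the true coefficient vector is attached as
#'   attribute `beta`.
#' @export
#' @examples
#' d <- generate_regression_dataset(100, beta = c(1, rep(-2, 5), rep(1, 5)),
#'                                  noise_sd = 0.1, seed = 1)
#' attr(d, "beta")
generate_regression_dataset <- function(n_zones, beta, noise_sd, seed,
                                        sd_covariate = NULL, sd_slope = 0) {
  if (n_zones < 30) {
    abort("n_zones must be at least 30")
  }
  if (length(beta) != 11) {
    abort("beta must have length 11 (intercept + 10 class proportions)")
  }
  if (noise_sd < 0) {
    abort("noise_sd must be non-negative")
  }
  vars <- detailed_classes()
  if (!is.null(sd_covariate) && !sd_covariate %in% vars) {
    abort(sprintf("unknown sd_covariate '%s'", sd_covariate))
  }
  set.seed(seed)
  # Dirichlet over 10 classes + remainder via normalised gammas.
  g <- matrix(stats::rgamma(n_zones * 11, shape = 1), n_zones, 11)
  props <- g / rowSums(g)
  X <- props[, 1:10, drop = FALSE]
  colnames(X) <- vars
  mu <- beta[1] + as.vector(X %*% beta[-1])
  sd_i <- rep(noise_sd, n_zones)
  if (!is.null(sd_covariate)) {
    sd_i <- sd_i + sd_slope * X[, sd_covariate]
  }
  if (any(sd_i < 0)) {
    abort("heteroscedastic sd is negative for some rows; reduce sd_slope")
  }
  y <- mu + rnorm(n_zones, sd = sd_i)
  out <- bind_cols(
    tibble(zone = seq_len(n_zones), balance_index = y),
    as_tibble(X)
  )
  attr(out, "beta") <- setNames(beta, c("(Intercept)", vars))
  out
}
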