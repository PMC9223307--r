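#' Plot a synthetic scene layer
#'
#' Tile map of one scene layer: land use (categorical), zones, population
#' (log10 fill) or night-light DN.
#'
#' @param object An `es_scene`.
#' @param layer `"landuse"`, `"zones"`, `"population"` or
#'   `"nightlight"`.
#' @param year Year label for the yearly layers (default: first year).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.es_scene <- function(object, layer = c("landuse", "zones",
                                                "population",
                                                "nightlight"),
                              year = NULL, ...) {
  layer <- match.arg(layer)
  if (is.null(year)) year <- object$config$years[1]
  m <- switch(layer,
    landuse = object$landuse[[as.character(year)]],
    nightlight = object$nightlight[[as.character(year)]],
    population = object$population,
    zones = object$zones
  )
  df <- tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row))
  p <- if (layer == "landuse") {
    lut <- landuse_classes()
    p + ggplot2::geom_tile(ggplot2::aes(
      fill = factor(.data$value, levels = lut$code,
                    labels = lut$land_class)
    )) +
      ggplot2::labs(fill = "land class")
  } else if (layer == "zones") {
    p + ggplot2::geom_tile(ggplot2::aes(fill = factor(.data$value))) +
      ggplot2::labs(fill = "zone")
  } else if (layer == "population") {
    p + ggplot2::geom_tile(ggplot2::aes(fill = log10(.data$value + 1))) +
      ggplot2::labs(fill = "log10(pop + 1)")
  } else {
    p + ggplot2::geom_tile(ggplot2::aes(fill = .data$value)) +
      ggplot2::labs(fill = "DN")
  }
  p + ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s (%s)", layer, year),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot ecosystem-service value trends
#'
#' Per-class ESV trajectories over the assessment years for one zone
#' (default the whole region).
#'
#' @param esv Output of [esv_compute()].
#' @param zone Zone to plot (default `"ALL"`).
#' @return A ggplot object.
#' @export
plot_esv_trend <- function(esv, zone = "ALL") {
  zn <- zone
  df <- esv_totals(esv, by = "class") |>
    filter(.data$zone == zn)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$year, y = .data$esv_1e8_yuan,
    colour = .data$land_class, group = .data$land_class
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "year", y = "ESV (1e8 yuan)",
                  colour = "land class") +
    ggplot2::theme_minimal()
}

#' Plot a quantile-regression path
#'
#' Coefficient estimates against the quantile for each term, with a
#' bootstrap-SE ribbon where available and the OLS estimate as a dashed
#' reference line - the conventional display of how covariate effects
#' shift across the conditional distribution.
#'
#' @param object An `es_qpath` from [quantile_path()].
#' @param terms Terms to display (default: all but the intercept).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.es_qpath <- function(object, terms = NULL, ...) {
  td <- tidy(object)
  if (is.null(terms)) {
    terms <- setdiff(unique(td$term), "(Intercept)")
  }
  qd <- filter(td, .data$method == "quantile", .data$term %in% terms)
  od <- filter(td, .data$method == "OLS", .data$term %in% terms)
  p <- ggplot2::ggplot(qd, ggplot2::aes(x = .data$theta,
                                        y = .data$estimate))
  if (!all(is.na(qd$std.error))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$estimate - 1.96 * .data$std.error,
                   ymax = .data$estimate + 1.96 * .data$std.error),
      alpha = 0.2
    )
  }
  p +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(data = od, ggplot2::aes(yintercept = .data$estimate),
                        linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$term), scales = "free_y") +
    ggplot2::labs(x = "quantile", y = "coefficient") +
    ggplot2::theme_minimal()
}

#' Plot the balance typology
#'
#' Zone-by-year tile map of the surplus/balance/deficit classes from
#' [classify_balance()].
#'
#' @param classed Output of [classify_balance()].
#' @return A ggplot object.
#' @export
plot_balance_classes <- function(classed) {
  lv <- c("high deficit", "higher deficit", "general deficit", "balance",
          "general surplus", "higher surplus", "high surplus")
  df <- mutate(classed, class_label = factor(.data$class_label,
                                             levels = lv))
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$year), y = factor(.data$zone),
    fill = .data$class_label
  )) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_brewer(palette = "RdYlGn", drop = FALSE,
                               na.value = "grey80") +
    ggplot2::labs(x = "year", y = "zone", fill = "class") +
    ggplot2::theme_minimal()
}
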