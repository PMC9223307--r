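#' Supply-demand balance index per zone
#'
#' `BI = supply - demand` per zone and year. Because supply is monetary
#' and the demand index dimensionless, the default `"normalized"` mode
#' min-max scales both sides to `[0, 1]` within each year before
#' subtracting (so `BI` lies in `[-1, 1]` and is antisymmetric under
#' swapping supply and demand); `"raw"` subtracts the unscaled values
#' literally. Positive `BI` is surplus, negative deficit.
#'
#' @param supply Tibble with columns `zone`, `year` and a supply column
#'   (`esv_1e8_yuan` or `supply`), e.g. `esv_totals(esv, by = "year")`.
#' @param demand Tibble with columns `zone`, `year`, `demand_index`, e.g.
#'   from [zone_demand()].
#' @param mode `"normalized"` (default) or `"raw"`.
#' @return A tibble with `zone`, `year`, `supply`, `demand`,
#'   `supply_scaled`, `demand_scaled`, `balance`; the mode is attached as
#'   attribute `mode`.
#' @export
#' @examples
#' s <- tibble::tibble(zone = c("1", "2"), year = 2020,
#'                     supply = c(10, 2))
#' d <- tibble::tibble(zone = c("1", "2"), year = 2020,
#'                     demand_index = c(1, 8))
#' balance_index(s, d)
balance_index <- function(supply, demand, mode = c("normalized", "raw")) {
  mode <- match.arg(mode)
  if ("esv_1e8_yuan" %in% names(supply) && !"supply" %in% names(supply)) {
    supply <- rename(supply, supply = "esv_1e8_yuan")
  }
  stop_if_missing_cols(supply, c("zone", "year", "supply"), "supply")
  stop_if_missing_cols(demand, c("zone", "year", "demand_index"), "demand")
  supply <- mutate(supply, zone = as.character(.data$zone),
                   year = as.character(.data$year))
  demand <- mutate(demand, zone = as.character(.data$zone),
                   year = as.character(.data$year))
  unmatched <- c(
    setdiff(paste(supply$zone, supply$year),
            paste(demand$zone, demand$year)),
    setdiff(paste(demand$zone, demand$year),
            paste(supply$zone, supply$year))
  )
  if (length(unmatched) > 0) {
    abort(sprintf(
      "supply and demand zone sets differ; unmatched (zone year): %s",
      paste(unique(unmatched), collapse = "; ")
    ))
  }
  out <- inner_join(select(supply, "zone", "year", "supply"),
                    select(demand, "zone", "year",
                           demand = "demand_index"),
                    by = c("zone", "year"))
  out <- if (mode == "normalized") {
    out |>
      group_by(.data$year) |>
      mutate(supply_scaled = minmax(.data$supply),
             demand_scaled = minmax(.data$demand)) |>
      ungroup()
  } else {
    mutate(out, supply_scaled = .data$supply,
           demand_scaled = .data$demand)
  }
  out <- mutate(out, balance = .data$supply_scaled - .data$demand_scaled)
  attr(out, "mode") <- mode
  out
}

# Min-max to [0,1]; a constant vector maps to 0.
minmax <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Jenks natural-breaks classification
#'
#' Optimal univariate classification into `k` classes minimising the
#' total within-class sum of squared deviations (Fisher's optimal
#' partition, computed by dynamic programming over the sorted values;
#' deterministic, globally optimal).
#'
#' @param values Numeric vector with at least `k` distinct values.
#' @param k Number of classes.
#' @return An object of class `es_breaks`: list with `breaks` (length
#'   `k + 1`: the minimum, the upper value of each of the first `k - 1`
#'   classes, and the maximum), `k`, and `within_ss` (the minimised
#'   objective).
#' @export
#' @examples
#' jenks_breaks(c(1, 2, 3, 10, 11, 12), k = 2)
jenks_breaks <- function(values, k) {
  x <- sort(values[!is.na(values)])
  n <- length(x)
  if (k < 1) abort("k must be at least 1")
  if (length(unique(x)) < k) {
    abort(sprintf(
      "cannot form %d classes from %d distinct value(s)",
      k, length(unique(x))
    ))
  }
  # prefix sums for O(1) within-class SSD
  c1 <- cumsum(x)
  c2 <- cumsum(x^2)
  ssq <- function(i, j) {
    s1 <- c1[j] - if (i > 1) c1[i - 1] else 0
    s2 <- c2[j] - if (i > 1) c2[i - 1] else 0
    s2 - s1^2 / (j - i + 1)
  }
  # cost[m, j]: best objective for first j points in m classes
  cost <- matrix(Inf, k, n)
  split_at <- matrix(0L, k, n) # first index of last class
  for (j in 1:n) {
    cost[1, j] <- ssq(1, j)
    split_at[1, j] <- 1L
  }
  if (k > 1) {
    for (m in 2:k) {
      for (j in m:n) {
        best <- Inf
        best_i <- m
        for (i in m:j) {
          cand <- cost[m - 1, i - 1] + ssq(i, j)
          if (cand < best) {
            best <- cand
            best_i <- i
          }
        }
        cost[m, j] <- best
        split_at[m, j] <- as.integer(best_i)
      }
    }
  }
  # backtrack class upper boundaries
  uppers <- numeric(k)
  j <- n
  for (m in k:1) {
    uppers[m] <- x[j]
    j <- split_at[m, j] - 1L
  }
  structure(
    list(breaks = c(x[1], uppers), k = k, within_ss = cost[k, n]),
    class = "es_breaks"
  )
}

#' @export
print.es_breaks <- function(x, ...) {
  cat(sprintf("<es_breaks> k = %d, within-class SS = %.6g\nbreaks: %s\n",
              x$k, x$within_ss,
              paste(signif(x$breaks, 6), collapse = ", ")))
  invisible(x)
}

#' Assign values to a fitted classification scheme
#'
#' Left-open intervals with ties at a break assigned to the lower class:
#' class `m` is `(b[m], b[m+1]]` (the first class also includes the
#' minimum). Values outside the fitted range go to the nearest terminal
#' class with a warning.
#'
#' @param values Numeric vector.
#' @param scheme An `es_breaks` from [jenks_breaks()].
#' @return Integer vector of class indices in `1..k` (1 = lowest values).
#' @export
#' @examples
#' sc <- jenks_breaks(c(1, 2, 3, 10, 11, 12), 2)
#' classify(c(1, 3, 10, 12), sc)
classify <- function(values, scheme) {
  stopifnot(inherits(scheme, "es_breaks"))
  b <- scheme$breaks
  out_of_range <- values < b[1] | values > b[length(b)]
  if (any(out_of_range, na.rm = TRUE)) {
    warn(sprintf(
      "%d value(s) outside the fitted range assigned to terminal classes",
      sum(out_of_range, na.rm = TRUE)
    ))
  }
  inner <- b[2:scheme$k] # upper bounds of classes 1..k-1
  idx <- 1L + vapply(values, function(v) sum(v > inner), integer(1))
  pmin(pmax(idx, 1L), scheme$k)
}

#' Five-level classification of a supply or demand vector
#'
#' Jenks natural breaks with `k` levels labelled from `"low"` up to
#' `"high"`, the conventional five-level map legend for supply and demand
#' indices. If the data hold fewer distinct values than `k`, the class
#' count collapses to what the data support.
#'
#' @param values Numeric vector.
#' @param k Number of levels (default 5).
#' @param labels Labels from lowest to highest; length `>= k`.
#' @return An ordered factor of length `length(values)`; the fitted
#'   scheme is attached as attribute `scheme`.
#' @export
#' @examples
#' classify_levels(c(1, 2, 10, 11, 30, 31, 60, 61, 100, 101))
classify_levels <- function(values, k = 5,
                            labels = c("low", "lower", "general",
                                       "higher", "high")) {
  k_eff <- min(k, length(unique(values[!is.na(values)])))
  if (length(labels) < k_eff) abort("not enough labels for k classes")
  scheme <- jenks_breaks(values, k_eff)
  idx <- classify(values, scheme)
  out <- factor(labels[idx], levels = labels[seq_len(k_eff)],
                ordered = TRUE)
  attr(out, "scheme") <- scheme
  out
}

#' Seven-class surplus/balance/deficit typology of a balance index
#'
#' Fits Jenks breaks with `k` classes (default 7) to the balance index,
#' names the class containing zero (or the class nearest zero when zero
#' lies outside the data range) `"balance"`, and grades classes above it
#' as surplus (`general` -> `higher` -> `high` with distance) and below
#' it as deficit. Breaks are refitted within each year by default,
#' matching year-by-year map legends; pass `per_year = FALSE` to fit one
#' scheme across all years for temporal comparability. With fewer
#' distinct values than `k` the class count collapses (all-equal values
#' give a single `"balance"` class).
#'
#' @param balance A tibble from [balance_index()] (columns `zone`,
#'   `year`, `balance`).
#' @param k Number of classes (default 7).
#' @param per_year Refit breaks per year (default TRUE).
#' @return `balance` with columns `class_idx` (1 = most deficit) and
#'   `class_label` appended; fitted schemes attached as attribute
#'   `schemes` (a named list by year, or `"all"`).
#' @export
#' @examples
#' bt <- tibble::tibble(zone = as.character(1:6), year = 2020,
#'                      balance = c(-0.9, -0.5, -0.05, 0.02, 0.5, 0.9))
#' classify_balance(bt, k = 3)
classify_balance <- function(balance, k = 7, per_year = TRUE) {
  stop_if_missing_cols(balance, c("zone", "year", "balance"), "balance")
  classify_grp <- function(df, scheme_store, key) {
    k_eff <- min(k, length(unique(df$balance)))
    scheme <- jenks_breaks(df$balance, k_eff)
    idx <- classify(df$balance, scheme)
    # class whose interval holds zero; clamps when 0 is out of range
    inner <- if (scheme$k > 1) scheme$breaks[2:scheme$k] else numeric(0)
    zero_idx <- min(max(1L + sum(0 > inner), 1L), scheme$k)
    d <- idx - zero_idx
    grade <- function(dd) {
      dplyr::case_when(abs(dd) == 1 ~ "general",
                       abs(dd) == 2 ~ "higher",
                       abs(dd) >= 3 ~ "high")
    }
    lab <- dplyr::case_when(
      d == 0 ~ "balance",
      d > 0 ~ paste(grade(d), "surplus"),
      TRUE ~ paste(grade(d), "deficit")
    )
    df$class_idx <- idx
    df$class_label <- lab
    scheme_store[[key]] <- scheme
    list(df = df, schemes = scheme_store)
  }
  schemes <- list()
  if (per_year) {
    parts <- list()
    for (y in unique(as.character(balance$year))) {
      res <- classify_grp(
        filter(balance, as.character(.data$year) == y), schemes, y
      )
      parts[[y]] <- res$df
      schemes <- res$schemes
    }
    out <- bind_rows(parts)
  } else {
    res <- classify_grp(balance, schemes, "all")
    out <- res$df
    schemes <- res$schemes
  }
  attr(out, "schemes") <- schemes
  attr(out, "mode") <- attr(balance, "mode")
  out
}
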