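# Independent oracles used across the suite. These deliberately use
# brute-force enumeration so they share no code path with the package.

# Minimum within-class SSD over all ordered partitions of sorted x into
# k contiguous classes (exhaustive over the (n-1 choose k-1) split sets).
brute_jenks_ss <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  ss <- function(v) sum((v - mean(v))^2)
  if (k == 1) return(ss(x))
  splits <- utils::combn(n - 1, k - 1)
  best <- Inf
  for (j in seq_len(ncol(splits))) {
    bounds <- c(0, splits[, j], n)
    tot <- 0
    for (m in seq_len(k)) {
      tot <- tot + ss(x[(bounds[m] + 1):bounds[m + 1]])
    }
    best <- min(best, tot)
  }
  best
}

# Minimum check loss over all exact fits through p observations (every
# quantile-regression optimum is such a basic solution).
brute_check_loss <- function(X, y, theta) {
  n <- nrow(X)
  p <- ncol(X)
  best <- Inf
  for (s in asplit(utils::combn(n, p), 2)) {
    b <- tryCatch(solve(X[s, , drop = FALSE], y[s]),
                  error = function(e) NULL)
    if (is.null(b)) next
    best <- min(best, sum(check_loss(y - X %*% b, theta)))
  }
  best
}

# Are the cells of each zone 4-connected? (flood fill per zone label)
zones_contiguous <- function(zones) {
  for (z in sort(unique(as.vector(zones)))) {
    mask <- zones == z
    idx <- which(mask, arr.ind = TRUE)
    visited <- matrix(FALSE, nrow(zones), ncol(zones))
    queue <- list(idx[1, ])
    visited[idx[1, 1], idx[1, 2]] <- TRUE
    count <- 1L
    while (length(queue) > 0) {
      cur <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        r <- cur[1] + d[1]
        c <- cur[2] + d[2]
        if (r >= 1 && r <= nrow(zones) && c >= 1 && c <= ncol(zones) &&
              mask[r, c] && !visited[r, c]) {
          visited[r, c] <- TRUE
          count <- count + 1L
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
    if (count != nrow(idx)) return(FALSE)
  }
  TRUE
}

detailed_classes_cols <- function(d) {
  setdiff(names(d), c("zone", "balance_index"))
}

# Printed reference tables: per-class and per-service ESV levels
# (100 million yuan) for the five assessment years.
printed_esv_by_class <- function() {
  tibble::tribble(
    ~year, ~cultivated, ~woodland, ~grassland, ~water, ~construction, ~unused, ~total,
    2000, 4243.53, 19717.48, 2374.04, 2560.93, 0, 8.81, 28904.79,
    2005, 4199.99, 19741.14, 2364.15, 2631.90, 0, 8.72, 28945.90,
    2010, 4167.01, 19749.84, 2360.30, 2651.55, 0, 8.88, 28937.58,
    2015, 4114.10, 19691.11, 2359.07, 2699.60, 0, 8.85, 28872.73,
    2020, 4039.06, 19762.78, 2279.47, 2814.56, 0, 8.84, 28904.72
  )
}

printed_esv_by_service <- function() {
  tibble::tribble(
    ~year, ~`gas regulation`, ~`climate regulation`, ~`water conservation`,
    ~`soil formation and protection`, ~`waste disposal`,
    ~`biodiversity conservation`, ~`food production`, ~`raw material`,
    ~entertainment,
    2000, 3728.13, 3301.07, 4654.92, 5057.19, 3632.64, 3881.46, 808.63, 2424.63, 1416.13,
    2005, 3727.67, 3297.88, 4684.97, 5049.56, 3650.00, 3882.79, 802.18, 2426.76, 1424.09,
    2010, 3726.26, 3294.44, 4691.68, 5043.12, 3649.78, 3881.25, 797.34, 2427.30, 1426.40,
    2015, 3712.89, 3280.69, 4699.65, 5021.14, 3652.49, 3869.47, 789.46, 2419.55, 1427.40,
    2020, 3710.13, 3271.23, 4745.79, 4996.63, 3670.03, 3866.67, 775.88, 2426.47, 1441.89
  )
}

# Source-table cells whose printed values are not arithmetically
# derivable from the packaged area and coefficient tables (the unused-
# land column drifts from 2010 on, and the grand totals inherit it).
inconsistent_class_cells <- function() {
  tibble::tibble(
    year = c(2010, 2015, 2020, 2010, 2015, 2020),
    land_class = c("unused", "unused", "unused", "total", "total", "total")
  )
}
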