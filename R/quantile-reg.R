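#' Check loss (asymmetric absolute deviation)
#'
#' `rho_theta(u) = u * (theta - 1[u < 0])`, the objective of quantile
#' regression: residuals above the fit are weighted `theta`, residuals
#' below `1 - theta`.
#'
#' @param u Numeric residual vector.
#' @param theta Quantile in (0, 1).
#' @return Numeric vector of losses.
#' @export
check_loss <- function(u, theta) {
  u * (theta - (u < 0))
}

# Build the model matrix (intercept + named covariates) and response from
# a tidy regression dataset.
design_matrix <- function(data, response = "balance_index",
                          covariates = NULL) {
  stop_if_missing_cols(data, response, "regression data")
  if (is.null(covariates)) {
    covariates <- intersect(detailed_classes(), names(data))
    if (length(covariates) == 0) {
      covariates <- setdiff(
        names(data)[vapply(data, is.numeric, logical(1))],
        c(response, "zone", "year")
      )
    }
  }
  stop_if_missing_cols(data, covariates, "regression data")
  X <- cbind("(Intercept)" = 1,
             as.matrix(data[, covariates, drop = FALSE]))
  y <- data[[response]]
  if (nrow(X) <= ncol(X)) {
    abort(sprintf("need more observations (%d) than parameters (%d)",
                  nrow(X), ncol(X)))
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    abort(sprintf("collinear covariate column(s): %s",
                  paste(dropped, collapse = ", ")))
  }
  list(X = X, y = y, covariates = covariates, response = response)
}

#' Ordinary least squares on a tidy regression dataset
#'
#' The mean-regression benchmark fitted alongside the quantile path:
#' intercept plus the supplied covariate columns (by default the 10
#' detailed land-use proportions), via `stats::lm`.
#'
#' @param data Tibble with the response and covariate columns (e.g. from
#'   [generate_regression_dataset()]).
#' @param response Name of the response column.
#' @param covariates Character vector of covariate columns; default: the
#'   detailed land-use proportion columns present in `data`, else all
#'   numeric non-id columns.
#' @return An object of class `es_ols`: list with `coefficients`, `se`,
#'   `p_value`, `fit` (the underlying `lm`), `response`, `covariates`.
#' @export
#' @examples
#' d <- generate_regression_dataset(120, c(0.5, rep(-1, 5), rep(1, 5)),
#'                                  0.05, seed = 3)
#' coef(fit_ols(d))
fit_ols <- function(data, response = "balance_index", covariates = NULL) {
  dm <- design_matrix(data, response, covariates)
  df <- data.frame(.y = dm$y, dm$X[, -1, drop = FALSE],
                   check.names = FALSE)
  fit <- lm(.y ~ ., data = df)
  sm <- summary(fit)$coefficients
  structure(
    list(
      coefficients = setNames(coef(fit), colnames(dm$X)),
      se = setNames(sm[, "Std. Error"], colnames(dm$X)),
      p_value = setNames(sm[, "Pr(>|t|)"], colnames(dm$X)),
      fit = fit, response = dm$response, covariates = dm$covariates,
      n = nrow(dm$X)
    ),
    class = "es_ols"
  )
}

#' @export
coef.es_ols <- function(object, ...) object$coefficients

#' @export
print.es_ols <- function(x, ...) {
  cat(sprintf("<es_ols> n = %d\n", x$n))
  print(round(x$coefficients, 4))
  invisible(x)
}

# Core check-loss minimiser on (X, y): MM / iteratively reweighted least
# squares with epsilon continuation, optionally polished by exact
# interpolation through the p observations nearest the fit (quantile-
# regression solutions interpolate p data points).
rq_solve <- function(X, y, theta, polish = TRUE, max_iter = 200,
                     tol = 1e-10) {
  n <- nrow(X)
  p <- ncol(X)
  beta <- qr.coef(qr(X), y) # OLS start
  eps <- 1e-4
  obj <- function(b) sum(check_loss(y - X %*% b, theta))
  best <- beta
  best_obj <- obj(beta)
  for (iter in seq_len(max_iter)) {
    r <- as.vector(y - X %*% beta)
    w <- 1 / pmax(abs(r), eps)
    # weighted normal equations of the majoriser of the check loss
    XtW <- t(X * w)
    rhs <- XtW %*% y + (theta - 0.5) * colSums(X)
    beta_new <- tryCatch(
      as.vector(solve(XtW %*% X, rhs)),
      error = function(e) beta
    )
    step <- max(abs(beta_new - beta))
    beta <- beta_new
    o <- obj(beta)
    if (o < best_obj) {
      best <- beta
      best_obj <- o
    }
    if (step < tol) {
      if (eps <= 1e-12) break
      eps <- eps / 100
    }
  }
  beta <- best
  if (polish) {
    # candidate basic solutions: all p-subsets when the problem is small
    # enough to enumerate, else exact fits through p of the m
    # observations with smallest |residual|
    if (choose(n, p) <= 3000) {
      cand_rows <- seq_len(n)
    } else {
      r <- abs(as.vector(y - X %*% beta))
      m <- p + 4L
      while (m > p && choose(m, p) > 3000) m <- m - 1L
      m <- min(m, n)
      cand_rows <- order(r)[seq_len(m)]
    }
    subsets <- utils::combn(cand_rows, p)
    for (s in seq_len(ncol(subsets))) {
      rows <- subsets[, s]
      Xs <- X[rows, , drop = FALSE]
      b <- tryCatch(solve(Xs, y[rows]), error = function(e) NULL)
      if (is.null(b)) next
      o <- obj(b)
      if (o < best_obj - 1e-14) {
        best_obj <- o
        best <- as.vector(b)
      }
    }
    beta <- best
  }
  list(coefficients = setNames(as.vector(beta), colnames(X)),
       loss = best_obj)
}

#' Quantile regression by check-loss minimisation
#'
#' Estimates `beta(theta)` minimising the asymmetric absolute-deviation
#' (check) loss. The solver runs majorise-minimise reweighted least
#' squares with epsilon continuation and then polishes the solution over
#' exact fits through nearby observation subsets (optimal quantile fits
#' interpolate `p` observations), so the returned objective matches the
#' global basic-solution minimum to solver tolerance. Standard errors,
#' when requested, come from a seeded x-y pair bootstrap.
#'
#' @inheritParams fit_ols
#' @param theta Quantile in (0, 1).
#' @param se `"none"` (default) or `"bootstrap"`.
#' @param boot_reps Bootstrap resamples (default 1000).
#' @param seed Seed for the bootstrap.
#' @param polish Run the basic-solution polish step (default TRUE).
#' @return An object of class `es_rqfit`: `coefficients`, `theta`,
#'   `loss` (attained check loss), `se`, `p_value` (normal-approximation
#'   bootstrap p-values, `NA` without SEs), `fitted`, `residuals`.
#' @export
#' @examples
#' d <- generate_regression_dataset(100, c(1, rep(-2, 5), rep(0.5, 5)),
#'                                  0.1, seed = 4)
#' fit_quantile(d, theta = 0.5)
fit_quantile <- function(data, theta, response = "balance_index",
                         covariates = NULL, se = c("none", "bootstrap"),
                         boot_reps = 1000, seed = 1, polish = TRUE) {
  se <- match.arg(se)
  if (!is.numeric(theta) || length(theta) != 1 || theta <= 0 ||
        theta >= 1) {
    abort("theta must be a single value strictly between 0 and 1")
  }
  dm <- design_matrix(data, response, covariates)
  sol <- rq_solve(dm$X, dm$y, theta, polish = polish)
  se_vec <- setNames(rep(NA_real_, ncol(dm$X)), colnames(dm$X))
  p_vec <- se_vec
  if (se == "bootstrap") {
    boots <- bootstrap_coefs(dm$X, dm$y, theta, boot_reps, seed)
    se_vec[] <- apply(boots, 2, sd)
    z <- sol$coefficients / se_vec
    p_vec[] <- 2 * stats::pnorm(-abs(z))
  }
  structure(
    list(
      coefficients = sol$coefficients, theta = theta, loss = sol$loss,
      se = se_vec, p_value = p_vec,
      fitted = as.vector(dm$X %*% sol$coefficients),
      residuals = dm$y - as.vector(dm$X %*% sol$coefficients),
      n = nrow(dm$X), response = dm$response, covariates = dm$covariates
    ),
    class = "es_rqfit"
  )
}

bootstrap_coefs <- function(X, y, theta, boot_reps, seed) {
  n <- nrow(X)
  set.seed(seed)
  out <- matrix(NA_real_, boot_reps, ncol(X),
                dimnames = list(NULL, colnames(X)))
  for (b in seq_len(boot_reps)) {
    idx <- sample.int(n, n, replace = TRUE)
    Xb <- X[idx, , drop = FALSE]
    if (qr(Xb)$rank < ncol(Xb)) next
    out[b, ] <- rq_solve(Xb, y[idx], theta, polish = FALSE)$coefficients
  }
  out[complete.cases(out), , drop = FALSE]
}

#' @export
coef.es_rqfit <- function(object, ...) object$coefficients

#' @export
print.es_rqfit <- function(x, ...) {
  cat(sprintf("<es_rqfit> theta = %.2f, n = %d, check loss = %.6g\n",
              x$theta, x$n, x$loss))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @rdname tidy_esdbalance
#' @export
tidy.es_rqfit <- function(x, ...) {
  tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    p.value = unname(x$p_value),
    theta = x$theta
  )
}

#' @rdname tidy_esdbalance
#' @export
glance.es_rqfit <- function(x, ...) {
  tibble(theta = x$theta, loss = x$loss, nobs = x$n)
}

#' @rdname tidy_esdbalance
#' @export
tidy.es_ols <- function(x, ...) {
  tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    p.value = unname(x$p_value)
  )
}

#' @rdname tidy_esdbalance
#' @export
glance.es_ols <- function(x, ...) {
  s <- summary(x$fit)
  tibble(r.squared = s$r.squared, sigma = s$sigma, nobs = x$n)
}

#' Quantile-regression path over a theta grid
#'
#' Fits the check-loss regression at each quantile of `theta_grid` plus
#' the OLS benchmark, with seeded pair-bootstrap standard errors and
#' two-sided significance stars at the 10/5/1% levels - the layout of a
#' published quantile-estimation table.
#'
#' @inheritParams fit_quantile
#' @param theta_grid Quantiles to fit (default `c(0.1, 0.3, 0.5, 0.7,
#'   0.9)`).
#' @param se `"bootstrap"` (default) or `"none"`.
#' @return An object of class `es_qpath`: list with `ols` (an `es_ols`),
#'   `fits` (list of `es_rqfit` by theta), `theta_grid`, and `crossings`
#'   (count of fitted-quantile crossing pairs, a diagnostic).
#' @export
#' @examples
#' d <- generate_regression_dataset(150, c(1, rep(-3, 5), rep(1, 5)),
#'                                  0.1, seed = 5)
#' qp <- quantile_path(d, theta_grid = c(0.25, 0.75), se = "none")
#' tidy(qp)
quantile_path <- function(data, theta_grid = c(0.1, 0.3, 0.5, 0.7, 0.9),
                          response = "balance_index", covariates = NULL,
                          se = c("bootstrap", "none"), boot_reps = 1000,
                          seed = 1) {
  se <- match.arg(se)
  if (any(theta_grid <= 0 | theta_grid >= 1)) {
    abort("all quantiles must lie strictly between 0 and 1")
  }
  theta_grid <- sort(theta_grid)
  ols <- fit_ols(data, response, covariates)
  fits <- lapply(theta_grid, function(th) {
    fit_quantile(data, th, response, covariates, se = se,
                 boot_reps = boot_reps, seed = seed)
  })
  names(fits) <- as.character(theta_grid)
  # quantile-crossing diagnostic: adjacent fitted quantiles out of order
  crossings <- 0L
  if (length(fits) > 1) {
    for (i in seq_len(length(fits) - 1)) {
      crossings <- crossings +
        sum(fits[[i]]$fitted > fits[[i + 1]]$fitted + 1e-10)
    }
  }
  structure(
    list(ols = ols, fits = fits, theta_grid = theta_grid,
         crossings = crossings),
    class = "es_qpath"
  )
}

#' Tidiers for fitted objects
#'
#' `tidy()` returns one row per term (long over quantiles for a path);
#' `glance()` returns one-row fit summaries.
#'
#' @param x A fitted `es_ols`, `es_rqfit` or `es_qpath` object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy_esdbalance
NULL

#' @rdname tidy_esdbalance
#' @export
tidy.es_qpath <- function(x, ...) {
  bind_rows(
    mutate(tidy(x$ols), method = "OLS", theta = NA_real_),
    purrr::map_dfr(x$fits, function(f) mutate(tidy(f), method = "quantile"))
  ) |>
    mutate(stars = dplyr::case_when(
      is.na(.data$p.value) ~ "",
      .data$p.value < 0.01 ~ "***",
      .data$p.value < 0.05 ~ "**",
      .data$p.value < 0.10 ~ "*",
      TRUE ~ ""
    ))
}

#' @rdname tidy_esdbalance
#' @export
glance.es_qpath <- function(x, ...) {
  tibble(
    n_quantiles = length(x$fits),
    crossings = x$crossings,
    nobs = x$ols$n
  )
}

#' @export
print.es_qpath <- function(x, ...) {
  cat(sprintf(
    "<es_qpath> %d quantile fit(s) + OLS, n = %d, crossings = %d\n",
    length(x$fits), x$ols$n, x$crossings
  ))
  invisible(x)
}

#' Format a quantile path like a published estimation table
#'
#' One row pair per term: coefficient with significance stars over the
#' bootstrap standard error in parentheses; one column per quantile plus
#' OLS.
#'
#' @param path An `es_qpath`.
#' @param digits Decimal places (default 3).
#' @return A tibble with a `term` column and one character column per
#'   fit.
#' @export
format_quantile_table <- function(path, digits = 3) {
  td <- tidy(path)
  td |>
    mutate(
      column = ifelse(.data$method == "OLS", "OLS",
                      sprintf("theta=%g", .data$theta)),
      cell = sprintf(
        paste0("%.", digits, "f%s (%.", digits, "f)"),
        .data$estimate, .data$stars, .data$std.error
      )
    ) |>
    select("term", "column", "cell") |>
    tidyr::pivot_wider(names_from = "column", values_from = "cell")
}
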