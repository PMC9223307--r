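test_that("intercept-only median fit is the sample median, robust to outliers", {
  d <- tibble::tibble(balance_index = c(1, 2, 3, 4, 100))
  f <- fit_quantile(d, 0.5, covariates = character(0))
  expect_equal(unname(coef(f)), 3)
  # other quantiles hit empirical quantile-type solutions
  d2 <- tibble::tibble(balance_index = 1:10)
  f9 <- fit_quantile(d2, 0.9, covariates = character(0))
  expect_equal(sum(check_loss(d2$balance_index - coef(f9), 0.9)),
               min(sapply(1:10, function(v)
                 sum(check_loss(d2$balance_index - v, 0.9)))),
               tolerance = 1e-10)
})

test_that("solver attains the brute-force basic-solution minimum (n<=10, p<=2)", {
  set.seed(77)
  for (i in 1:40) {
    n <- sample(4:10, 1)
    p <- sample(1:2, 1)
    X <- cbind(`(Intercept)` = 1, matrix(rnorm(n * p), n, p,
               dimnames = list(NULL, paste0("x", seq_len(p)))))
    if (n <= ncol(X)) next
    y <- rnorm(n)
    theta <- runif(1, 0.1, 0.9)
    d <- tibble::as_tibble(as.data.frame(X[, -1, drop = FALSE]))
    d$balance_index <- y
    f <- fit_quantile(d, theta, covariates = paste0("x", seq_len(p)))
    expect_lte(f$loss, brute_check_loss(X, y, theta) + 1e-8)
  }
})

test_that("one-covariate median fit matches the exhaustive line-through-pairs search", {
  d <- tibble::tibble(
    x1 = c(0.1, 0.5, 0.9, 1.4, 2.0, 2.6, 3.1, 3.8),
    balance_index = c(0.3, 1.2, 1.4, 2.9, 3.6, 4.1, 6.4, 7.2)
  )
  f <- fit_quantile(d, 0.5, covariates = "x1")
  X <- cbind(1, d$x1)
  expect_equal(f$loss, brute_check_loss(X, d$balance_index, 0.5),
               tolerance = 1e-10)
})

test_that("noiseless data is recovered exactly by OLS and the quantile fit", {
  beta <- c(1.5, -6, -4, -9, -1, -2, 5, 1.2, -0.4, -0.2, 0.9)
  d <- generate_regression_dataset(80, beta, noise_sd = 0, seed = 13)
  expect_equal(unname(coef(fit_ols(d))), beta, tolerance = 1e-9)
  expect_equal(unname(coef(fit_quantile(d, 0.5))), beta,
               tolerance = 1e-7)
})

test_that("constant response gives intercept-only solution", {
  d <- generate_regression_dataset(50, rep(0, 11), noise_sd = 0, seed = 2)
  d$balance_index <- 4.2
  f <- fit_ols(d)
  expect_equal(unname(coef(f)[1]), 4.2, tolerance = 1e-10)
  expect_equal(unname(coef(f)[-1]), rep(0, 10), tolerance = 1e-8)
})

test_that("rank-deficient designs error naming the collinear column", {
  d <- generate_regression_dataset(60, c(1, rep(0.5, 10)), 0.1, seed = 3)
  d$dup <- d$urban
  expect_error(
    fit_ols(d, covariates = c(detailed_classes_cols(d)[
      !detailed_classes_cols(d) %in% "dup"], "dup")),
    "collinear.*dup"
  )
  expect_error(fit_quantile(d, 1.2), "between 0 and 1")
  expect_error(fit_quantile(d, 0), "between 0 and 1")
})

test_that("median regression approaches OLS under symmetric noise", {
  beta <- c(1, rep(-4, 5), rep(2, 5))
  d <- generate_regression_dataset(800, beta, noise_sd = 0.3, seed = 21)
  ols <- fit_ols(d)
  med <- fit_quantile(d, 0.5)
  expect_true(all(abs(coef(med) - coef(ols)) <= 2 * ols$se))
})

test_that("quantile fits are equivariant to positive scaling of the response", {
  d <- generate_regression_dataset(100, c(1, rep(-2, 5), rep(1, 5)),
                                   0.2, seed = 31)
  f1 <- fit_quantile(d, 0.3)
  d2 <- dplyr::mutate(d, balance_index = 7 * balance_index)
  f2 <- fit_quantile(d2, 0.3)
  expect_equal(unname(coef(f2)), 7 * unname(coef(f1)), tolerance = 1e-6)
})

test_that("location-shift data keeps slopes constant across quantiles", {
  beta <- c(1, rep(-3, 5), rep(1.5, 5))
  d <- generate_regression_dataset(600, beta, noise_sd = 0.1, seed = 41)
  qp <- quantile_path(d, theta_grid = c(0.2, 0.5, 0.8), se = "bootstrap",
                      boot_reps = 150, seed = 1)
  td <- tidy(qp)
  for (term in c("urban", "other_forest")) {
    est <- td$estimate[td$method == "quantile" & td$term == term]
    se <- td$std.error[td$method == "quantile" & td$term == term]
    expect_true(all(abs(est - beta[match(term, names(attr(d, "beta")))])
                    <= 3 * se))
  }
})

test_that("heteroscedastic noise shows up as slope growth across quantiles", {
  d <- generate_regression_dataset(500, c(1, 2, rep(0.5, 9)),
                                   noise_sd = 0.2, seed = 11,
                                   sd_covariate = "urban", sd_slope = 1.5)
  slopes <- sapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(th)
    coef(fit_quantile(d, th))[["urban"]])
  expect_true(all(diff(slopes) > 0))
  expect_true(all(abs(slopes) == sort(abs(slopes))))
})

test_that("the quantile path tidies into a publication-shaped table", {
  d <- generate_regression_dataset(120, c(0.5, rep(-2, 5), rep(1, 5)),
                                   0.1, seed = 51)
  qp <- quantile_path(d, theta_grid = c(0.25, 0.75), se = "bootstrap",
                      boot_reps = 80, seed = 9)
  td <- tidy(qp)
  expect_setequal(unique(td$method), c("OLS", "quantile"))
  expect_equal(sum(td$method == "quantile"), 2 * 11)
  expect_true(all(td$stars %in% c("", "*", "**", "***")))
  gl <- glance(qp)
  expect_equal(gl$n_quantiles, 2L)
  tab <- format_quantile_table(qp)
  expect_equal(nrow(tab), 11)
  expect_true(all(c("OLS", "theta=0.25", "theta=0.75") %in% names(tab)))
  # single-quantile grid still works
  qp1 <- quantile_path(d, theta_grid = 0.5, se = "none")
  expect_equal(length(qp1$fits), 1L)
})
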