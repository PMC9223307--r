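test_that("configuration validation names the offending entry", {
  expect_error(
    landscape_config(class_proportions = c(cultivated = 0.5, woodland = 0.4)),
    "class_proportions sum"
  )
  expect_error(
    landscape_config(class_proportions = c(swamp = 1)),
    "unknown class.*swamp"
  )
  expect_error(
    landscape_config(transition_rates = tibble::tibble(
      from = "cultivated", to = "construction", rate = -0.1
    )),
    "negative transition rate for cultivated -> construction"
  )
  expect_error(
    landscape_config(transition_rates = tibble::tibble(
      from = c("water", "water"), to = c("cultivated", "grassland"),
      rate = c(0.7, 0.6)
    )),
    "outflow from class 'water' exceeds 1"
  )
  expect_error(
    landscape_config(grid_shape = c(5, 5), n_zones = 26),
    "n_zones"
  )
})

test_that("identity transitions keep land use constant across years", {
  cfg <- landscape_config(
    grid_shape = c(20, 20),
    transition_rates = tibble::tibble(from = character(), to = character(),
                                      rate = numeric()),
    seed = 4
  )
  scene <- generate_scene(cfg)
  for (y in names(scene$landuse)[-1]) {
    expect_identical(scene$landuse[[y]], scene$landuse[[1]])
  }
})

test_that("scenes are bit-identical under the same seed and differ across seeds", {
  cfg <- landscape_config(grid_shape = c(25, 25), seed = 11)
  s1 <- generate_scene(cfg)
  s2 <- generate_scene(cfg)
  expect_identical(s1$landuse, s2$landuse)
  expect_identical(s1$population, s2$population)
  expect_identical(s1$nightlight, s2$nightlight)
  expect_identical(s1$zones, s2$zones)
  s3 <- generate_scene(landscape_config(grid_shape = c(25, 25), seed = 12))
  expect_false(identical(s1$landuse, s3$landuse))
})

test_that("class shares follow the Markov closed form within 3 binomial SDs", {
  cfg <- landscape_config(
    grid_shape = c(100, 100),
    transition_rates = tibble::tibble(
      from = "cultivated", to = "construction", rate = 0.05
    ),
    seed = 3
  )
  scene <- generate_scene(cfg)
  p0 <- cfg$class_proportions[["cultivated"]]
  expected <- p0 * 0.95^4 # 4 intervals between the 5 years
  observed <- mean(scene$landuse[["2020"]] == 1L)
  tol <- 3 * sqrt(expected * (1 - expected) / 1e4)
  expect_lt(abs(observed - expected), tol)
})

test_that("cell count is conserved and scene layers are well-formed", {
  scene <- generate_scene(landscape_config(grid_shape = c(30, 40), seed = 8))
  n <- 30 * 40
  for (y in names(scene$landuse)) {
    lu <- scene$landuse[[y]]
    expect_equal(length(lu), n)
    expect_true(all(lu %in% 1:6))
    dn <- scene$nightlight[[y]]
    expect_true(all(dn == floor(dn)))
    expect_true(all(dn >= 0 & dn <= 63))
  }
  expect_true(all(scene$population >= 0))
  expect_equal(dim(scene$population), c(30L, 40L))
  expect_setequal(unique(as.vector(scene$zones)), 1:9)
})

test_that("zones are contiguous and cover the grid", {
  scene <- generate_scene(landscape_config(grid_shape = c(30, 30),
                                           n_zones = 7, seed = 21))
  expect_true(all(!is.na(scene$zones)))
  expect_true(zones_contiguous(scene$zones))
})

test_that("regression dataset is exact without noise and centred with null beta", {
  beta <- c(2, -3, -1, -5, -2, -2, 4, 1, 0.5, -0.5, 1.5)
  d0 <- generate_regression_dataset(60, beta, noise_sd = 0, seed = 2)
  X <- as.matrix(d0[, detailed_classes_cols(d0)])
  expect_equal(d0$balance_index, beta[1] + as.vector(X %*% beta[-1]),
               tolerance = 1e-12)

  dn <- generate_regression_dataset(2000, rep(0, 11), noise_sd = 1, seed = 5)
  expect_lt(abs(mean(dn$balance_index)), 3 / sqrt(2000))

  expect_error(generate_regression_dataset(10, beta, 0.1, seed = 1),
               "at least 30")
  expect_error(generate_regression_dataset(60, beta, -1, seed = 1),
               "non-negative")
})

test_that("proportions lie on the simplex and truth is recoverable by OLS", {
  beta <- c(1, rep(-4, 5), rep(2, 5))
  d <- generate_regression_dataset(500, beta, noise_sd = 0.1, seed = 1)
  X <- as.matrix(d[, detailed_classes_cols(d)])
  expect_true(all(X >= 0 & X <= 1))
  expect_true(all(rowSums(X) <= 1 + 1e-12))
  fit <- fit_ols(d)
  expect_true(all(abs(coef(fit) - beta) <= 3 * fit$se))
})
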