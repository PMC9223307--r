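test_that("night-light statistics match closed forms", {
  all63 <- matrix(63L, 5, 5)
  s <- light_stats(all63)
  expect_equal(s$I, 1)
  expect_equal(s$S, 1)
  expect_equal(s$nlci, 1)

  quarter <- matrix(0L, 10, 10)
  quarter[1:25] <- 63L
  s2 <- light_stats(quarter)
  expect_equal(s2$I, 1)
  expect_equal(s2$S, 0.25)
  expect_equal(s2$nlci, 0.8 * 1 + 0.2 * 0.25)

  toy <- matrix(c(0L, 0L, 0L, 0L, 0L, 21L, 21L, 42L, 42L, 63L), 2, 5)
  s3 <- light_stats(toy)
  expect_equal(s3$I, (21 * 2 + 42 * 2 + 63) / (5 * 63))
  expect_equal(s3$S, 0.5)
  expect_equal(s3$nlci, 0.8 * 0.6 + 0.2 * 0.5)

  dark <- matrix(0L, 4, 4)
  s4 <- light_stats(dark)
  expect_equal(s4$I, 0)
  expect_equal(s4$S, 0)
  expect_equal(s4$nlci, 0)
})

test_that("composite weights must sum to one and NLCI stays in [0,1]", {
  expect_error(light_stats(matrix(0L, 2, 2), w_intensity = 0.9,
                           w_share = 0.2), "sum to 1")
  set.seed(1)
  for (i in 1:20) {
    dn <- matrix(sample(0:63, 64, replace = TRUE), 8, 8)
    s <- light_stats(dn)
    expect_true(s$nlci >= 0 && s$nlci <= 1)
    expect_true(s$I >= 0 && s$I <= 1)
  }
})

test_that("out-of-range or fractional DN input is rejected with guidance", {
  expect_error(light_stats(matrix(c(0, 255), 1, 2)), "rescale_dn")
  expect_error(light_stats(matrix(c(0.5, 1), 1, 2)), "integers")
})

test_that("continuous radiance rescales onto the DN range", {
  set.seed(3)
  rad <- matrix(rexp(400, rate = 0.1), 20, 20)
  dn <- rescale_dn(rad)
  expect_true(all(dn >= 0 & dn <= 63))
  expect_equal(max(dn), 63)
  expect_no_error(light_stats(dn))
  expect_error(rescale_dn(-rad), "negative")
})

test_that("land-use degree is the built-up percentage of zone area", {
  full <- tabulate_areas(matrix(5L, 4, 4), year = 2000)
  expect_equal(landuse_degree(full)$degree_pct, 100)
  none <- tabulate_areas(matrix(1L, 4, 4), year = 2000)
  expect_equal(landuse_degree(none)$degree_pct, 0)
  g <- matrix(1L, 10, 10)
  g[1:25] <- 5L
  expect_equal(landuse_degree(tabulate_areas(g, year = 2000))$degree_pct, 25)
  empty <- tibble::tibble(zone = "z", year = 2000,
                          land_class = "cultivated", area_km2 = 0)
  expect_error(landuse_degree(empty), "zero area")
})

test_that("demand index matches its closed form and boundary behaviour", {
  x <- demand_index(tibble::tibble(degree_pct = 50, pop_density = 1000,
                                   nlci = 0.1))
  expect_equal(x$demand_index, 50 * 3 * 1)

  zero_d <- demand_index(tibble::tibble(degree_pct = 0,
                                        pop_density = 1e6, nlci = 1))
  expect_equal(zero_d$demand_index, 0)

  # doubling the population exponent doubles the index, others equal
  two <- demand_index(tibble::tibble(degree_pct = c(10, 10),
                                     pop_density = c(100, 10000),
                                     nlci = c(0.5, 0.5)))
  expect_equal(two$demand_index[2] / two$demand_index[1], 2)

  expect_error(demand_index(tibble::tibble(degree_pct = -1,
                                           pop_density = 1, nlci = 0)),
               "non-negative")
  expect_error(demand_index(tibble::tibble(degree_pct = Inf,
                                           pop_density = 1, nlci = 0)),
               "finite")
})

test_that("demand index is monotone non-decreasing in each argument", {
  base <- list(degree_pct = 20, pop_density = 500, nlci = 0.3)
  grids <- list(
    degree_pct = seq(0, 100, by = 5),
    pop_density = c(0, 0.5, 1, 10, 100, 1e4, 1e6),
    nlci = seq(0, 1, by = 0.05)
  )
  for (arg in names(grids)) {
    inputs <- base
    inputs[[arg]] <- grids[[arg]]
    df <- tibble::as_tibble(inputs)
    x <- demand_index(df)$demand_index
    expect_true(all(diff(x) >= -1e-12), label = paste("monotone in", arg))
  }
})

test_that("zone demand ranks zones like their built-up intensity", {
  scene <- generate_scene(landscape_config(seed = 1))
  d <- zone_demand(scene, years = 2020)
  built <- landuse_degree(
    dplyr::filter(tabulate_areas(scene), zone != "ALL", year == "2020")
  )
  r <- cor(d$demand_index, built$degree_pct[match(d$zone, built$zone)],
           method = "spearman")
  expect_gt(r, 0.9)
  expect_error(zone_demand(scene, years = 1999), "no year")
})
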