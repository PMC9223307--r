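test_that("balance index equals hand-computed differences", {
  s <- tibble::tibble(zone = as.character(1:5), year = 2020,
                      supply = c(10, 8, 6, 4, 2))
  d <- tibble::tibble(zone = as.character(1:5), year = 2020,
                      demand_index = c(1, 3, 6, 7, 9))
  raw <- balance_index(s, d, mode = "raw")
  expect_equal(raw$balance, c(9, 5, 0, -3, -7))

  norm <- balance_index(s, d, mode = "normalized")
  expect_equal(norm$balance,
               (s$supply - 2) / 8 - (d$demand_index - 1) / 8)
  expect_true(all(norm$balance >= -1 & norm$balance <= 1))
})

test_that("equal supply and demand give zero balance everywhere", {
  s <- tibble::tibble(zone = as.character(1:4), year = 1,
                      supply = c(3, 5, 7, 9))
  d <- tibble::tibble(zone = as.character(1:4), year = 1,
                      demand_index = c(3, 5, 7, 9))
  expect_true(all(balance_index(s, d, mode = "raw")$balance == 0))
  expect_true(all(balance_index(s, d)$balance == 0))
})

test_that("normalized balance is antisymmetric under swapping sides", {
  set.seed(7)
  s <- tibble::tibble(zone = as.character(1:12), year = 1,
                      supply = runif(12, 0, 50))
  d <- tibble::tibble(zone = as.character(1:12), year = 1,
                      demand_index = runif(12, 0, 9))
  fwd <- balance_index(s, d)
  swapped <- balance_index(
    dplyr::rename(d, supply = demand_index),
    dplyr::rename(s, demand_index = supply)
  )
  expect_equal(fwd$balance, -swapped$balance, tolerance = 1e-12)
})

test_that("zone mismatch errors list the unmatched zones", {
  s <- tibble::tibble(zone = c("1", "2"), year = 1, supply = c(1, 2))
  d <- tibble::tibble(zone = c("2", "3"), year = 1,
                      demand_index = c(1, 2))
  expect_error(balance_index(s, d), "unmatched.*1.*3")
})

test_that("Jenks breaks split clearly clustered data at the gap", {
  sc <- jenks_breaks(c(1, 2, 3, 10, 11, 12), k = 2)
  expect_equal(sc$breaks, c(1, 3, 12))
  expect_equal(classify(c(1, 2, 3, 10, 11, 12), sc),
               c(1L, 1L, 1L, 2L, 2L, 2L))
  expect_equal(sc$within_ss, brute_jenks_ss(c(1, 2, 3, 10, 11, 12), 2))
})

test_that("Jenks edge cases: k = 1, k = n, infeasible k", {
  x <- c(4, 8, 15, 16, 23, 42)
  one <- jenks_breaks(x, 1)
  expect_equal(one$within_ss, sum((x - mean(x))^2))
  expect_true(all(classify(x, one) == 1L))
  full <- jenks_breaks(x, length(x))
  expect_equal(full$within_ss, 0)
  expect_equal(classify(x, full), seq_along(x))
  expect_error(jenks_breaks(c(1, 1, 2), 3), "distinct")
})

test_that("dynamic-programming breaks match the exhaustive minimiser", {
  set.seed(123)
  for (i in 1:60) {
    n <- sample(5:15, 1)
    x <- round(rnorm(n, sd = 10), 2)
    k <- sample(2:min(7, length(unique(x))), 1)
    expect_equal(jenks_breaks(x, k)$within_ss, brute_jenks_ss(x, k),
                 tolerance = 1e-9)
  }
})

test_that("classification is order-preserving, tie-to-lower and permutation-invariant", {
  set.seed(5)
  x <- rnorm(40)
  sc <- jenks_breaks(x, 5)
  idx <- classify(x, sc)
  expect_true(all(diff(idx[order(x)]) >= 0))
  perm <- sample(40)
  expect_equal(classify(x[perm], sc), idx[perm])
  # a value equal to a class upper bound belongs to the lower class
  upper1 <- sc$breaks[2]
  expect_equal(classify(upper1, sc), 1L)
  expect_warning(classify(max(x) + 10, sc), "outside")
  expect_equal(suppressWarnings(classify(max(x) + 10, sc)), 5L)
})

test_that("balance typology assigns surplus/deficit sides by sign", {
  bt <- tibble::tibble(
    zone = as.character(1:14), year = 2020,
    balance = c(-0.9, -0.85, -0.8, -0.5, -0.45, -0.4, -0.02, 0.02,
                0.4, 0.45, 0.5, 0.8, 0.85, 0.9)
  )
  cl <- classify_balance(bt, k = 7)
  surplus <- grepl("surplus", cl$class_label)
  deficit <- grepl("deficit", cl$class_label)
  expect_true(all(surplus[cl$balance > 0.1]))
  expect_true(all(deficit[cl$balance < -0.1]))
  # ordering: class index non-decreasing with balance
  expect_true(all(diff(cl$class_idx[order(cl$balance)]) >= 0))
  # more surplus-ward labels as balance grows
  expect_equal(cl$class_label[cl$balance == 0.9], "high surplus")
  expect_equal(cl$class_label[cl$balance == -0.9], "high deficit")
})

test_that("degenerate all-equal balance collapses to a single balance class", {
  bt <- tibble::tibble(zone = as.character(1:5), year = 1, balance = 0)
  cl <- classify_balance(bt, k = 7)
  expect_true(all(cl$class_label == "balance"))
  expect_true(all(cl$class_idx == 1L))
})

test_that("five-level classification labels low to high", {
  x <- c(1, 2, 10, 11, 30, 31, 60, 61, 100, 101)
  lv <- classify_levels(x)
  expect_s3_class(lv, "ordered")
  expect_equal(as.character(lv[1]), "low")
  expect_equal(as.character(lv[10]), "high")
  expect_true(all(diff(as.integer(lv)[order(x)]) >= 0))
})
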