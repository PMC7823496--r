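test_that("replicate aggregation averages technical within biological first", {
  d <- data.frame(T = 0, bio = 1:3, v = c(2, 2, 2))
  a <- aggregate_replicates(d, "v", "T", "bio")
  expect_equal(a$mean, 2)
  expect_equal(a$se, 0)

  d2 <- data.frame(T = 0, bio = 1:3, v = c(1, 2, 3))
  a2 <- aggregate_replicates(d2, "v", "T", "bio")
  expect_equal(a2$mean, 2)
  expect_equal(a2$se, 0.5774, tolerance = 1e-4)

  # one bio replicate with two technical values {1, 3}, one with {2}
  d3 <- data.frame(T = 0, bio = c(1, 1, 2), v = c(1, 3, 2))
  a3 <- aggregate_replicates(d3, "v", "T", "bio")
  expect_equal(a3$n, 2)
  expect_equal(a3$mean, 2)
  expect_equal(a3$se, 0)
})

test_that("pooled t-test reproduces the hand-computed example", {
  cmp <- paired_condition_compare(c(0, 0, 1, 1), c(1, 1, 2, 2))
  # independent oracle: textbook pooled-variance formula
  sp2 <- (3 * var(c(0, 0, 1, 1)) + 3 * var(c(1, 1, 2, 2))) / 6
  t_manual <- (0.5 - 1.5) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(cmp$t_statistic, t_manual, tolerance = 1e-12)
  expect_equal(abs(cmp$t_statistic), 2.449, tolerance = 1e-3)
  expect_equal(cmp$df, 6)
  expect_lt(abs(cmp$p_value - 0.0499), 5e-4)
  expect_true(cmp$significant)  # p <= alpha boundary rule
})

test_that("identical samples give t = 0, p = 1", {
  cmp <- paired_condition_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(cmp$t_statistic, 0)
  expect_equal(cmp$p_value, 1)
  expect_false(cmp$significant)
})

test_that("t-test symmetry and shift invariance", {
  set.seed(31)
  for (i in 1:10) {
    x <- rnorm(4)
    y <- rnorm(5, mean = 0.5)
    ab <- paired_condition_compare(x, y)
    ba <- paired_condition_compare(y, x)
    expect_equal(ba$t_statistic, -ab$t_statistic, tolerance = 1e-12)
    expect_equal(ba$p_value, ab$p_value, tolerance = 1e-12)
    shifted <- paired_condition_compare(x + 3, y + 3)
    expect_equal(shifted$t_statistic, ab$t_statistic, tolerance = 1e-9)
    expect_equal(shifted$p_value, ab$p_value, tolerance = 1e-9)
  }
})

test_that("zero pooled variance with unequal means reports p = 0 + degeneracy", {
  cmp <- paired_condition_compare(c(1, 1), c(2, 2))
  expect_equal(cmp$p_value, 0)
  expect_true(cmp$degenerate)
  same <- paired_condition_compare(c(1, 1), c(1, 1))
  expect_equal(same$p_value, 1)
  expect_false(same$degenerate)
  expect_error(paired_condition_compare(1, c(1, 2)), "at least 2")
})

test_that("per-temperature comparison walks the shared grid in order", {
  set.seed(7)
  temps <- seq(0, 25, by = 2.5)
  a <- data.frame(measurement_temperature_C = rep(temps, each = 3),
                  value = rnorm(3 * length(temps)))
  b <- data.frame(measurement_temperature_C = rep(temps, each = 3),
                  value = rnorm(3 * length(temps), mean = 8))
  cmp <- compare_genotypes(a, b)
  expect_equal(cmp$measurement_temperature_C, temps)
  expect_true(all(cmp$significant))
  expect_true(all(cmp$letters_b == "b"))
  disjoint <- data.frame(measurement_temperature_C = 100, value = 1:3)
  expect_error(compare_genotypes(a, disjoint), "overlap")
})
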