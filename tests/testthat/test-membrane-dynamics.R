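test_that("order parameter matches its closed form and flags excursions", {
  iso <- order_parameter(1.5, 1.5)
  expect_equal(iso$S, 0)
  expect_equal(iso$a0, 1.5)
  op <- order_parameter(3.00, 1.50)
  expect_equal(op$a0, 2.00, tolerance = 1e-12)
  expect_equal(op$S, 0.405525, tolerance = 1e-9)
  expect_false(op$out_of_range)
  expect_warning(rigid <- order_parameter(3.00, 0), "outside")
  expect_equal(rigid$S, 1.6221, tolerance = 1e-9)
  expect_true(rigid$out_of_range)
  expect_error(order_parameter(0, 1), "positive")
})

test_that("order parameter is scale invariant; a0 scales linearly", {
  set.seed(4)
  for (i in 1:20) {
    ap <- runif(1, 1.6, 3.2)
    pe <- runif(1, 0.5, ap - 0.1)
    k <- runif(1, 0.1, 10)
    base <- order_parameter(ap, pe)
    scaled <- order_parameter(k * ap, k * pe)
    expect_equal(scaled$S, base$S, tolerance = 1e-12)
    expect_equal(scaled$a0, k * base$a0, tolerance = 1e-12)
  }
})

test_that("correlation times match their closed forms", {
  sym <- correlation_times(1.5, 2, 2, 2, unit = "G")
  expect_equal(sym$tau2B, 0)
  expect_equal(sym$tau2C, 0)
  ct <- correlation_times(1.5, h_plus = 4, h_zero = 4, h_minus = 1, unit = "G")
  expect_equal(ct$tau2B, 9.765e-10, tolerance = 1e-12)
  expect_equal(ct$tau2C, 9.765e-10, tolerance = 1e-12)
  ct2 <- correlation_times(2, h_plus = 1, h_zero = 4, h_minus = 1, unit = "G")
  expect_equal(ct2$tau2B, 0, tolerance = 1e-20)
  expect_equal(ct2$tau2C, 2.604e-9, tolerance = 1e-12)
  # the default mT convention is the same number at a tenth the field value
  expect_equal(correlation_times(0.15, 4, 4, 1, unit = "mT"),
               correlation_times(1.5, 4, 4, 1, unit = "G"))
  expect_error(correlation_times(1.5, 0, 2, 2), "positive")
  expect_error(correlation_times(-1, 2, 2, 2), "positive")
})

test_that("correlation times: amplitude-scale invariance, linearity in width", {
  set.seed(9)
  for (i in 1:20) {
    h <- runif(3, 0.5, 5)
    k <- runif(1, 0.2, 8)
    dh <- runif(1, 0.8, 3)
    base <- correlation_times(dh, h[1], h[2], h[3], unit = "G")
    scaled <- correlation_times(dh, k * h[1], k * h[2], k * h[3], unit = "G")
    expect_equal(scaled, base, tolerance = 1e-12)
    wider <- correlation_times(2 * dh, h[1], h[2], h[3], unit = "G")
    expect_equal(wider$tau2B, 2 * base$tau2B, tolerance = 1e-12)
    expect_equal(wider$tau2C, 2 * base$tau2C, tolerance = 1e-12)
  }
})

test_that("recovered S decreases strictly along a fluidizing series", {
  s_targets <- seq(0.65, 0.25, by = -0.05)  # splitting gap shrinks with T
  recovered <- vapply(s_targets, function(S) {
    spl <- splittings_for_order(S, a0 = 1.5)
    sp <- simulate_anisotropic(anisotropic_params(A_par = spl$A_par,
                                                  A_perp = spl$A_perp),
                               grid_2k)
    recover_S(sp)
  }, 0)
  expect_true(all(diff(recovered) < 0))
  expect_true(all(abs(recovered - s_targets) < 0.02))
})

test_that("dynamics_table dispatches on the available features", {
  f1 <- extract_anisotropic_features(
    simulate_anisotropic(anisotropic_params(), grid_2k))
  f2 <- extract_fast_motion_features(
    simulate_fast_motion(fast_params_for_tau(3e-10, 5e-10), grid_2k))
  f3 <- eprdyn:::features_row()  # non-analyzable
  tab <- dynamics_table(rbind(f1, f2, f3))
  expect_false(is.na(tab$S[1]))
  expect_true(is.na(tab$tau2B_s[1]))
  expect_true(is.na(tab$S[2]))
  expect_false(is.na(tab$tau2B_s[2]))
  expect_true(all(is.na(unlist(tab[3, c("S", "tau2B_s", "tau2C_s")]))))
})
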