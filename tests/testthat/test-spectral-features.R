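test_that("central linewidth is recovered to sub-grid accuracy", {
  p <- fast_motion_params(width_A = 0.15)
  f <- extract_fast_motion_features(simulate_fast_motion(p, grid_4k))
  expect_lt(abs(f$deltaH0_mT - 0.15), grid_4k$step / 2)
})

test_that("pure noise is reported as non-analyzable, not an error", {
  set.seed(1)
  sp <- epr_spectrum(grid_2k$field, rnorm(grid_2k$n_points),
                     list(spin_label = "16-SASL"))
  expect_false(extract_fast_motion_features(sp)$analyzable)
  expect_false(extract_anisotropic_features(sp)$analyzable)
})

test_that("linear baselines are removed exactly and idempotently", {
  # Gaussian lines: the edge windows are genuinely line-free, so removal of
  # the added slope is exact to numerical precision.
  p0 <- fast_motion_params(width_A = 0.2, lineshape = "gaussian")
  flat <- simulate_fast_motion(p0, grid_4k)
  sloped <- simulate_fast_motion(fast_motion_params(width_A = 0.2,
                                                    lineshape = "gaussian",
                                                    baseline_slope = 0.3),
                                 grid_4k)
  corrected <- correct_baseline(sloped)
  scale <- max(abs(flat$intensity))
  expect_lt(max(abs(corrected$intensity - flat$intensity)) / scale, 1e-6)
  # Lorentzian tails reach the fitting windows; removal is then exact only
  # to the tail level, which stays below 1e-3 of the peak.
  lflat <- simulate_fast_motion(fast_motion_params(width_B = -0.02,
                                                   width_C = 0.03), grid_4k)
  lslope <- simulate_fast_motion(fast_motion_params(width_B = -0.02,
                                                    width_C = 0.03,
                                                    baseline_slope = 0.3),
                                 grid_4k)
  lcorr <- correct_baseline(lslope)
  expect_lt(max(abs(lcorr$intensity - lflat$intensity)) /
              max(abs(lflat$intensity)), 1e-3)
  twice <- correct_baseline(corrected)
  expect_lt(max(abs(twice$intensity - corrected$intensity)) / scale, 1e-9)
  zero <- epr_spectrum(grid_2k$field, rep(0, grid_2k$n_points))
  expect_equal(correct_baseline(zero)$intensity, rep(0, grid_2k$n_points))
})

test_that("anisotropic splittings survive mirroring about the centre field", {
  sp <- simulate_anisotropic(anisotropic_params(A_par = 2.8, A_perp = 1.3),
                             grid_2k)
  f <- extract_anisotropic_features(sp)
  mirrored <- epr_spectrum(rev(2 * 335 - sp$field), rev(sp$intensity),
                           sp$metadata)
  fm <- extract_anisotropic_features(mirrored)
  expect_true(fm$analyzable)
  expect_equal(fm$A_par_prime_mT, f$A_par_prime_mT, tolerance = 1e-6)
  expect_equal(fm$A_perp_prime_mT, f$A_perp_prime_mT, tolerance = 1e-6)
})

test_that("amplitude scaling and field translation behave as symmetries", {
  p <- fast_params_for_tau(3e-10, 5e-10)
  sp <- simulate_fast_motion(p, grid_4k)
  f0 <- extract_fast_motion_features(sp)
  for (k in c(0.25, 3, 40)) {
    scaled <- epr_spectrum(sp$field, k * sp$intensity, sp$metadata)
    f <- extract_fast_motion_features(scaled)
    expect_equal(f$h_plus, k * f0$h_plus, tolerance = 1e-9)
    expect_equal(f$h_zero, k * f0$h_zero, tolerance = 1e-9)
    expect_equal(f$h_minus, k * f0$h_minus, tolerance = 1e-9)
    expect_equal(f$deltaH0_mT, f0$deltaH0_mT, tolerance = 1e-12)
  }
  shifted <- epr_spectrum(sp$field + 7.5, sp$intensity, sp$metadata)
  fs <- extract_fast_motion_features(shifted)
  expect_equal(fs[, 1:6], f0[, 1:6], tolerance = 1e-9, ignore_attr = TRUE)

  spa <- simulate_anisotropic(anisotropic_params(), grid_2k)
  fa0 <- extract_anisotropic_features(spa)
  fa <- extract_anisotropic_features(
    epr_spectrum(spa$field - 12, 5 * spa$intensity, spa$metadata))
  expect_equal(fa$A_par_prime_mT, fa0$A_par_prime_mT, tolerance = 1e-9)
  expect_equal(fa$A_perp_prime_mT, fa0$A_perp_prime_mT, tolerance = 1e-9)
})

test_that("features converge under grid refinement", {
  p <- fast_params_for_tau(3e-10, 5e-10)
  coarse <- field_grid(329, 341, 2048)
  fine <- field_grid(329, 341, 4096)
  fc <- extract_fast_motion_features(simulate_fast_motion(p, coarse))
  ff <- extract_fast_motion_features(simulate_fast_motion(p, fine))
  expect_lt(abs(fc$deltaH0_mT - ff$deltaH0_mT), coarse$step / 2)

  pa <- anisotropic_params(A_par = 3, A_perp = 1.5)
  ac <- extract_anisotropic_features(simulate_anisotropic(pa, coarse))
  af <- extract_anisotropic_features(simulate_anisotropic(pa, fine))
  expect_lt(abs(ac$A_par_prime_mT - af$A_par_prime_mT), coarse$step / 2)
  expect_lt(abs(ac$A_perp_prime_mT - af$A_perp_prime_mT), coarse$step / 2)
})

test_that("features stay within 2% of noiseless values at SNR 50 (median over seeds)", {
  opts <- extraction_options(smooth = TRUE)
  p <- fast_params_for_tau(2.6e-10, 3.9e-10)
  clean <- simulate_fast_motion(p, grid_4k)
  f0 <- extract_fast_motion_features(clean)
  errs <- NULL
  for (s in 1:20) {
    f <- extract_fast_motion_features(add_noise(clean, f0$h_zero / 50, s), opts)
    expect_true(f$analyzable)
    errs <- rbind(errs, abs(c(f$deltaH0_mT / f0$deltaH0_mT,
                              f$h_plus / f0$h_plus, f$h_zero / f0$h_zero,
                              f$h_minus / f0$h_minus) - 1))
  }
  expect_true(all(apply(errs, 2, median) < 0.02))
  expect_true(all(errs < 0.10))

  pa <- anisotropic_params(A_par = 3, A_perp = 1.5)
  cleana <- simulate_anisotropic(pa, grid_2k)
  a0 <- extract_anisotropic_features(cleana)
  erra <- NULL
  for (s in 1:20) {
    f <- extract_anisotropic_features(
      add_noise(cleana, max(abs(cleana$intensity)) / 50, s), opts)
    expect_true(f$analyzable)
    erra <- rbind(erra, abs(c(f$A_par_prime_mT / a0$A_par_prime_mT,
                              f$A_perp_prime_mT / a0$A_perp_prime_mT) - 1))
  }
  expect_true(all(apply(erra, 2, median) < 0.02))
  expect_true(all(erra < 0.10))
})

test_that("rising noise eventually flips spectra to non-analyzable", {
  pa <- anisotropic_params(A_par = 3, A_perp = 1.5)
  clean <- simulate_anisotropic(pa, grid_2k)
  peak <- max(abs(clean$intensity))
  opts <- extraction_options(smooth = TRUE)
  flags <- vapply(c(0.001, 0.01, 3, 10), function(rel) {
    extract_anisotropic_features(add_noise(clean, rel * peak, 11), opts)$analyzable
  }, TRUE)
  expect_true(flags[1])
  expect_false(flags[length(flags)])
  expect_false(is.unsorted(rev(flags)))
})
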