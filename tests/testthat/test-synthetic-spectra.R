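test_that("parameter validation rejects unphysical simulations", {
  expect_error(fast_motion_params(width_A = 0.1, width_B = -0.2),
               "positive")
  expect_error(fast_motion_params(width_A = 0.6), "resolved-line")
  expect_error(anisotropic_params(A_par = 1.5, A_perp = 1.5), "A_par > A_perp")
  expect_error(anisotropic_params(A_par = 3, A_perp = -1), "A_par > A_perp")
  expect_error(field_grid(341, 329), "start")
  expect_error(field_grid(329, 341, 10), ">= 64")
  expect_error(simulate_fast_motion(fast_motion_params(),
                                    field_grid(334, 336, 128)),
               "does not cover")
})

test_that("identical parameters and seed give bit-identical spectra", {
  p <- fast_motion_params(noise_sd = 0.3, seed = 7L)
  s1 <- simulate_fast_motion(p, grid_2k)
  s2 <- simulate_fast_motion(p, grid_2k)
  expect_identical(s1$intensity, s2$intensity)

  pa <- anisotropic_params(noise_sd = 0.05, seed = 7L)
  a1 <- simulate_anisotropic(pa, grid_2k)
  a2 <- simulate_anisotropic(pa, grid_2k)
  expect_identical(a1$intensity, a2$intensity)
})

test_that("simulation with a seed leaves the ambient RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_fast_motion(fast_motion_params(noise_sd = 0.1, seed = 5L),
                                 grid_2k))
  expect_identical(.Random.seed, before)
})

test_that("equal-width triplet yields three congruent lines", {
  p <- fast_motion_params(width_A = 0.15, width_B = 0, width_C = 0)
  f <- extract_fast_motion_features(simulate_fast_motion(p, grid_4k))
  expect_true(f$analyzable)
  expect_lt(abs(f$h_plus - f$h_zero) / f$h_zero, 0.01)
  expect_lt(abs(f$h_minus - f$h_zero) / f$h_zero, 0.01)
})

test_that("ground-truth correlation times follow the closed form", {
  expect_equal(ground_truth_tau(fast_motion_params(width_B = 0,
                                                   width_C = 0.02))$tau2B, 0)
  expect_equal(ground_truth_tau(fast_motion_params(width_C = 0.03))$tau2C,
               3.906e-10, tolerance = 1e-12)
  expect_equal(ground_truth_tau(fast_motion_params(width_B = -0.02))$tau2B,
               2.604e-10, tolerance = 1e-12)
  expect_error(ground_truth_tau(fast_motion_params(lineshape = "gaussian")),
               "Lorentzian")
})

test_that("integrated first-derivative signal closes at the window edges", {
  for (sp in list(
    simulate_fast_motion(fast_motion_params(width_B = -0.02, width_C = 0.03),
                         grid_4k),
    simulate_fast_motion(fast_motion_params(lineshape = "gaussian"), grid_4k),
    simulate_anisotropic(anisotropic_params(), grid_2k))) {
    absorb <- cumsum(sp$intensity) * diff(sp$field[1:2])
    expect_lt(abs(absorb[length(absorb)]), 0.01 * max(abs(absorb)))
  }
})

test_that("anisotropic simulator realizes the requested splittings", {
  for (targets in list(c(3, 1.5), c(2.6, 1.2), c(1.9, 1.4))) {
    p <- anisotropic_params(A_par = targets[1], A_perp = targets[2])
    f <- extract_anisotropic_features(simulate_anisotropic(p, grid_2k))
    expect_true(f$analyzable)
    expect_lt(abs(f$A_par_prime_mT - targets[1]), grid_2k$step / 2)
    expect_lt(abs(f$A_perp_prime_mT - targets[2]), grid_2k$step / 2)
  }
})

test_that("degenerate anisotropic geometry is rejected", {
  p <- anisotropic_params(A_par = 1.501, A_perp = 1.5)
  expect_error(simulate_anisotropic(p, grid_2k), "unresolvable")
})

test_that("fast-motion round trip recovers the analytic correlation times", {
  p <- fast_params_for_tau(2.604e-10, 3.906e-10)
  f <- extract_fast_motion_features(simulate_fast_motion(p, grid_4k))
  ct <- correlation_times(f$deltaH0_mT, f$h_plus, f$h_zero, f$h_minus)
  gt <- ground_truth_tau(p)
  expect_lt(abs(ct$tau2B - gt$tau2B) / gt$tau2B, 0.05)
  expect_lt(abs(ct$tau2C - gt$tau2C) / gt$tau2C, 0.05)
})

test_that("spectrum files round-trip exactly, with optional JSON sidecar", {
  sp <- simulate_fast_motion(fast_motion_params(noise_sd = 0.2, seed = 3L),
                             grid_2k,
                             metadata = list(spin_label = "16-SASL",
                                             measurement_temperature_C = 12.5,
                                             genotype = "Delisa",
                                             growth_temperature_C = 5,
                                             replicate_id = "b1t2"))
  path <- withr::local_tempfile(fileext = ".txt")
  write_spectrum(sp, path, json_sidecar = TRUE)
  back <- read_spectrum(path)
  expect_identical(back$field, sp$field)
  expect_identical(back$intensity, sp$intensity)
  expect_equal(back$metadata$measurement_temperature_C, 12.5)
  expect_equal(back$metadata$genotype, "Delisa")
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$spin_label, "16-SASL")
})
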