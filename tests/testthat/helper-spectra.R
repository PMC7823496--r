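# Shared fixtures: standard grids and a helper computing S from extracted
# splittings, used across feature/dynamics tests.

grid_2k <- field_grid(329, 341, 2048)
grid_4k <- field_grid(329, 341, 4096)

recover_S <- function(spectrum, options = extraction_options()) {
  f <- extract_anisotropic_features(spectrum, options)
  if (!f$analyzable) return(NA_real_)
  order_parameter(f$A_par_prime_mT, f$A_perp_prime_mT)$S
}

# Fast-motion parameter set realizing requested correlation times (seconds).
fast_params_for_tau <- function(tau2B, tau2C, width_A = 0.15, ...) {
  fast_motion_params(width_A = width_A,
                     width_B = -tau2B / (6.51e-10 * 20),
                     width_C = tau2C / (6.51e-10 * 20), ...)
}

add_noise <- function(spectrum, sd, seed) {
  set.seed(seed)
  spectrum$intensity <- spectrum$intensity +
    stats::rnorm(length(spectrum$intensity), sd = sd)
  spectrum
}
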