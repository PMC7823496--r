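#' Parameters for a fast-motion (three-line) nitroxide simulation
#'
#' Forward model for the motionally narrowed nitroxide triplet: three
#' first-derivative lines of equal integrated intensity at
#' `center_field - mI * hyperfine_splitting_aN` for mI = +1, 0, -1 (the
#' low-field line is mI = +1 and supplies the amplitude h+), with the
#' mI-dependent peak-to-peak width
#' `width_A + width_B * mI + width_C * mI^2`. The mI-linear and mI-quadratic
#' width coefficients are exactly the quantities the rotational correlation
#' times tau2B and tau2C measure, which makes [ground_truth_tau()] an
#' analytic oracle for the whole simulate-extract-compute chain.
#'
#' Field modulation is not modelled explicitly; widths are effective
#' (modulation-folded) peak-to-peak widths.
#'
#' @param center_field Field of the mI = 0 line, mT.
#' @param hyperfine_splitting_aN Isotropic nitrogen hyperfine splitting, mT
#'   (spacing between adjacent lines). Must exceed 3x the largest linewidth so
#'   the three lines stay resolved.
#' @param width_A,width_B,width_C Width-law coefficients, mT. All three
#'   resulting linewidths must be strictly positive.
#' @param lineshape `"lorentzian"` or `"gaussian"`.
#' @param noise_sd Standard deviation of additive Gaussian noise (intensity
#'   units), independent per point.
#' @param baseline_slope Linear baseline slope, intensity per mT.
#' @param seed Integer seed for the noise, or `NULL` to use the ambient RNG
#'   stream. Identical parameters + seed give bit-identical spectra.
#' @return A validated parameter list of class `fast_motion_params`.
#' @seealso [simulate_fast_motion()], [ground_truth_tau()]
#' @export
fast_motion_params <- function(center_field = 335,
                               hyperfine_splitting_aN = 1.5,
                               width_A = 0.15, width_B = 0, width_C = 0,
                               lineshape = c("lorentzian", "gaussian"),
                               noise_sd = 0, baseline_slope = 0, seed = NULL) {
  lineshape <- match.arg(lineshape)
  widths <- width_A + width_B * c(1, 0, -1) + width_C * c(1, 0, 1)
  if (any(widths <= 0)) {
    stop("all three linewidths width_A + width_B*mI + width_C*mI^2 must be positive")
  }
  if (hyperfine_splitting_aN <= 3 * max(widths)) {
    stop("hyperfine_splitting_aN must exceed 3x the largest linewidth (resolved-line regime)")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(center_field = center_field,
                 hyperfine_splitting_aN = hyperfine_splitting_aN,
                 width_A = width_A, width_B = width_B, width_C = width_C,
                 lineshape = lineshape, noise_sd = noise_sd,
                 baseline_slope = baseline_slope, seed = seed),
            class = "fast_motion_params")
}

fast_motion_widths <- function(params) {
  mI <- c(1, 0, -1)
  stats::setNames(params$width_A + params$width_B * mI + params$width_C * mI^2,
                  c("plus", "zero", "minus"))
}

#' Simulate a fast-motion nitroxide first-derivative spectrum
#'
#' @param params A [fast_motion_params()] object.
#' @param grid A [field_grid()].
#' @param metadata Metadata list stored in the returned spectrum;
#'   `spin_label` defaults to `"16-SASL"`.
#' @return An [epr_spectrum()].
#' @examples
#' p <- fast_motion_params(width_A = 0.15, width_B = -0.02, width_C = 0.03)
#' sp <- simulate_fast_motion(p, field_grid(329, 341, 4096))
#' @export
simulate_fast_motion <- function(params, grid = field_grid(),
                                 metadata = list(spin_label = "16-SASL")) {
  stopifnot(inherits(params, "fast_motion_params"))
  w <- fast_motion_widths(params)
  centers <- params$center_field - c(1, 0, -1) * params$hyperfine_splitting_aN
  lo <- min(centers) - 3 * max(w)
  hi <- max(centers) + 3 * max(w)
  if (min(grid$field) > lo || max(grid$field) < hi) {
    stop("field grid does not cover all three lines +- 3 linewidths")
  }
  y <- deriv_line(grid$field, centers[1L], w[["plus"]], params$lineshape) +
    deriv_line(grid$field, centers[2L], w[["zero"]], params$lineshape) +
    deriv_line(grid$field, centers[3L], w[["minus"]], params$lineshape)
  y <- y + params$baseline_slope * (grid$field - params$center_field)
  if (params$noise_sd > 0) {
    y <- y + with_local_seed(params$seed,
                             stats::rnorm(length(y), sd = params$noise_sd))
  }
  epr_spectrum(grid$field, y, metadata)
}

#' Analytic correlation times implied by fast-motion simulation parameters
#'
#' Closed-form inverse of the simulate -> extract -> correlation-time chain.
#' For area-normalized Lorentzian derivative lines the peak-to-peak amplitude
#' is proportional to 1/width^2, so the amplitude-ratio square roots in the
#' tau formulas reduce to linewidth ratios and (with widths in gauss,
#' 1 mT = 10 G):
#' \deqn{\tau_{2B} = 6.51 \times 10^{-10} \cdot (\Delta H_{-1} - \Delta H_{+1})
#'   = 6.51 \times 10^{-10} \cdot (-2\, width_B \cdot 10)}
#' \deqn{\tau_{2C} = 6.51 \times 10^{-10} \cdot (\Delta H_{-1} + \Delta H_{+1}
#'   - 2 \Delta H_0) = 6.51 \times 10^{-10} \cdot (2\, width_C \cdot 10)}
#' both in seconds. The 1/width^2 amplitude identity is exact only for
#' Lorentzian lines, so Gaussian parameter sets are rejected.
#'
#' @param params A [fast_motion_params()] with `lineshape = "lorentzian"`.
#' @return A list with `tau2B` and `tau2C` in seconds.
#' @examples
#' ground_truth_tau(fast_motion_params(width_B = -0.02, width_C = 0.03))
#' @export
ground_truth_tau <- function(params) {
  stopifnot(inherits(params, "fast_motion_params"))
  if (params$lineshape != "lorentzian") {
    stop("ground_truth_tau is defined only for Lorentzian lineshapes")
  }
  mt_to_gauss <- 10
  list(tau2B = 6.51e-10 * (-2 * params$width_B) * mt_to_gauss,
       tau2C = 6.51e-10 * (2 * params$width_C) * mt_to_gauss)
}

#' Parameters for an anisotropic (axially split) nitroxide simulation
#'
#' Forward model for the motionally restricted spectra seen with a 5-SASL
#' probe near the membrane polar heads: a phenomenological superposition of an
#' axially split derivative-Lorentzian doublet (which supplies the outer
#' extrema at `center_field +- A_par` and, through its inner lobes, the inner
#' extrema at `center_field -+ A_perp` with the canonical sign pattern:
#' low-field minimum, high-field maximum) and an optional narrow central
#' component. The doublet separation and width are calibrated internally by
#' self-extraction so that the realized outer and inner splittings match
#' `2*A_par` and `2*A_perp`; [simulate_anisotropic()] verifies this before
#' returning.
#'
#' @param center_field Spectrum centre, mT.
#' @param A_par Target outer half-splitting A'par, mT.
#' @param A_perp Target inner half-splitting A'perp, mT. Must satisfy
#'   `A_par > A_perp > 0`.
#' @param component_width Peak-to-peak width of the central component, mT.
#' @param mixing_weight Weight in `[0, 1)` of the central component in the
#'   peak-normalized mixture; must stay below 0.5 so the outer extrema remain
#'   the global ones.
#' @param noise_sd,baseline_slope,seed As in [fast_motion_params()].
#' @return A validated parameter list of class `anisotropic_params`.
#' @export
anisotropic_params <- function(center_field = 335, A_par = 3, A_perp = 1.5,
                               component_width = 0.35, mixing_weight = 0.15,
                               noise_sd = 0, baseline_slope = 0, seed = NULL) {
  if (!(A_par > A_perp && A_perp > 0)) stop("require A_par > A_perp > 0")
  if (component_width <= 0) stop("component_width must be positive")
  if (mixing_weight < 0 || mixing_weight >= 0.5) {
    stop("mixing_weight must lie in [0, 0.5) so the outer extrema dominate")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(center_field = center_field, A_par = A_par, A_perp = A_perp,
                 component_width = component_width,
                 mixing_weight = mixing_weight, noise_sd = noise_sd,
                 baseline_slope = baseline_slope, seed = seed),
            class = "anisotropic_params")
}

# Noise-free anisotropic composite for internal calibration: doublet lines at
# center +- d with peak-to-peak width w, plus central component, each piece
# normalized to unit maximum absolute intensity before mixing.
aniso_composite <- function(field, center, d, w, mixing_weight, component_width) {
  doublet <- deriv_lorentzian(field, center - d, w) +
    deriv_lorentzian(field, center + d, w)
  doublet <- doublet / max(abs(doublet))
  if (mixing_weight > 0) {
    central <- deriv_lorentzian(field, center, component_width)
    central <- central / max(abs(central))
    (1 - mixing_weight) * doublet + mixing_weight * central
  } else {
    doublet
  }
}

#' Simulate an anisotropic nitroxide first-derivative spectrum
#'
#' The realized spectrum's outermost extrema are separated by `2*A_par` and
#' its characteristic inner extrema by `2*A_perp` (verified by
#' self-extraction to within half a grid step before noise and baseline are
#' added; a geometry that cannot produce four distinct extrema raises an
#' error).
#'
#' @param params An [anisotropic_params()] object.
#' @param grid A [field_grid()].
#' @param metadata Metadata list; `spin_label` defaults to `"5-SASL"`.
#' @return An [epr_spectrum()].
#' @examples
#' p <- anisotropic_params(A_par = 3, A_perp = 1.5)
#' sp <- simulate_anisotropic(p, field_grid(329, 341, 2048))
#' @export
simulate_anisotropic <- function(params, grid = field_grid(),
                                 metadata = list(spin_label = "5-SASL")) {
  stopifnot(inherits(params, "anisotropic_params"))
  ctr <- params$center_field
  if (min(grid$field) > ctr - params$A_par - 2 ||
      max(grid$field) < ctr + params$A_par + 2) {
    stop("field grid does not cover the outer extrema with margin")
  }
  # Fixed-point calibration of (half-separation d, doublet width w): for an
  # isolated doublet the outer separation is 2d + w and the inner is 2d - w;
  # overlap and the central component perturb both, so iterate on the realized
  # splittings as measured by the package's own (default) extraction path, so
  # that simulate -> extract round-trips exactly by construction.
  opts <- extraction_options()
  d <- (params$A_par + params$A_perp) / 2
  w <- params$A_par - params$A_perp
  tol <- grid$step / 4
  ok <- FALSE
  for (iter in seq_len(80L)) {
    if (w <= grid$step || d <= w / 2) break
    y <- aniso_composite(grid$field, ctr, d, w,
                         params$mixing_weight, params$component_width)
    feat <- extract_anisotropic_features(epr_spectrum(grid$field, y), opts)
    if (!feat$analyzable) break
    err_o <- 2 * (params$A_par - feat$A_par_prime_mT)
    err_i <- 2 * (params$A_perp - feat$A_perp_prime_mT)
    if (abs(err_o) < tol && abs(err_i) < tol) {
      ok <- TRUE
      break
    }
    d <- d + (err_o + err_i) / 4
    w <- w + (err_o - err_i) / 2
  }
  if (!ok) {
    stop("unresolvable anisotropic geometry: requested splittings/widths do ",
         "not yield four distinct extrema at the target positions")
  }
  y <- y + params$baseline_slope * (grid$field - ctr)
  if (params$noise_sd > 0) {
    y <- y + with_local_seed(params$seed,
                             stats::rnorm(length(y), sd = params$noise_sd))
  }
  epr_spectrum(grid$field, y, metadata)
}

#' Hyperfine splittings that realize a requested order parameter
#'
#' Inverts the order-parameter relation: given a target S and isotropic
#' coupling a0, returns the outer/inner half-splittings with
#' `a0 = (A_par + 2 A_perp) / 3` and `S = 0.5407 (A_par - A_perp) / a0`.
#' Useful for designing simulated temperature series with known ground truth.
#'
#' @param S Target order parameter (dimensionless, `0 < S` and small enough
#'   that `A_perp > 0`, i.e. `S < 3 * 0.5407 = 1.6221`).
#' @param a0 Target isotropic hyperfine coupling, mT.
#' @return A list with `A_par` and `A_perp` in mT.
#' @examples
#' splittings_for_order(0.4055, a0 = 2)
#' @export
splittings_for_order <- function(S, a0 = 1.5) {
  stopifnot(S > 0, a0 > 0)
  gap <- S * a0 / 0.5407
  A_par <- a0 + 2 * gap / 3
  A_perp <- a0 - gap / 3
  if (A_perp <= 0) stop("requested S too large for positive A_perp")
  list(A_par = A_par, A_perp = A_perp)
}
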