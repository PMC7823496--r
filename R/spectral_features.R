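#' Options controlling spectral feature extraction
#'
#' @param baseline Correct a linear baseline (via [correct_baseline()])
#'   before analysing. Default `TRUE`; harmless on already-flat spectra.
#' @param smooth Apply a Savitzky-Golay filter before extremum detection.
#'   Default `FALSE` (noiseless synthetic data); switch on (window 5,
#'   order 2) for noisy data and keep the setting identical across all
#'   spectra of a series.
#' @param smooth_window Odd filter window length in points.
#' @param smooth_order Polynomial order of the filter.
#' @param snr_threshold Analyzability rule: every required extremum must
#'   exceed `snr_threshold` times the robust noise estimate (MAD of the
#'   detrended field-edge windows). Default 4.
#' @param edge_fraction Fraction of points at each field edge treated as
#'   line-free for noise estimation and baseline fitting. Default 0.05.
#' @return A list of class `extraction_options`.
#' @export
extraction_options <- function(baseline = TRUE, smooth = FALSE,
                               smooth_window = 5L, smooth_order = 2L,
                               snr_threshold = 4, edge_fraction = 0.05) {
  smooth_window <- as.integer(smooth_window)
  if (smooth && (smooth_window %% 2L == 0L || smooth_window < 3L)) {
    stop("smooth_window must be odd and >= 3")
  }
  if (edge_fraction <= 0 || edge_fraction > 0.25) {
    stop("edge_fraction must be in (0, 0.25]")
  }
  structure(list(baseline = baseline, smooth = smooth,
                 smooth_window = smooth_window, smooth_order = smooth_order,
                 snr_threshold = snr_threshold, edge_fraction = edge_fraction),
            class = "extraction_options")
}

# All interior local extrema of y (plateaus carry the preceding slope sign).
local_extrema <- function(y) {
  s <- sign(diff(y))
  if (any(s == 0)) {
    for (i in seq_along(s)) if (s[i] == 0 && i > 1L) s[i] <- s[i - 1L]
  }
  ch <- which(s[-length(s)] != s[-1L] & s[-length(s)] != 0)
  idx <- ch + 1L
  data.frame(index = idx,
             type = ifelse(s[ch] > 0, "max", "min"),
             value = y[idx], stringsAsFactors = FALSE)
}

# Local polynomial refinement of an extremum position/value on a uniform
# grid. A cubic is fitted by least squares over a symmetric window of
# `half_width` points around the raw extremum (the window is sized by the
# caller from the line's own extremum-pair distance, i.e. it scales with the
# lobe width); the cubic's stationary point nearest the window centre is the
# refined extremum. Modelling the cubic term cancels the position bias a
# plain parabola picks up from lobe asymmetry, while the wide window
# averages point noise. Falls back to the exact 3-point parabola when the
# window is too narrow for a stable fit.
refine_extremum <- function(field, y, i, half_width = 1L) {
  n <- length(y)
  if (i <= 1L || i >= n) return(list(field = field[i], value = y[i]))
  m <- max(1L, as.integer(half_width))
  lo <- max(1L, i - m)
  hi <- min(n, i + m)
  if (hi - lo + 1L >= 9L) {
    x <- field[lo:hi] - field[i]
    cf <- stats::lm.fit(cbind(1, x, x^2, x^3), y[lo:hi])$coefficients
    disc <- cf[3L]^2 - 3 * cf[2L] * cf[4L]
    if (is.finite(disc) && disc >= 0 && cf[4L] != 0) {
      roots <- c(-cf[3L] + sqrt(disc), -cf[3L] - sqrt(disc)) / (3 * cf[4L])
      xv <- roots[which.min(abs(roots))]
      if (abs(xv) <= (field[hi] - field[lo]) / 2) {
        return(list(field = field[i] + xv,
                    value = cf[1L] + cf[2L] * xv + cf[3L] * xv^2 + cf[4L] * xv^3))
      }
    }
  }
  denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
  if (denom == 0) return(list(field = field[i], value = y[i]))
  step <- field[i + 1L] - field[i]
  delta <- 0.5 * (y[i - 1L] - y[i + 1L]) / denom
  list(field = field[i] + delta * step,
       value = y[i] - (y[i - 1L] - y[i + 1L])^2 / (8 * denom))
}

# Topographic prominence of maxima at indices `idx`: height above the
# deeper of the two saddle minima separating the peak from higher terrain
# (or the signal edge) on each side.
peak_prominence <- function(y, idx) {
  vapply(idx, function(i) {
    h <- y[i]
    left <- h
    j <- i
    while (j > 1L) {
      j <- j - 1L
      if (y[j] > h) break
      left <- min(left, y[j])
    }
    right <- h
    j <- i
    n <- length(y)
    while (j < n) {
      j <- j + 1L
      if (y[j] > h) break
      right <- min(right, y[j])
    }
    h - max(left, right)
  }, 0)
}

edge_window_indices <- function(n, edge_fraction) {
  k <- max(5L, floor(edge_fraction * n))
  list(left = seq_len(k), right = seq(n - k + 1L, n))
}

# Robust per-point noise: MAD of linearly detrended edge windows.
noise_sigma <- function(field, y, edge_fraction = 0.05) {
  win <- edge_window_indices(length(y), edge_fraction)
  detrend <- function(idx) {
    stats::residuals(stats::lm.fit(cbind(1, field[idx]), y[idx]))
  }
  stats::mad(c(detrend(win$left), detrend(win$right)), center = 0)
}

#' Subtract a linear baseline fitted through the field-edge windows
#'
#' Fits a straight line through the outer `edge_fraction` of points at each
#' end of the field axis (assumed line-free) and subtracts it. Idempotent
#' within numerical tolerance. A warning is issued when the edge windows show
#' structure comparable to the spectrum itself, which indicates that spectral
#' lines overlap the fitting windows.
#'
#' @param spectrum An [epr_spectrum()].
#' @param edge_fraction Fraction of points per edge used for the fit.
#' @return The corrected [epr_spectrum()].
#' @export
correct_baseline <- function(spectrum, edge_fraction = 0.05) {
  stopifnot(inherits(spectrum, "epr_spectrum"))
  f <- spectrum$field
  y <- spectrum$intensity
  win <- edge_window_indices(length(y), edge_fraction)
  idx <- c(win$left, win$right)
  rng_all <- diff(range(y))
  rng_edge <- max(diff(range(y[win$left])), diff(range(y[win$right])))
  fit <- stats::lm.fit(cbind(1, f[idx]), y[idx])
  base <- fit$coefficients[1L] + fit$coefficients[2L] * f
  # Flag edge structure only when it exceeds both a fifth of the full signal
  # range and what point noise alone would explain -- smooth line tails
  # leaking into the windows, not noise, are the hazard for the fit.
  sigma_edge <- noise_sigma(f, y, edge_fraction)
  if (rng_all > 0 && rng_edge > 0.2 * rng_all && rng_edge > 10 * sigma_edge) {
    warning("edge windows show spectral structure; baseline fit may overlap lines")
  }
  epr_spectrum(f, y - base, spectrum$metadata)
}

prepare_signal <- function(spectrum, options) {
  if (!is_uniform_grid(spectrum$field)) {
    stop("feature extraction requires a uniform field grid")
  }
  if (options$baseline) spectrum <- correct_baseline(spectrum, options$edge_fraction)
  y <- spectrum$intensity
  if (options$smooth) {
    y <- signal::sgolayfilt(y, p = options$smooth_order, n = options$smooth_window)
  }
  list(field = spectrum$field, y = y,
       sigma = noise_sigma(spectrum$field, y, options$edge_fraction))
}

features_row <- function(A_par = NA_real_, A_perp = NA_real_,
                         deltaH0 = NA_real_, h_plus = NA_real_,
                         h_zero = NA_real_, h_minus = NA_real_,
                         analyzable = FALSE) {
  out <- data.frame(A_par_prime_mT = A_par, A_perp_prime_mT = A_perp,
                    deltaH0_mT = deltaH0, h_plus = h_plus, h_zero = h_zero,
                    h_minus = h_minus, analyzable = analyzable)
  class(out) <- c("spectral_features", class(out))
  out
}

#' Extract fast-motion (three-line) spectral features
#'
#' Locates the three nitroxide derivative lines (each a positive lobe
#' followed by a negative lobe), assigns them by field order to the mI = +1,
#' 0, -1 lines, and measures the amplitudes `h_plus`, `h_zero`, `h_minus`
#' (peak-to-peak, positive extremum minus negative extremum) and the central
#' peak-to-peak linewidth `deltaH0` (field separation of the central line's
#' two extrema). Extremum positions and values are refined by three-point
#' quadratic interpolation. When the three lines are selected, the three
#' largest peak-to-peak candidates ordered by field are used.
#'
#' A spectrum is analyzable only if all six required extrema exceed
#' `snr_threshold` times the robust noise estimate; otherwise a row with
#' `analyzable = FALSE` is returned (never an error), mirroring how measured
#' spin-label spectra drop out of analysis at unfavourable temperatures.
#'
#' @param spectrum An [epr_spectrum()] on a uniform field grid.
#' @param options An [extraction_options()] list.
#' @return A one-row data frame of class `spectral_features` with columns
#'   `A_par_prime_mT`, `A_perp_prime_mT` (both `NA` here), `deltaH0_mT`,
#'   `h_plus`, `h_zero`, `h_minus`, `analyzable`.
#' @examples
#' sp <- simulate_fast_motion(fast_motion_params(), field_grid(329, 341, 2048))
#' extract_fast_motion_features(sp)
#' @export
extract_fast_motion_features <- function(spectrum, options = extraction_options()) {
  sig <- prepare_signal(spectrum, options)
  thr <- options$snr_threshold * sig$sigma
  ext <- local_extrema(sig$y)
  maxima <- ext[ext$type == "max" & ext$value > thr, , drop = FALSE]
  minima <- ext[ext$type == "min" & ext$value < -thr, , drop = FALSE]
  if (nrow(maxima) < 3L || nrow(minima) < 3L) return(features_row())
  # One positive lobe can carry several raw local maxima under noise;
  # prominence-ranked selection keeps one representative per physical line.
  prom <- peak_prominence(sig$y, maxima$index)
  top <- maxima$index[order(prom, decreasing = TRUE)[1:3]]
  top <- sort(top)
  # Each line is the (positive lobe, deepest negative lobe before the next
  # selected line) pair.
  keep <- list()
  bounds <- c(top, length(sig$y) + 1L)
  for (k in 1:3) {
    cand <- minima[minima$index > top[k] & minima$index < bounds[k + 1L], ,
                   drop = FALSE]
    if (nrow(cand) == 0L) return(features_row())
    keep[[k]] <- list(i_max = top[k], i_min = cand$index[which.min(cand$value)])
  }
  amp <- numeric(3L)
  centre_fields <- matrix(0, 3L, 2L)
  for (k in 1:3) {
    m <- max(3L, as.integer(round(0.35 * (keep[[k]]$i_min - keep[[k]]$i_max))))
    rmax <- refine_extremum(sig$field, sig$y, keep[[k]]$i_max, m)
    rmin <- refine_extremum(sig$field, sig$y, keep[[k]]$i_min, m)
    amp[k] <- rmax$value - rmin$value
    centre_fields[k, ] <- c(rmax$field, rmin$field)
  }
  features_row(deltaH0 = centre_fields[2L, 2L] - centre_fields[2L, 1L],
               h_plus = amp[1L], h_zero = amp[2L], h_minus = amp[3L],
               analyzable = TRUE)
}

# Shared anatomy rules for axially split spectra. Outer pair: the global
# maximum and global minimum (polarity-agnostic, so mirrored/negated spectra
# give identical splittings). Inner pair: the first opposite-type local
# extremum inward of the low-field outer extremum and the last opposite-type
# extremum before the high-field one.
aniso_splittings_core <- function(field, y, sigma = 0, snr_threshold = 4) {
  fail <- list(ok = FALSE)
  n <- length(y)
  i_max <- which.max(y)
  i_min <- which.min(y)
  thr <- snr_threshold * sigma
  if (i_max %in% c(1L, n) || i_min %in% c(1L, n)) return(fail)
  if (y[i_max] <= thr || y[i_min] >= -thr) return(fail)
  low <- min(i_max, i_min)
  high <- max(i_max, i_min)
  low_type <- if (low == i_max) "max" else "min"
  high_type <- if (low_type == "max") "min" else "max"
  ext <- local_extrema(y)
  ext <- ext[ext$index > low & ext$index < high &
               abs(ext$value) > thr, , drop = FALSE]
  # A genuine inner extremum carries a lobe of its own sign (a minimum dips
  # below zero, a maximum rises above it); this rejects noise wiggles riding
  # on the flanks of the outer lobes.
  ext <- ext[(ext$type == "max" & ext$value > thr) |
               (ext$type == "min" & ext$value < -thr), , drop = FALSE]
  # The characteristic inner pair brackets the spectrum centre: the low-field
  # member sits in the low-field half of the inter-outer interval and is the
  # strongest extremum of the type opposite to the low-field outer lobe (and
  # mirror-wise on the high-field side). "Strongest" (deepest minimum /
  # highest maximum) is robust to residual noise wiggles on the lobe flanks.
  mid <- (low + high) / 2
  pick <- function(cand, type) {
    cand <- cand[cand$type == type, , drop = FALSE]
    if (nrow(cand) == 0L) return(NA_integer_)
    if (type == "min") cand$index[which.min(cand$value)]
    else cand$index[which.max(cand$value)]
  }
  il <- pick(ext[ext$index <= mid, , drop = FALSE], high_type)
  ih <- pick(ext[ext$index >= mid, , drop = FALSE], low_type)
  if (is.na(il) || is.na(ih) || il >= ih) return(fail)
  m_lo <- max(3L, as.integer(round(0.25 * (il - low))))
  m_hi <- max(3L, as.integer(round(0.25 * (high - ih))))
  r_lo <- refine_extremum(field, y, low, m_lo)
  r_hi <- refine_extremum(field, y, high, m_hi)
  r_il <- refine_extremum(field, y, il, m_lo)
  r_ih <- refine_extremum(field, y, ih, m_hi)
  A_par <- (r_hi$field - r_lo$field) / 2
  A_perp <- (r_ih$field - r_il$field) / 2
  if (!(A_par > A_perp && A_perp > 0)) return(fail)
  list(ok = TRUE, A_par = A_par, A_perp = A_perp)
}

#' Extract anisotropic (axially split) spectral features
#'
#' Measures the outer half-splitting `A'par` (half the separation between the
#' global low-field maximum and global high-field minimum) and the inner
#' half-splitting `A'perp` (half the separation between the characteristic
#' inner extrema pair: the first local minimum inward of the low-field outer
#' maximum and the last local maximum before the high-field outer minimum),
#' each refined by quadratic interpolation. The rules are polarity-agnostic,
#' so a spectrum mirrored about its centre yields identical splittings.
#'
#' Returns `analyzable = FALSE` (not an error) when the required extrema do
#' not rise above `snr_threshold` times the robust noise estimate.
#'
#' @inheritParams extract_fast_motion_features
#' @return A one-row `spectral_features` data frame with the splittings set
#'   and the fast-motion amplitudes `NA`.
#' @examples
#' sp <- simulate_anisotropic(anisotropic_params(A_par = 3, A_perp = 1.5),
#'                            field_grid(329, 341, 2048))
#' extract_anisotropic_features(sp)
#' @export
extract_anisotropic_features <- function(spectrum, options = extraction_options()) {
  sig <- prepare_signal(spectrum, options)
  geom <- aniso_splittings_core(sig$field, sig$y, sig$sigma,
                                options$snr_threshold)
  if (!geom$ok) return(features_row())
  features_row(A_par = geom$A_par, A_perp = geom$A_perp, analyzable = TRUE)
}
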