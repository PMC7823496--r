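# Analytic first-derivative lineshapes, parameterized directly by the
# peak-to-peak width of the derivative (the quantity read off an EPR trace).
# Absorption profiles are area-normalized, i.e. every line carries the same
# integrated (double-integral) intensity; for a Lorentzian this yields the
# derivative peak-to-peak amplitude proportional to 1/width^2, which is the
# identity the motional-narrowing correlation-time formulas rely on.

# Lorentzian absorption HWHM gamma for derivative peak-to-peak width w:
# extrema of dA/dB at +-gamma/sqrt(3) => w = 2*gamma/sqrt(3).
deriv_lorentzian <- function(field, center, width_pp) {
  gamma <- sqrt(3) / 2 * width_pp
  u <- field - center
  -(2 / pi) * gamma * u / (u^2 + gamma^2)^2
}

# Gaussian: extrema of dA/dB at +-sigma => w = 2*sigma.
deriv_gaussian <- function(field, center, width_pp) {
  sigma <- width_pp / 2
  u <- field - center
  -u / sigma^2 * stats::dnorm(u, sd = sigma)
}

deriv_line <- function(field, center, width_pp,
                       lineshape = c("lorentzian", "gaussian")) {
  lineshape <- match.arg(lineshape)
  if (width_pp <= 0) stop("line width must be strictly positive")
  switch(lineshape,
         lorentzian = deriv_lorentzian(field, center, width_pp),
         gaussian = deriv_gaussian(field, center, width_pp))
}
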