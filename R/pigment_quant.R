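#' Chlorophyll and carotenoid concentrations from acetone-extract absorbances
#'
#' Standard 80%-acetone equations from absorbances at 663.2, 664.8 and
#' 470 nm:
#' \deqn{C_a = 12.25 A_{663.2} - 2.79 A_{664.8}}
#' \deqn{C_b = 21.50 A_{664.8} - 5.10 A_{663.2}}
#' \deqn{C_{a+b} = 7.15 A_{663.2} + 18.71 A_{664.8}}
#' \deqn{C_{x+c} = (1000 A_{470} - 1.82 C_a - 85.02 C_b) / 198}
#' all in ug/mL of extract. The coefficient identity (12.25 - 5.10 = 7.15,
#' 21.50 - 2.79 = 18.71) guarantees `Ca + Cb = Ca_plus_b` exactly. Negative
#' results (a blank/turbidity indicator) are flagged, never clipped.
#'
#' @param a663_2,a664_8,a470 Absorbances (>= 0). Vectorized.
#' @param dilution_factor Extract volume over sample volume; the default 210
#'   corresponds to 0.01 mL of chloroplast suspension brought to 2.10 mL with
#'   80% acetone.
#' @param per_sample If `TRUE`, additionally report concentrations scaled
#'   back to the original sample (`* dilution_factor`).
#' @return A data frame with columns `Ca`, `Cb`, `Ca_plus_b`, `Cx_plus_c`
#'   (ug/mL extract), `negative_flag` (any pigment below zero), and when
#'   `per_sample = TRUE` the four `_sample` columns (ug/mL sample).
#' @examples
#' pigment_concentrations(0.5, 0.3, 0.8)
#' @export
pigment_concentrations <- function(a663_2, a664_8, a470,
                                   dilution_factor = 210,
                                   per_sample = FALSE) {
  n <- length(a663_2)
  if (any(lengths(list(a664_8, a470)) != n)) {
    stop("absorbance vectors must have equal length")
  }
  if (any(c(a663_2, a664_8, a470) < 0)) stop("absorbances must be >= 0")
  if (any(dilution_factor <= 0)) stop("dilution_factor must be positive")
  ca <- 12.25 * a663_2 - 2.79 * a664_8
  cb <- 21.50 * a664_8 - 5.10 * a663_2
  cab <- 7.15 * a663_2 + 18.71 * a664_8
  cxc <- (1000 * a470 - 1.82 * ca - 85.02 * cb) / 198
  out <- data.frame(Ca = ca, Cb = cb, Ca_plus_b = cab, Cx_plus_c = cxc,
                    negative_flag = ca < 0 | cb < 0 | cxc < 0)
  if (per_sample) {
    out$Ca_sample <- ca * dilution_factor
    out$Cb_sample <- cb * dilution_factor
    out$Ca_plus_b_sample <- cab * dilution_factor
    out$Cx_plus_c_sample <- cxc * dilution_factor
  }
  out
}
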