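#' Monoisotopic atomic masses used throughout the package
#'
#' Masses (amu) of the most abundant isotope of each element considered in
#' CHNOSP formula assignment, plus the proton mass used to convert a neutral
#' monoisotopic mass to the singly deprotonated \eqn{[M-H]^-} ion m/z.
#' The electron mass is neglected; at 200--900 m/z this contributes well under
#' 0.5 ppm and is absorbed by the assignment tolerance.
#'
#' @format Named numeric vector with elements \code{C, H, N, O, S, P}.
#' @export
MONOISOTOPIC_MASS <- c(
  C = 12.000000,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069,
  P = 30.97376151
)

#' @rdname MONOISOTOPIC_MASS
#' @export
PROTON_MASS <- 1.0072765

#' @rdname MONOISOTOPIC_MASS
#' @export
C13_C12_DELTA <- 1.003355

#' Average (abundance-weighted) atomic masses
#'
#' Used for element-mass C:N ratios of the detected metabolome, where atom
#' counts are multiplied by standard atomic weights (C = 12.011, N = 14.007),
#' and for amino-acid molar masses.
#'
#' @format Named numeric vector with elements \code{C, H, N, O, S, P}.
#' @export
AVERAGE_MASS <- c(
  C = 12.011,
  H = 1.008,
  N = 14.007,
  O = 15.999,
  S = 32.06,
  P = 30.974
)

# Exact CH2 monoisotopic spacing of a homologous series (C + 2 H).
CH2_MASS <- 14.0156500638

ELEMENTS <- c("C", "H", "N", "O", "S", "P")
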