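# Monoisotopic atomic masses (Da) of the most abundant isotope, CIAAW/AME2020
# values. Pinned here so masses are identical across environments.
.MONOISOTOPIC <- c(
  H  = 1.00782503207,
  D  = 2.01410177785,
  B  = 11.00930536,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  F  = 18.99840316,
  Na = 22.9897692809,
  Mg = 23.985041697,
  Si = 27.9769265347,
  P  = 30.9737616320,
  S  = 31.9720711744,
  Cl = 34.9688526890,
  K  = 38.9637064864,
  Ca = 39.962590863,
  Fe = 55.934936326,
  Cu = 62.929597720,
  Zn = 63.929142010,
  Se = 79.916521800,
  Br = 78.918337600,
  I  = 126.904471900
)

# electron rest mass, Da
.ELECTRON_MASS <- 0.000548579909

# 13C - 12C mass difference, Da, and natural 13C abundance
.C13_SHIFT <- 1.0033548378
.C13_ABUNDANCE <- 0.0107

#' Tabulated monoisotopic atomic masses
#'
#' Returns the packaged table of monoisotopic atomic masses (mass of the most
#' abundant isotope of each element, in Da) used throughout the package.
#'
#' @return Named numeric vector of masses in Da.
#' @export
#' @examples
#' atomic_masses()[c("C", "H", "N", "O")]
atomic_masses <- function() .MONOISOTOPIC
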