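# Physical constants and element data.  Single source of truth for unit
# conversions used across the package.

#' Unit conversion and element data
#'
#' `angstrom_per_bohr` (0.52917721092) converts internal bohr coordinates to
#' the angstrom used in XYZ files; `kcal_per_hartree` (627.509474) converts
#' energies for reporting.  One atomic unit of magnetic field strength
#' (B0) is 2.3505e5 T; field vectors are always given in units of B0.
#'
#' @name efmr-constants
#' @keywords internal
NULL

angstrom_per_bohr <- 0.52917721092
kcal_per_hartree <- 627.509474

.element_Z <- c(
  H = 1L, He = 2L, Li = 3L, Be = 4L, B = 5L, C = 6L, N = 7L, O = 8L,
  F = 9L, Ne = 10L, Na = 11L, Mg = 12L, Al = 13L, Si = 14L, P = 15L,
  S = 16L, Cl = 17L, Ar = 18L
)

# Covalent radii in angstrom (Cordero et al. consensus values), used only
# for bond-graph fragment auto-detection.
.covalent_radius <- c(
  H = 0.31, He = 0.28, Li = 1.28, Be = 0.96, B = 0.84, C = 0.76, N = 0.71,
  O = 0.66, F = 0.57, Ne = 0.58, Na = 1.66, Mg = 1.41, Al = 1.21,
  Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02, Ar = 1.06
)

element_number <- function(symbol) {
  z <- .element_Z[symbol]
  if (anyNA(z)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbol[is.na(z)]), collapse = ", "))
  }
  unname(z)
}
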