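# Pinned element data. Monoisotopic masses and isotope abundances follow the
# IUPAC 2013/CODATA recommended values; the version string below is recorded
# in every database build so stored m/z values are traceable to this table.

ELEMENT_TABLE_VERSION <- "IUPAC-2013/CODATA-2014"

#' Electron rest mass in unified atomic mass units
#' @keywords internal
ELECTRON_MASS <- 0.000548579909

# one row per stable isotope; the monoisotopic mass of an element is the mass
# of its most abundant isotope
.isotope_data <- data.frame(
  element   = c("H", "H",
                "C", "C",
                "N", "N",
                "O", "O", "O",
                "F",
                "Na",
                "Si", "Si", "Si",
                "P",
                "S", "S", "S", "S",
                "Cl", "Cl",
                "K", "K", "K",
                "Br", "Br",
                "I"),
  mass      = c(1.00782503207, 2.01410177812,
                12.0, 13.00335483507,
                14.00307400443, 15.00010889888,
                15.99491461957, 16.99913175650, 17.99915961286,
                18.99840316273,
                22.98976928,
                27.97692653465, 28.97649466490, 29.973770136,
                30.97376199842,
                31.9720711744, 32.9714589098, 33.967867004, 35.96708071,
                34.968852682, 36.965902602,
                38.9637064864, 39.963998166, 40.9618252579,
                78.9183376, 80.9162897,
                126.9044719),
  abundance = c(0.999885, 0.000115,
                0.9893, 0.0107,
                0.99636, 0.00364,
                0.99757, 0.00038, 0.00205,
                1.0,
                1.0,
                0.92223, 0.04685, 0.03092,
                1.0,
                0.9499, 0.0075, 0.0425, 0.0001,
                0.7576, 0.2424,
                0.932581, 0.000117, 0.067302,
                0.5069, 0.4931,
                1.0),
  stringsAsFactors = FALSE
)

# common (lowest) valences; hypervalent states (S(VI), P(V)) are deliberately
# not modelled -- ring/double-bond arithmetic uses these fixed values
.valence <- c(C = 4L, H = 1L, N = 3L, O = 2L, P = 3L, S = 2L,
              Na = 1L, K = 1L, Cl = 1L, Br = 1L, F = 1L, I = 1L, Si = 4L)

.build_element_table <- function() {
  iso <- .isotope_data
  els <- unique(iso$element)
  mono <- vapply(els, function(e) {
    sub <- iso[iso$element == e, ]
    sub$mass[which.max(sub$abundance)]
  }, numeric(1))
  list(
    version   = ELEMENT_TABLE_VERSION,
    elements  = els,
    mono_mass = mono,
    valence   = .valence,
    isotopes  = split(iso[, c("mass", "abundance")], iso$element)
  )
}

.ELEMENTS <- .build_element_table()

#' Pinned element table
#'
#' Returns the element data used for all mass arithmetic in the package:
#' per-element monoisotopic mass (mass of the most abundant stable isotope,
#' in unified atomic mass units), the stable-isotope list with natural
#' abundances, and the standard valence used for ring-plus-double-bond
#' calculations. Covers C, H, N, O, P, S, Na, K, Cl, Br, F, I and Si.
#'
#' @return A list with components `version` (table identifier recorded in
#'   database builds), `elements`, `mono_mass` (named numeric), `valence`
#'   (named integer) and `isotopes` (per-element data frames of mass and
#'   abundance).
#' @examples
#' element_table()$mono_mass[["C"]]
#' @export
element_table <- function() .ELEMENTS

#' Physical constants for charge-corrected mass arithmetic
#'
#' @return Named list with `electron_mass` (u) and `proton_mz`, the m/z of a
#'   bare proton (monoisotopic H mass minus one electron mass).
#' @examples
#' physical_constants()$proton_mz  # 1.007276
#' @export
physical_constants <- function() {
  list(
    electron_mass = ELECTRON_MASS,
    proton_mz = .ELEMENTS$mono_mass[["H"]] - ELECTRON_MASS
  )
}
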