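#' Atomic property tables
#'
#' Per-element constants used by the weighted descriptors: standard atomic
#' mass (unified atomic mass units, CIAAW 2021 abridged values) and first
#' ionization energy (eV, NIST Atomic Spectra Database).  The table is the
#' single authority for property lookups so an alternative convention (for
#' example carbon-referenced weights) can be swapped in one place.
#'
#' @format data.frame with columns `element`, `mass`, `ionization`.
#' @export
atom_properties <- function() {
  data.frame(
    element    = c("H", "B", "C", "N", "O", "F", "Na", "Si", "P", "S",
                   "Cl", "Br", "I", "Se", "As", "K"),
    mass       = c(1.008, 10.811, 12.011, 14.007, 15.999, 18.998, 22.990,
                   28.086, 30.974, 32.066, 35.453, 79.904, 126.904, 78.971,
                   74.922, 39.098),
    ionization = c(13.598, 8.298, 11.260, 14.534, 13.618, 17.423, 5.139,
                   8.152, 10.487, 10.360, 12.968, 11.814, 10.451, 9.752,
                   9.789, 4.341),
    stringsAsFactors = FALSE)
}

# principal quantum number of the valence shell (E-state intrinsic states)
PRINCIPAL_QUANTUM <- c(H = 1, B = 2, C = 2, N = 2, O = 2, F = 2,
                       Na = 3, Si = 3, P = 3, S = 3, Cl = 3,
                       K = 4, Br = 4, Se = 4, As = 4, I = 5)

# valence electron counts
VALENCE_ELECTRONS <- c(H = 1, B = 3, C = 4, N = 5, O = 6, F = 7,
                       Na = 1, Si = 4, P = 5, S = 6, Cl = 7,
                       K = 1, Br = 7, Se = 6, As = 5, I = 7)

# property vector for a graph; elements outside the table fail loudly
atom_property_values <- function(g, prop = c("mass", "ionization")) {
  prop <- match.arg(prop)
  tab <- atom_properties()
  idx <- match(g$atoms$element, tab$element)
  if (anyNA(idx))
    stop("no ", prop, " tabulated for element(s): ",
         paste(unique(g$atoms$element[is.na(idx)]), collapse = ", "))
  tab[[prop]][idx]
}
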