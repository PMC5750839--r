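# Element reference data: Bondi van der Waals radii and standard atomic
# masses. Radii feed the Gaussian shape model; masses feed the MW filter.

.BONDI_RADII <- c(
  H = 1.20, He = 1.40,
  C = 1.70, N = 1.55, O = 1.52, F = 1.47,
  Na = 2.27, Mg = 1.73, Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75,
  K = 2.75, Br = 1.85, I = 1.98
)

.DEFAULT_VDW <- 1.70

.ATOMIC_MASSES <- c(
  H = 1.008, He = 4.003, Li = 6.94, B = 10.81, C = 12.011, N = 14.007,
  O = 15.999, F = 18.998, Na = 22.990, Mg = 24.305, Si = 28.085,
  P = 30.974, S = 32.06, Cl = 35.45, K = 39.098, Ca = 40.078,
  Br = 79.904, I = 126.904
)

# Typical neutral-atom valences used for implicit-hydrogen assignment.
.VALENCES <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1,
               I = 1, B = 3, Si = 4)

#' Van der Waals radius of an element
#'
#' Bondi radii; unknown elements fall back to 1.70 Angstrom with a warning.
#'
#' @param element Character vector of element symbols.
#' @return Numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(element) {
  r <- unname(.BONDI_RADII[element])
  if (anyNA(r)) {
    unknown <- unique(element[is.na(r)])
    warning("No van der Waals radius for element(s) ",
            paste(unknown, collapse = ", "),
            "; using default ", .DEFAULT_VDW, " Angstrom")
    r[is.na(r)] <- .DEFAULT_VDW
  }
  r
}

atomic_mass <- function(element) {
  m <- unname(.ATOMIC_MASSES[element])
  if (anyNA(m)) {
    stop("No atomic mass for element(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  }
  m
}

element_valence <- function(element) {
  v <- unname(.VALENCES[element])
  v[is.na(v)] <- 0
  v
}
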