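#' Physical constants and unit conversions
#'
#' External units throughout the package are Angstrom, eV, elementary charge,
#' femtosecond, amu and Kelvin. Dispersion internals work in Hartree atomic
#' units and convert at the module boundary. All conversion constants live in
#' this one table.
#'
#' @format A named list:
#' \describe{
#'   \item{coulomb_ev_ang}{e^2/(4 pi eps0) in eV*Angstrom per e^2 (14.3996...)}
#'   \item{bohr_ang}{Bohr radius in Angstrom}
#'   \item{hartree_ev}{Hartree in eV}
#'   \item{kb_ev}{Boltzmann constant in eV/K}
#'   \item{kb_kcal}{Boltzmann constant in kcal/mol/K}
#'   \item{amu_ev_fs_ang}{1 amu expressed in eV*fs^2/Angstrom^2 (103.64...)}
#'   \item{fine_structure}{fine-structure constant alpha = e^2/(4 pi eps0 hbar c)}
#'   \item{c_cm_fs}{speed of light in cm/fs (for wavenumber conversion)}
#'   \item{evang3_bar}{1 eV/Angstrom^3 in bar}
#' }
#' @export
ff_constants <- list(
  coulomb_ev_ang = 14.399645478425664,
  bohr_ang       = 0.529177210903,
  hartree_ev     = 27.211386245988,
  kb_ev          = 8.617333262e-5,
  kb_kcal        = 1.987204259e-3,
  amu_ev_fs_ang  = 103.642696562,
  fine_structure = 1 / 137.035999084,
  c_cm_fs        = 2.99792458e-5,
  evang3_bar     = 1.602176634e6
)

# Supported elements: the 8 predominant in biosystems.
.ff_elements <- data.frame(
  symbol = c("H", "C", "N", "O", "F", "P", "S", "Cl"),
  z      = c(1L, 6L, 7L, 8L, 9L, 15L, 16L, 17L),
  mass   = c(1.008, 12.011, 14.007, 15.999, 18.998403, 30.973762, 32.06, 35.45),
  # Cordero covalent radii, Angstrom
  r_cov  = c(0.31, 0.76, 0.71, 0.66, 0.57, 1.07, 1.05, 1.02),
  # Free-atom static dipole polarizability (a.u.) and homonuclear C6 (Ha a0^6),
  # the Chu-Dalgarno reference values conventionally used with the
  # Tkatchenko-Scheffler method.
  alpha_free = c(4.50, 12.0, 7.4, 5.4, 3.8, 25.0, 19.6, 15.0),
  c6_free    = c(6.50, 46.6, 24.2, 15.6, 9.5, 185.0, 134.0, 94.6),
  stringsAsFactors = FALSE
)

#' Supported atomic numbers
#' @return Integer vector of the 8 supported atomic numbers (H, C, N, O, F, P, S, Cl).
#' @export
supported_elements <- function() .ff_elements$z

#' Map atomic numbers to element symbols (and back)
#' @param z Integer vector of atomic numbers.
#' @return Character vector of symbols.
#' @export
element_symbol <- function(z) {
  idx <- match(z, .ff_elements$z)
  if (anyNA(idx)) {
    stop("unsupported atomic number(s) ", paste(unique(z[is.na(idx)]), collapse = ", "),
         "; supported elements are ", paste(.ff_elements$symbol, collapse = ", "))
  }
  .ff_elements$symbol[idx]
}

#' @rdname element_symbol
#' @param symbol Character vector of element symbols (case as in "Cl").
#' @export
element_number <- function(symbol) {
  idx <- match(toupper(symbol), toupper(.ff_elements$symbol))
  if (anyNA(idx)) {
    stop("unsupported element(s) ", paste(unique(symbol[is.na(idx)]), collapse = ", "),
         "; supported elements are ", paste(.ff_elements$symbol, collapse = ", "))
  }
  .ff_elements$z[idx]
}

#' Atomic masses in amu
#' @param z Integer vector of atomic numbers.
#' @return Numeric vector of masses (amu).
#' @export
atomic_mass <- function(z) .ff_elements$mass[match(z, .ff_elements$z)]

#' Covalent radii in Angstrom
#' @param z Integer vector of atomic numbers.
#' @return Numeric vector of Cordero covalent radii (Angstrom).
#' @export
covalent_radius <- function(z) .ff_elements$r_cov[match(z, .ff_elements$z)]

#' Free-atom dispersion reference table
#'
#' Per-element free-atom static polarizability (a.u.) and homonuclear C6
#' coefficient (Ha a0^6) used by the Tkatchenko-Scheffler volume scaling.
#' @return data.frame with columns symbol, z, alpha_free, c6_free.
#' @export
free_atom_reference <- function() {
  .ff_elements[, c("symbol", "z", "alpha_free", "c6_free")]
}

# erf via pnorm (no external dependency)
.erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# softplus and its derivative (numerically safe)
.softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
.sigmoid <- function(x) 1 / (1 + exp(-x))
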