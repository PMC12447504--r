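#' ZBL short-range nuclear repulsion configuration
#'
#' The universal Ziegler-Biersack-Littmark screened-Coulomb repulsion
#' `E_pair = (Z_i Z_j e^2 / 4 pi eps0 r) * phi(r / a_ij)` with the 4-term
#' exponential screening function
#' `phi(x) = sum_k c_k exp(-d_k x)` and screening length
#' `a_ij = a0_pref / (Z_i^p + Z_j^p)`. A cosine switching function takes the
#' term smoothly (C1) to zero between `r_inner` and `r_outer`. All constants
#' are overridable so a variant parametrization can be dropped in.
#'
#' @param coeff,expo Screening coefficients and exponents (4 terms); the
#'   coefficients must sum to 1 (ZBL normalization).
#' @param a_pref Screening-length prefactor in Angstrom (0.46850).
#' @param a_exp Exponent p in the screening length (0.23).
#' @param r_inner,r_outer Switching window in Angstrom (energy untouched below
#'   `r_inner`, exactly zero beyond `r_outer`).
#' @return An object of class `zbl_config`.
#' @export
zbl_config <- function(coeff = c(0.18175, 0.50986, 0.28022, 0.02817),
                       expo = c(3.19980, 0.94229, 0.40290, 0.20162),
                       a_pref = 0.46850, a_exp = 0.23,
                       r_inner = 1.5, r_outer = 2.0) {
  if (length(coeff) != length(expo)) stop("coeff and expo must have equal length")
  if (abs(sum(coeff) - 1) > 1e-6) {
    stop("ZBL screening coefficients must sum to 1 (universal normalization)")
  }
  if (!(r_inner > 0 && r_inner < r_outer)) stop("need 0 < r_inner < r_outer")
  structure(list(coeff = coeff, expo = expo, a_pref = a_pref, a_exp = a_exp,
                 r_inner = r_inner, r_outer = r_outer), class = "zbl_config")
}

# switching function and derivative: 1 below r_inner, cosine ramp, 0 above
.zbl_switch <- function(r, cfg) {
  s <- ifelse(r <= cfg$r_inner, 1,
              ifelse(r >= cfg$r_outer, 0,
                     0.5 * (1 + cos(pi * (r - cfg$r_inner) /
                                      (cfg$r_outer - cfg$r_inner)))))
  ds <- ifelse(r <= cfg$r_inner | r >= cfg$r_outer, 0,
               -0.5 * pi / (cfg$r_outer - cfg$r_inner) *
                 sin(pi * (r - cfg$r_inner) / (cfg$r_outer - cfg$r_inner)))
  list(s = s, ds = ds)
}

# per-pair ZBL energy and d(energy)/dr for vectors of Z and r
.zbl_pair <- function(zi, zj, r, cfg) {
  ke <- ff_constants$coulomb_ev_ang
  a <- cfg$a_pref / (zi^cfg$a_exp + zj^cfg$a_exp)
  x <- r / a
  phi <- dphi <- 0
  for (k in seq_along(cfg$coeff)) {
    ek <- cfg$coeff[k] * exp(-cfg$expo[k] * x)
    phi <- phi + ek
    dphi <- dphi - cfg$expo[k] * ek / a
  }
  bare <- ke * zi * zj / r
  sw <- .zbl_switch(r, cfg)
  e <- bare * phi * sw$s
  dedr <- (-bare / r * phi + bare * dphi) * sw$s + bare * phi * sw$ds
  list(e = e, dedr = dedr)
}

#' ZBL repulsion energy
#'
#' @param system An [atomic_system()].
#' @param neighbors A [build_neighbor_table()] result; its cutoff must be at
#'   least the outer switching radius.
#' @param config A [zbl_config()].
#' @return List with `energy` (eV), `pair_energies` (eV, aligned with the
#'   neighbor table) and `forces` (N x 3, eV/Angstrom).
#' @export
zbl_energy <- function(system, neighbors, config = zbl_config()) {
  if (neighbors$cutoff < config$r_outer) {
    stop("neighbor table cutoff must be >= the ZBL outer switching radius")
  }
  n <- n_atoms(system)
  if (!length(neighbors$i)) {
    return(list(energy = 0, pair_energies = numeric(0), forces = matrix(0, n, 3)))
  }
  p <- .zbl_pair(system$numbers[neighbors$i], system$numbers[neighbors$j],
                 neighbors$d, config)
  list(energy = sum(p$e), pair_energies = p$e,
       forces = .pair_forces(neighbors, p$dedr, n))
}
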