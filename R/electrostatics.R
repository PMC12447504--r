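#' Project raw partial charges onto the total-charge constraint
#'
#' Distributes any deficit uniformly: `q_i = raw_i + (Q - sum(raw)) / N`, so
#' that `sum(q) == Q` holds exactly. This is the constraint mechanism used
#' whenever the model's raw charge outputs enter an energy.
#'
#' @param raw Finite numeric vector of raw charges (e).
#' @param total_charge Target total charge Q (e).
#' @param sigma Damping width to carry along (Angstrom).
#' @return An object of class `charge_set`: list with `q`, `sigma`,
#'   `total_charge`.
#' @export
project_charges <- function(raw, total_charge = 0, sigma = 1.0) {
  if (any(!is.finite(raw))) stop("raw charges must be finite")
  q <- raw + (total_charge - sum(raw)) / length(raw)
  structure(list(q = q, sigma = sigma, total_charge = total_charge),
            class = "charge_set")
}

# damped Coulomb pair kernel: f(r) = erf(r/sigma)/r and f'(r); finite at 0
.elec_kernel <- function(r, sigma) {
  x <- r / sigma
  small <- x < 1e-6
  f <- ifelse(small, 2 / (sqrt(pi) * sigma), .erf(x) / r)
  df <- ifelse(small, 0,
               2 * exp(-x^2) / (sqrt(pi) * sigma * r) - .erf(x) / r^2)
  list(f = f, df = df)
}

#' Damped point-charge electrostatic energy
#'
#' `E_elec = k_e sum_(i<j) q_i q_j erf(r_ij / sigma) / r_ij` with the Coulomb
#' constant `k_e` for eV/Angstrom/e units. The erf damping renders the energy
#' finite at r = 0 (`q_i q_j k_e 2/(sigma sqrt(pi))`) and leaves the bare
#' Coulomb asymptote untouched for `r >> sigma`. As in the dispersion module,
#' each pair term is shifted to zero at the cutoff.
#'
#' @param system An [atomic_system()].
#' @param neighbors Long-range neighbor table.
#' @param charges A [project_charges()] result (or a list with `q`, `sigma`).
#' @param shift Apply the cutoff energy shift (default TRUE; skipped for an
#'   infinite cutoff).
#' @return List with `energy` (eV), `pair_energies` (eV), `forces` (N x 3,
#'   eV/Angstrom, at fixed q), and `dE_dq` (eV/e) for the chain rule when the
#'   charges are position-dependent model outputs.
#' @export
electrostatic_energy <- function(system, neighbors, charges, shift = TRUE) {
  sigma <- charges$sigma
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0")
  q <- charges$q
  n <- n_atoms(system)
  ke <- ff_constants$coulomb_ev_ang
  if (!length(neighbors$i)) {
    return(list(energy = 0, pair_energies = numeric(0),
                forces = matrix(0, n, 3), dE_dq = numeric(n)))
  }
  ii <- neighbors$i; jj <- neighbors$j
  kern <- .elec_kernel(neighbors$d, sigma)
  f <- kern$f; df <- kern$df
  fc <- 0
  if (shift && is.finite(neighbors$cutoff)) {
    fc <- .elec_kernel(neighbors$cutoff, sigma)$f
  }
  qq <- q[ii] * q[jj]
  e <- ke * qq * (f - fc)
  dedr <- ke * qq * df
  dE_dq <- tapply2(ii, ke * q[jj] * (f - fc), n) +
    tapply2(jj, ke * q[ii] * (f - fc), n)
  list(energy = sum(e), pair_energies = e,
       forces = .pair_forces(neighbors, dedr, n), dE_dq = dE_dq)
}

#' Molecular dipole moment from point charges
#'
#' `mu = sum_i q_i (r_i - r_0)` with the origin `r_0` at the center of nuclear
#' charge, which is well defined for ions and conventional in dipole-training
#' schemes. For neutral systems the dipole is origin-independent; for a system
#' of total charge Q an origin shift by Delta changes it by `-Q * Delta`.
#'
#' @param system An [atomic_system()].
#' @param charges A [project_charges()] result.
#' @return Length-3 dipole vector (e Angstrom).
#' @export
dipole_from_charges <- function(system, charges) {
  origin <- .charge_origin(system)
  as.numeric(colSums(charges$q * (system$positions -
                                    matrix(origin, n_atoms(system), 3, byrow = TRUE))))
}

.charge_origin <- function(system) {
  w <- as.numeric(system$numbers)
  colSums(system$positions * w) / sum(w)
}
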