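#' Molecular-dynamics state
#'
#' @param system An [atomic_system()].
#' @param velocities N x 3 matrix (Angstrom/fs); defaults to zero.
#' @param masses Atomic masses in amu (default from the element table).
#' @param time Elapsed time (fs).
#' @return An object of class `md_state`.
#' @export
md_state <- function(system, velocities = NULL, masses = NULL, time = 0) {
  n <- n_atoms(system)
  if (is.null(velocities)) velocities <- matrix(0, n, 3)
  if (is.null(masses)) masses <- atomic_mass(system$numbers)
  if (any(masses <= 0)) stop("masses must be > 0")
  structure(list(system = system, velocities = as.matrix(velocities),
                 masses = masses, time = time, forces = NULL, energy = NULL),
            class = "md_state")
}

#' Kinetic energy and instantaneous temperature
#' @param state An [md_state()].
#' @return List with `kinetic` (eV) and `temperature` (K, from 3N degrees of
#'   freedom).
#' @export
kinetic_temperature <- function(state) {
  m <- state$masses * ff_constants$amu_ev_fs_ang
  ke <- 0.5 * sum(m * rowSums(state$velocities^2))
  n <- length(state$masses)
  list(kinetic = ke, temperature = 2 * ke / (3 * n * ff_constants$kb_ev))
}

#' Draw Maxwell-Boltzmann velocities
#' @param state An [md_state()].
#' @param temperature Target temperature (K).
#' @param seed Optional integer seed.
#' @param zero_momentum Remove the center-of-mass drift (default TRUE).
#' @return The state with fresh velocities.
#' @export
maxwell_boltzmann <- function(state, temperature, seed = NULL,
                              zero_momentum = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  m <- state$masses * ff_constants$amu_ev_fs_ang
  sd <- sqrt(ff_constants$kb_ev * temperature / m)
  n <- length(m)
  v <- matrix(stats::rnorm(3 * n), n, 3) * sd
  if (zero_momentum) {
    v <- v - matrix(colSums(v * m) / sum(m), n, 3, byrow = TRUE)
  }
  state$velocities <- v
  state
}

.ensure_forces <- function(state, calculator) {
  if (is.null(state$forces)) {
    out <- calculator(state$system)
    state$forces <- out$forces
    state$energy <- out$energy
  }
  state
}

#' One NVE velocity-Verlet step
#'
#' Symplectic and deterministic; with zero forces positions advance by
#' `v * dt` (uniform linear motion).
#'
#' @param state An [md_state()].
#' @param calculator `function(system) -> list(energy, forces)`.
#' @param dt Time step (fs, > 0).
#' @return The advanced state (forces/energy cached).
#' @export
step_nve <- function(state, calculator, dt) {
  if (dt <= 0) stop("dt must be > 0")
  state <- .ensure_forces(state, calculator)
  m <- state$masses * ff_constants$amu_ev_fs_ang
  v_half <- state$velocities + 0.5 * dt * state$forces / m
  state$system$positions <- state$system$positions + dt * v_half
  out <- calculator(state$system)
  state$velocities <- v_half + 0.5 * dt * out$forces / m
  state$forces <- out$forces
  state$energy <- out$energy
  state$time <- state$time + dt
  state
}

#' One Langevin (BAOAB) NVT step
#'
#' Kick-drift / Ornstein-Uhlenbeck / drift-kick splitting. With
#' `friction -> 0` the stochastic kick vanishes and the update reduces to
#' velocity Verlet. Trajectories are bit-reproducible given the RNG state
#' (seed the session or pass `seed` to [run_md()]).
#'
#' @param state An [md_state()].
#' @param calculator Calculator closure.
#' @param dt Time step (fs).
#' @param temperature Target temperature (K, > 0).
#' @param friction Friction coefficient (1/fs).
#' @return Advanced state.
#' @export
step_nvt_langevin <- function(state, calculator, dt, temperature,
                              friction = 0.01) {
  if (temperature <= 0) stop("temperature must be > 0")
  state <- .ensure_forces(state, calculator)
  m <- state$masses * ff_constants$amu_ev_fs_ang
  n <- length(m)
  v <- state$velocities + 0.5 * dt * state$forces / m          # B
  state$system$positions <- state$system$positions + 0.5 * dt * v  # A
  if (friction > 0) {                                           # O
    c1 <- exp(-friction * dt)
    c2 <- sqrt((1 - c1^2) * ff_constants$kb_ev * temperature / m)
    v <- c1 * v + c2 * matrix(stats::rnorm(3 * n), n, 3)
  }
  state$system$positions <- state$system$positions + 0.5 * dt * v  # A
  out <- calculator(state$system)
  state$velocities <- v + 0.5 * dt * out$forces / m             # B
  state$forces <- out$forces
  state$energy <- out$energy
  state$time <- state$time + dt
  state
}

#' One isotropic NPT step (Langevin thermostat + Berendsen barostat)
#'
#' Performs a Langevin NVT step, then rescales the cell and coordinates
#' isotropically toward the target pressure with a Berendsen-style factor
#' `mu = (1 - dt/tau_p * kappa * (P_target - P))^(1/3)`. The instantaneous
#' pressure combines the ideal (kinetic) part with the pair virial supplied by
#' the calculator (`virial` element, eV); calculators without a virial get one
#' from a symmetric finite difference of the energy with respect to volume.
#' With `tau_p -> Inf` the update reduces to NVT.
#'
#' @param state An [md_state()] with a periodic system.
#' @param calculator Calculator closure.
#' @param dt Time step (fs).
#' @param temperature Target temperature (K).
#' @param pressure Target pressure (bar).
#' @param friction Langevin friction (1/fs).
#' @param tau_p Barostat coupling time (fs).
#' @param kappa Assumed compressibility (1/bar; water-like default 4.5e-5).
#' @return Advanced state.
#' @export
step_npt_isotropic <- function(state, calculator, dt, temperature, pressure,
                               friction = 0.01, tau_p = 1000, kappa = 4.5e-5) {
  if (!any(state$system$pbc)) stop("NPT requires a periodic system")
  state <- step_nvt_langevin(state, calculator, dt, temperature, friction)
  p_inst <- instantaneous_pressure(state, calculator)
  if (is.finite(tau_p)) {
    mu <- (1 - dt / tau_p * kappa * (pressure - p_inst))^(1 / 3)
    state$system$cell <- state$system$cell * mu
    state$system$positions <- state$system$positions * mu
    state$forces <- NULL   # geometry changed
  }
  state$pressure <- p_inst
  state
}

#' Instantaneous pressure (bar) of a periodic state
#'
#' `P = (2 KE + W) / (3 V)` with the virial `W = -3 V dE/dV` from the
#' calculator or from a central finite difference over an isotropic volume
#' scaling.
#'
#' @param state An [md_state()].
#' @param calculator Calculator closure.
#' @param dlnv Relative volume perturbation for the finite difference.
#' @return Pressure in bar.
#' @export
instantaneous_pressure <- function(state, calculator, dlnv = 1e-4) {
  v <- abs(det(state$system$cell))
  ke <- kinetic_temperature(state)$kinetic
  out <- calculator(state$system)
  w <- out$virial
  if (is.null(w)) {
    scale_sys <- function(s, f) {
      s$cell <- s$cell * f
      s$positions <- s$positions * f
      s
    }
    ep <- calculator(scale_sys(state$system, (1 + dlnv)^(1 / 3)))$energy
    em <- calculator(scale_sys(state$system, (1 - dlnv)^(1 / 3)))$energy
    dedv <- (ep - em) / (2 * v * dlnv)
    w <- -3 * v * dedv
  }
  (2 * ke + w) / (3 * v) * ff_constants$evang3_bar
}

#' Run molecular dynamics
#'
#' Drives one of the integrators for `n_steps`, optionally recording frames
#' every `stride` steps, and logs step, energies, temperature (and pressure
#' for NPT).
#'
#' @param state Initial [md_state()].
#' @param calculator Calculator closure.
#' @param n_steps Number of steps.
#' @param dt Time step (fs; default 1).
#' @param ensemble One of `"nve"`, `"nvt"`, `"npt"`.
#' @param temperature,pressure Targets for nvt/npt.
#' @param friction,tau_p,kappa Thermostat/barostat parameters.
#' @param stride Frame-recording stride (0 = no frames).
#' @param seed Optional seed controlling the thermostat noise.
#' @return List with final `state`, `trajectory` (a [trajectory()] or NULL)
#'   and `log` (data.frame).
#' @export
run_md <- function(state, calculator, n_steps, dt = 1, ensemble = "nve",
                   temperature = 300, pressure = 1, friction = 0.01,
                   tau_p = 1000, kappa = 4.5e-5, stride = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ensemble <- match.arg(ensemble, c("nve", "nvt", "npt"))
  frames <- list(); vels <- list()
  log <- vector("list", n_steps)
  for (k in seq_len(n_steps)) {
    state <- switch(ensemble,
      nve = step_nve(state, calculator, dt),
      nvt = step_nvt_langevin(state, calculator, dt, temperature, friction),
      npt = step_npt_isotropic(state, calculator, dt, temperature, pressure,
                               friction, tau_p, kappa))
    kt <- kinetic_temperature(state)
    log[[k]] <- data.frame(step = k, time = state$time,
                           e_pot = state$energy, e_kin = kt$kinetic,
                           e_tot = state$energy + kt$kinetic,
                           temperature = kt$temperature,
                           pressure = if (ensemble == "npt") state$pressure else NA,
                           volume = if (!is.null(state$system$cell))
                             abs(det(state$system$cell)) else NA)
    if (stride > 0 && k %% stride == 0) {
      frames[[length(frames) + 1L]] <- state$system
      vels[[length(vels) + 1L]] <- state$velocities
    }
  }
  traj <- if (length(frames)) {
    trajectory(frames, dt * stride, velocities = vels)
  } else NULL
  list(state = state, trajectory = traj, log = do.call(rbind, log))
}

#' Relax a structure to a local minimum
#'
#' Backtracking steepest descent on the calculator's energy; the standard
#' preparation step before measuring conservation or sampling dynamics.
#'
#' @param system An [atomic_system()].
#' @param calculator Calculator closure.
#' @param max_steps Iteration cap.
#' @param fmax Convergence threshold on the maximum force component
#'   (eV/Angstrom).
#' @param step0 Initial step length (Angstrom).
#' @return List with `system` (relaxed), `energy`, `fmax`, `converged`.
#' @export
relax_structure <- function(system, calculator, max_steps = 500, fmax = 0.05,
                            step0 = 0.02) {
  out <- calculator(system)
  alpha <- step0
  for (k in seq_len(max_steps)) {
    if (max(abs(out$forces)) < fmax) break
    trial <- system
    d <- out$forces / max(1, max(abs(out$forces)))
    trial$positions <- system$positions + alpha * d
    o2 <- calculator(trial)
    if (o2$energy < out$energy) {
      system <- trial; out <- o2; alpha <- min(alpha * 1.2, 0.2)
    } else {
      alpha <- alpha / 2
    }
  }
  list(system = system, energy = out$energy, fmax = max(abs(out$forces)),
       converged = max(abs(out$forces)) < fmax)
}

#' Toy harmonic-bond calculator
#'
#' `E = 0.5 k sum_bonds (r - r0)^2` over an explicit bond list; handy for
#' integrator conservation tests.
#'
#' @param bonds 2-column integer matrix of bonded pairs.
#' @param k Spring constant (eV/Angstrom^2).
#' @param r0 Equilibrium length (Angstrom).
#' @return Calculator closure.
#' @export
harmonic_calculator <- function(bonds, k = 30, r0 = 1.0) {
  bonds <- as.matrix(bonds)
  function(system) {
    n <- n_atoms(system)
    f <- matrix(0, n, 3)
    e <- 0
    for (b in seq_len(nrow(bonds))) {
      i <- bonds[b, 1]; j <- bonds[b, 2]
      dr <- system$positions[j, ] - system$positions[i, ]
      r <- sqrt(sum(dr^2))
      e <- e + 0.5 * k * (r - r0)^2
      fij <- -k * (r - r0) * dr / r
      f[j, ] <- f[j, ] + fij
      f[i, ] <- f[i, ] - fij
    }
    list(energy = e, forces = f)
  }
}

#' Toy Lennard-Jones calculator (periodic-aware, with analytic virial)
#'
#' Truncated-and-shifted 12-6 potential for barostat and liquid-structure
#' tests.
#'
#' @param epsilon Well depth (eV).
#' @param sigma LJ diameter (Angstrom).
#' @param cutoff Cutoff (Angstrom).
#' @return Calculator closure returning energy, forces and virial.
#' @export
lj_calculator <- function(epsilon = 0.01, sigma = 3.0, cutoff = 7.5) {
  function(system) {
    nbr <- build_neighbor_table(system, cutoff)
    n <- n_atoms(system)
    if (!length(nbr$i)) {
      return(list(energy = 0, forces = matrix(0, n, 3), virial = 0))
    }
    sr6 <- (sigma / nbr$d)^6
    sc6 <- (sigma / cutoff)^6
    e <- 4 * epsilon * (sr6^2 - sr6) - 4 * epsilon * (sc6^2 - sc6)
    dedr <- 4 * epsilon * (-12 * sr6^2 + 6 * sr6) / nbr$d
    list(energy = sum(e),
         forces = .pair_forces(nbr, dedr, n),
         virial = -sum(dedr * nbr$d))
  }
}
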