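#' Force-field configuration
#'
#' Collects the hyperparameters of the four energy terms and per-term toggles
#' (useful for ablation: the coupling analysis requires isolating terms).
#'
#' @param model A [model_spec()].
#' @param zbl A [zbl_config()].
#' @param gamma Dispersion damping strength.
#' @param c8_ratio QDO C8 scaling constant.
#' @param sigma Electrostatic damping width (Angstrom).
#' @param cutoff_lr Long-range cutoff for electrostatics and dispersion
#'   (Angstrom; 12 by default).
#' @param terms Named logical vector enabling `zbl`, `semilocal`,
#'   `electrostatics`, `dispersion`.
#' @return An object of class `ff_config`.
#' @export
ff_config <- function(model = model_spec(), zbl = zbl_config(),
                      gamma = 1.0, c8_ratio = 0.48, sigma = 1.0,
                      cutoff_lr = 12.0,
                      terms = c(zbl = TRUE, semilocal = TRUE,
                                electrostatics = TRUE, dispersion = TRUE)) {
  structure(list(model = model, zbl = zbl, gamma = gamma, c8_ratio = c8_ratio,
                 sigma = sigma, cutoff_lr = cutoff_lr, terms = terms),
            class = "ff_config")
}

#' Evaluate the composed potential
#'
#' Computes `E_pot = E_zbl + E_semilocal + E_elec + E_disp` together with
#' forces that are the exact negative gradient of the composed scalar,
#' including the dependence of the predicted charges and Hirshfeld ratios on
#' atomic positions (reverse-mode chain rule through the semilocal model).
#'
#' @param system An [atomic_system()].
#' @param model A [semilocal_model()] (may be `NULL` if all model-dependent
#'   terms are disabled).
#' @param config An [ff_config()].
#' @return An object of class `energy_breakdown`: per-term energies (eV),
#'   `e_pot`, `forces` (N x 3, eV/Angstrom), plus the `predictions` and
#'   projected `charges` used.
#' @export
evaluate_potential <- function(system, model, config = ff_config()) {
  n <- n_atoms(system)
  terms <- config$terms
  need_model <- isTRUE(terms[["semilocal"]]) || isTRUE(terms[["electrostatics"]]) ||
    isTRUE(terms[["dispersion"]])
  cutoff_local <- max(config$model$r_local, config$zbl$r_outer)
  nbr_local <- build_neighbor_table(system, cutoff_local)
  # model neighbors restricted to r_local
  keep <- nbr_local$d <= config$model$r_local
  nbr_model <- structure(list(i = nbr_local$i[keep], j = nbr_local$j[keep],
                              rij = nbr_local$rij[keep, , drop = FALSE],
                              d = nbr_local$d[keep],
                              shifts = nbr_local$shifts[keep, , drop = FALSE],
                              cutoff = config$model$r_local),
                         class = "neighbor_table")
  forces <- matrix(0, n, 3)
  e_zbl <- e_sl <- e_elec <- e_disp <- 0
  pred <- NULL; charges <- NULL

  if (isTRUE(terms[["zbl"]])) {
    z <- zbl_energy(system, nbr_local, config$zbl)
    e_zbl <- z$energy
    forces <- forces + z$forces
  }

  if (need_model) {
    if (is.null(model)) stop("a semilocal_model is required for the enabled terms")
    pred <- predict_atomic(model, system, nbr_model)
    cache <- attr(pred, "cache")
    zh <- attr(pred, "zh")
    gE <- numeric(n); gq_raw <- numeric(n); gzh <- numeric(n)
    if (isTRUE(terms[["semilocal"]])) {
      e_sl <- semilocal_energy(pred)
      gE <- rep(1, n)
    }
    nbr_lr <- build_neighbor_table(system, config$cutoff_lr)
    if (isTRUE(terms[["electrostatics"]])) {
      charges <- project_charges(pred$q_raw, system$charge, config$sigma)
      el <- electrostatic_energy(system, nbr_lr, charges)
      e_elec <- el$energy
      forces <- forces + el$forces
      # chain through the charge projection: dE/dq_raw = (I - J/N) dE/dq
      gq_raw <- el$dE_dq - mean(el$dE_dq)
    }
    if (isTRUE(terms[["dispersion"]])) {
      dp <- dispersion_energy(system, nbr_lr, pred$h, config$gamma,
                              config$c8_ratio)
      e_disp <- dp$energy
      forces <- forces + dp$forces
      gzh <- dp$dE_dh * .sigmoid(zh)   # softplus chain
    }
    cot_x <- outer(gE, model$params$wE) + outer(gq_raw, model$params$wq) +
      outer(gzh, model$params$wh)
    grad_model <- .model_vjp(model, system, nbr_model, cache, cot_x)
    forces <- forces - grad_model
  }

  structure(list(e_zbl = e_zbl, e_semilocal = e_sl, e_elec = e_elec,
                 e_disp = e_disp, e_pot = e_zbl + e_sl + e_elec + e_disp,
                 forces = forces, predictions = pred, charges = charges),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("<energy_breakdown> (eV)\n")
  cat(sprintf("  E_zbl       %12.6f\n", x$e_zbl))
  cat(sprintf("  E_semilocal %12.6f\n", x$e_semilocal))
  cat(sprintf("  E_elec      %12.6f\n", x$e_elec))
  cat(sprintf("  E_disp      %12.6f\n", x$e_disp))
  cat(sprintf("  E_pot       %12.6f\n", x$e_pot))
  cat(sprintf("  max |F|     %12.6f eV/Angstrom\n", max(abs(x$forces))))
  invisible(x)
}

#' Calculator closure for the MD engine
#'
#' Wraps [evaluate_potential()] into the `function(system) -> list(energy,
#' forces)` interface the integrators consume.
#'
#' @param model A [semilocal_model()].
#' @param config An [ff_config()].
#' @return A calculator function.
#' @export
composer_calculator <- function(model, config = ff_config()) {
  force(model); force(config)
  function(system) {
    br <- evaluate_potential(system, model, config)
    list(energy = br$e_pot, forces = br$forces)
  }
}
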