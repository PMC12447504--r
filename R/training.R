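#' Loss trade-off weights
#'
#' @param lambda_F,lambda_mu,lambda_h Non-negative trade-off weights for the
#'   force, dipole and Hirshfeld loss terms. Defaults (1, 0.01, 0.01) weight
#'   forces dominantly; all are config-exposed.
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(lambda_F = 1, lambda_mu = 0.01, lambda_h = 0.01) {
  w <- c(lambda_F = lambda_F, lambda_mu = lambda_mu, lambda_h = lambda_h)
  if (any(w < 0)) stop("loss weights must be >= 0")
  structure(as.list(w), class = "loss_weights")
}

#' Training batch of labeled structures
#'
#' @param systems List of [atomic_system()] objects.
#' @param forces Optional list of N_b x 3 reference force matrices (eV/A).
#' @param dipoles Optional list of length-3 reference dipoles (e Angstrom).
#' @param hirshfeld Optional list of reference Hirshfeld-ratio vectors.
#' @return An object of class `training_batch`.
#' @export
training_batch <- function(systems, forces = NULL, dipoles = NULL,
                           hirshfeld = NULL) {
  B <- length(systems)
  chk <- function(ref, dim_ok, what) {
    if (is.null(ref)) return(invisible())
    if (length(ref) != B) stop(what, " must have one entry per structure")
    for (b in seq_len(B)) {
      if (!all(is.finite(unlist(ref[[b]])))) stop(what, " must be finite")
      if (!dim_ok(ref[[b]], systems[[b]])) stop(what, " has inconsistent shape")
    }
  }
  chk(forces, function(f, s) is.matrix(f) && all(dim(f) == c(n_atoms(s), 3)),
      "forces")
  chk(dipoles, function(m, s) length(m) == 3L, "dipoles")
  chk(hirshfeld, function(h, s) length(h) == n_atoms(s), "hirshfeld")
  structure(list(systems = systems, forces = forces, dipoles = dipoles,
                 hirshfeld = hirshfeld), class = "training_batch")
}

#' Combined force / dipole / Hirshfeld loss
#'
#' `L = lambda_F/B sum_b (1/N_b) sum_i ||F_true - F_pred||^2
#'    + lambda_mu/B sum_b ||mu_true - mu_pred||^2
#'    + lambda_h/B sum_b (1/N_b) sum_i (h_true - h_pred)^2`.
#' The force term is per-atom-averaged within each structure; the dipole term
#' is not atom-normalized.
#'
#' @param batch A [training_batch()] with references for every channel whose
#'   weight is nonzero.
#' @param predictions List (length B) of lists with elements `forces`,
#'   `dipole`, `h` as needed.
#' @param weights A [loss_weights()].
#' @return List with `loss` and the per-term breakdown
#'   (`force`, `dipole`, `hirshfeld`, already weighted).
#' @export
combined_loss <- function(batch, predictions, weights = loss_weights()) {
  B <- length(batch$systems)
  lf <- lm <- lh <- 0
  if (weights$lambda_F > 0) {
    if (is.null(batch$forces)) stop("lambda_F > 0 but batch carries no reference forces")
    for (b in seq_len(B)) {
      nb <- n_atoms(batch$systems[[b]])
      lf <- lf + sum((batch$forces[[b]] - predictions[[b]]$forces)^2) / nb
    }
    lf <- weights$lambda_F * lf / B
  }
  if (weights$lambda_mu > 0) {
    if (is.null(batch$dipoles)) stop("lambda_mu > 0 but batch carries no reference dipoles")
    for (b in seq_len(B)) {
      lm <- lm + sum((batch$dipoles[[b]] - predictions[[b]]$dipole)^2)
    }
    lm <- weights$lambda_mu * lm / B
  }
  if (weights$lambda_h > 0) {
    if (is.null(batch$hirshfeld)) stop("lambda_h > 0 but batch carries no reference Hirshfeld ratios")
    for (b in seq_len(B)) {
      nb <- n_atoms(batch$systems[[b]])
      lh <- lh + sum((batch$hirshfeld[[b]] - predictions[[b]]$h)^2) / nb
    }
    lh <- weights$lambda_h * lh / B
  }
  list(loss = lf + lm + lh, force = lf, dipole = lm, hirshfeld = lh)
}

# Precompute, per structure, everything the head-space losses need:
# final features X, element slots, the feature->force maps G (3N x F), the
# base force (readout energy weights zeroed), and the dipole design matrices.
.train_precompute <- function(model, batch, config, weights) {
  lapply(batch$systems, function(sys) {
    n <- n_atoms(sys)
    pc <- list(n = n)
    nbr <- build_neighbor_table(sys, model$spec$r_local)
    cache <- .model_forward(model, sys, nbr)
    pc$X <- cache$x_out
    pc$zslot <- cache$zslot
    if (weights$lambda_F > 0) {
      Fdim <- model$spec$features
      G <- matrix(0, 3 * n, Fdim)
      for (f in seq_len(Fdim)) {
        cot <- matrix(0, n, Fdim); cot[, f] <- 1
        G[, f] <- as.numeric(.model_vjp(model, sys, nbr, cache, cot))
      }
      pc$G <- G
      m0 <- model
      m0$params$wE <- rep(0, model$spec$features)
      pc$F_base <- as.numeric(evaluate_potential(sys, m0, config)$forces)
    }
    if (weights$lambda_mu > 0) {
      origin <- .charge_origin(sys)
      D <- sys$positions - matrix(origin, n, 3, byrow = TRUE)
      PX <- pc$X - matrix(colMeans(pc$X), n, model$spec$features, byrow = TRUE)
      pc$Mq <- crossprod(D, PX)                       # 3 x F
      Zm <- outer(pc$zslot, seq_along(supported_elements()), "==") * 1
      PZ <- Zm - matrix(colMeans(Zm), n, ncol(Zm), byrow = TRUE)
      pc$Mb <- crossprod(D, PZ)                       # 3 x nel
      # projected total-charge part: q gains (Q - sum raw)/N uniformly; with
      # centered designs above, mu = Mq wq + Mb bq + D^T (Q/N)
      pc$mu0 <- as.numeric(crossprod(D, rep(sys$charge / n, n)))
    }
    pc
  })
}

#' Train the model readouts on a labeled batch
#'
#' Optimizes the readout heads (energy weights for the force loss, charge head
#' for the dipole loss, Hirshfeld head for the h loss) with Adam and an
#' exponential learning-rate decay, holding the seeded message-passing trunk
#' fixed. Because the trunk is fixed, the force and dipole losses are exactly
#' quadratic in their head weights and the gradients are analytic; training is
#' deterministic (full batch, no stochasticity). Forces constrain the energy
#' head only up to a constant per element (absolute energies are not
#' identifiable from forces; relative energies of like compositions are).
#'
#' @param model A [semilocal_model()].
#' @param batch A [training_batch()] with the channels required by `weights`.
#' @param weights A [loss_weights()].
#' @param config An [ff_config()] used to evaluate the composed forces (its
#'   `model` spec should match `model$spec`).
#' @param n_steps Number of Adam steps (0 returns the model unchanged).
#' @param lr,lr_decay,beta1,beta2,eps Adam hyperparameters; the learning rate
#'   at step k is `lr * lr_decay^k`.
#' @return List with `model` (updated), `history` (data.frame of per-step
#'   losses) and `final_loss`.
#' @export
train_model <- function(model, batch, weights = loss_weights(),
                        config = ff_config(model = model$spec),
                        n_steps = 200, lr = 0.05, lr_decay = 0.995,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (n_steps == 0) {
    return(list(model = model, history = data.frame(), final_loss = NA_real_))
  }
  pre <- .train_precompute(model, batch, config, weights)
  B <- length(batch$systems)
  nel <- length(supported_elements())
  Fdim <- model$spec$features
  theta <- c(if (weights$lambda_F > 0) model$params$wE,
             if (weights$lambda_mu > 0) c(model$params$wq, model$params$bq),
             if (weights$lambda_h > 0) c(model$params$wh, model$params$bh))
  unpack <- function(th) {
    out <- list(); k <- 0
    if (weights$lambda_F > 0) { out$wE <- th[k + seq_len(Fdim)]; k <- k + Fdim }
    if (weights$lambda_mu > 0) {
      out$wq <- th[k + seq_len(Fdim)]; k <- k + Fdim
      out$bq <- th[k + seq_len(nel)]; k <- k + nel
    }
    if (weights$lambda_h > 0) {
      out$wh <- th[k + seq_len(Fdim)]; k <- k + Fdim
      out$bh <- th[k + seq_len(nel)]; k <- k + nel
    }
    out
  }
  loss_grad <- function(th) {
    hp <- unpack(th)
    L <- 0; g <- numeric(length(th))
    for (b in seq_len(B)) {
      pc <- pre[[b]]
      k <- 0
      if (weights$lambda_F > 0) {
        fpred <- pc$F_base - as.numeric(pc$G %*% hp$wE)
        res <- fpred - as.numeric(batch$forces[[b]])
        L <- L + weights$lambda_F / pc$n * sum(res^2) / B
        g[k + seq_len(Fdim)] <- g[k + seq_len(Fdim)] -
          2 * weights$lambda_F / (pc$n * B) * as.numeric(crossprod(pc$G, res))
        k <- k + Fdim
      }
      if (weights$lambda_mu > 0) {
        mu <- as.numeric(pc$Mq %*% hp$wq) + as.numeric(pc$Mb %*% hp$bq) + pc$mu0
        res <- mu - batch$dipoles[[b]]
        L <- L + weights$lambda_mu * sum(res^2) / B
        g[k + seq_len(Fdim)] <- g[k + seq_len(Fdim)] +
          2 * weights$lambda_mu / B * as.numeric(crossprod(pc$Mq, res))
        g[k + Fdim + seq_len(nel)] <- g[k + Fdim + seq_len(nel)] +
          2 * weights$lambda_mu / B * as.numeric(crossprod(pc$Mb, res))
        k <- k + Fdim + nel
      }
      if (weights$lambda_h > 0) {
        zh <- as.numeric(pc$X %*% hp$wh) + hp$bh[pc$zslot]
        hpred <- .softplus(zh)
        res <- hpred - batch$hirshfeld[[b]]
        w <- 2 * weights$lambda_h / (pc$n * B) * res * .sigmoid(zh)
        L <- L + weights$lambda_h / pc$n * sum(res^2) / B
        g[k + seq_len(Fdim)] <- g[k + seq_len(Fdim)] +
          as.numeric(crossprod(pc$X, w))
        # per-element bias gradient (dense, zeros for absent elements)
        gb <- numeric(nel)
        agg <- rowsum(w, pc$zslot)
        gb[as.integer(rownames(agg))] <- agg[, 1]
        g[k + Fdim + seq_len(nel)] <- g[k + Fdim + seq_len(nel)] + gb
        k <- k + Fdim + nel
      }
    }
    list(L = L, g = g)
  }
  m <- v <- numeric(length(theta))
  hist <- numeric(n_steps)
  for (step in seq_len(n_steps)) {
    lg <- loss_grad(theta)
    if (!is.finite(lg$L)) {
      stop("training diverged (non-finite loss) at step ", step,
           "; last finite loss ", if (step > 1) hist[step - 1] else NA)
    }
    hist[step] <- lg$L
    m <- beta1 * m + (1 - beta1) * lg$g
    v <- beta2 * v + (1 - beta2) * lg$g^2
    mh <- m / (1 - beta1^step)
    vh <- v / (1 - beta2^step)
    theta <- theta - lr * lr_decay^step * mh / (sqrt(vh) + eps)
  }
  hp <- unpack(theta)
  for (nm in names(hp)) model$params[[nm]] <- hp[[nm]]
  list(model = model,
       history = data.frame(step = seq_len(n_steps), loss = hist),
       final_loss = hist[n_steps])
}

#' Calibrate the damping hyperparameters on dimer scans
#'
#' Grid search for the (gamma, sigma) pair minimizing the mean-squared
#' interaction-energy error over a set of dimer scans,
#' `E_int(s) = E(dimer at s) - E(monomer 1) - E(monomer 2)`. Ties are broken
#' deterministically toward the smallest gamma, then the smallest sigma.
#'
#' @param scans List of scans; each scan is a list with `dimers` (list of
#'   [atomic_system()] at >= 2 separations), `monomer1`, `monomer2`.
#' @param references List of numeric vectors of reference interaction
#'   energies (eV), aligned with each scan's `dimers`.
#' @param model A [semilocal_model()].
#' @param config Base [ff_config()]; its gamma/sigma are overridden.
#' @param gamma_grid,sigma_grid Candidate values.
#' @return List with `gamma`, `sigma`, `mse`, and the full `grid` data.frame.
#' @export
calibrate_damping <- function(scans, references, model, config = ff_config(),
                              gamma_grid = seq(0.6, 1.6, by = 0.2),
                              sigma_grid = seq(0.6, 1.6, by = 0.2)) {
  if (!length(scans)) stop("empty scan set")
  for (sc in scans) {
    if (length(sc$dimers) < 2L) stop("each dimer scan needs >= 2 separations")
  }
  grid <- expand.grid(sigma = sigma_grid, gamma = gamma_grid)[, c("gamma", "sigma")]
  grid$mse <- NA_real_
  for (k in seq_len(nrow(grid))) {
    cfg <- config
    cfg$gamma <- grid$gamma[k]
    cfg$sigma <- grid$sigma[k]
    sq <- 0; np <- 0
    for (s in seq_along(scans)) {
      sc <- scans[[s]]
      e1 <- evaluate_potential(sc$monomer1, model, cfg)$e_pot
      e2 <- evaluate_potential(sc$monomer2, model, cfg)$e_pot
      for (p in seq_along(sc$dimers)) {
        eint <- evaluate_potential(sc$dimers[[p]], model, cfg)$e_pot - e1 - e2
        sq <- sq + (eint - references[[s]][p])^2
        np <- np + 1
      }
    }
    grid$mse[k] <- sq / np
  }
  # deterministic tie-break: smallest gamma, then smallest sigma
  ord <- order(grid$mse, grid$gamma, grid$sigma)
  best <- grid[ord[1], ]
  list(gamma = best$gamma, sigma = best$sigma, mse = best$mse, grid = grid)
}
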