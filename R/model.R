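#' Semilocal model specification
#'
#' Architecture of the pluggable atomic-property predictor: a
#' rotation-invariant message-passing network on radial-basis edge features.
#' Atomic energies E_i, raw partial charges q_i and Hirshfeld ratios h_i are
#' read out from the final atom features. The receptive field is bounded by
#' `r_local * layers` (see [effective_cutoff()]). The default mirrors the
#' production-scale configuration (128 features, 3 interaction layers, 4.5
#' Angstrom local cutoff); tests use a reduced model.
#'
#' @param r_local Local cutoff in Angstrom (> 0).
#' @param layers Number of message-passing layers T (>= 1).
#' @param features Atom feature width.
#' @param n_basis Number of radial basis functions per edge.
#' @param seed Integer seed for parameter initialization (bit-reproducible).
#' @return An object of class `local_model_spec`.
#' @export
model_spec <- function(r_local = 4.5, layers = 3L, features = 128L,
                       n_basis = 8L, seed = 1L) {
  if (r_local <= 0) stop("r_local must be > 0")
  if (layers < 1L) stop("layers must be >= 1")
  structure(list(r_local = r_local, layers = as.integer(layers),
                 features = as.integer(features),
                 n_basis = as.integer(n_basis), seed = as.integer(seed)),
            class = "local_model_spec")
}

#' Effective (receptive-field) cutoff of the semilocal model
#'
#' Message passing propagates information at most one local cutoff per update
#' step, so the representable interaction range is upper bounded by
#' `r_local * layers`. With the default spec (4.5 Angstrom, 3 layers) this is
#' 13.5 Angstrom.
#'
#' @param spec A [model_spec()].
#' @return The effective cutoff in Angstrom.
#' @export
effective_cutoff <- function(spec) spec$r_local * spec$layers

#' Construct (initialize) a semilocal model
#'
#' Draws all weights from the spec's seed; the global RNG state is left
#' untouched. Identical specs yield bit-identical parameters.
#'
#' @param spec A [model_spec()].
#' @return An object of class `semilocal_model` with elements `spec` and
#'   `params`.
#' @export
semilocal_model <- function(spec = model_spec()) {
  F <- spec$features; K <- spec$n_basis; T <- spec$layers
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  rn <- function(n, m, sd) matrix(stats::rnorm(n * m, sd = sd), n, m)
  nel <- length(supported_elements())
  params <- list(
    emb = rn(nel, F, 1.0),
    wQ = stats::rnorm(F, sd = 0.5),
    wS = stats::rnorm(F, sd = 0.5),
    layers = lapply(seq_len(T), function(t) {
      list(A = rn(F, F, 1 / sqrt(F)),
           B = rn(K, F, 1 / sqrt(K)),
           U = rn(F, F, 1 / sqrt(F)))
    }),
    wE = stats::rnorm(F, sd = 0.3 / sqrt(F)), bE = stats::rnorm(nel, sd = 0.1),
    wq = stats::rnorm(F, sd = 0.1 / sqrt(F)), bq = rep(0, nel),
    wh = stats::rnorm(F, sd = 0.2 / sqrt(F)),
    bh = rep(log(exp(0.8) - 1), nel)
  )
  structure(list(spec = spec, params = params), class = "semilocal_model")
}

#' @export
print.semilocal_model <- function(x, ...) {
  cat("<semilocal_model> ", x$spec$features, " features, ", x$spec$layers,
      " layers, r_local ", x$spec$r_local, " Angstrom (effective cutoff ",
      effective_cutoff(x$spec), " Angstrom)\n", sep = "")
  invisible(x)
}

# radial basis x smooth cutoff envelope, with derivative; r: vector
.edge_features <- function(r, rc, K) {
  mu <- seq(0, rc, length.out = K)
  w <- rc / K
  g <- exp(-(outer(r, mu, "-"))^2 / (2 * w^2))
  dg <- -g * outer(r, mu, "-") / w^2
  env <- ifelse(r < rc, 0.5 * (1 + cos(pi * r / rc)), 0)
  denv <- ifelse(r < rc, -0.5 * pi / rc * sin(pi * r / rc), 0)
  list(phi = g * env, dphi = dg * env + g * denv)
}

# forward pass; returns final features and a cache for the reverse pass
.model_forward <- function(model, system, neighbors) {
  spec <- model$spec; p <- model$params
  n <- n_atoms(system); F <- spec$features
  zslot <- match(system$numbers, supported_elements())
  x <- p$emb[zslot, , drop = FALSE] +
    outer(rep(system$charge / n, n), p$wQ) +
    outer(rep(system$spin / n, n), p$wS)
  src <- c(neighbors$i, neighbors$j)
  dst <- c(neighbors$j, neighbors$i)
  d <- c(neighbors$d, neighbors$d)
  ef <- .edge_features(d, spec$r_local, spec$n_basis)
  cache <- list(zslot = zslot, src = src, dst = dst, d = d,
                phi = ef$phi, dphi = ef$dphi, layers = vector("list", spec$layers))
  for (t in seq_len(spec$layers)) {
    L <- p$layers[[t]]
    xa <- x %*% L$A
    pb <- ef$phi %*% L$B
    msg <- matrix(0, n, F)
    if (length(src)) {
      contrib <- pb * xa[src, , drop = FALSE]
      s <- rowsum(contrib, group = dst)
      msg[as.integer(rownames(s)), ] <- s
    }
    u <- tanh(msg)
    cache$layers[[t]] <- list(x_in = x, xa = xa, pb = pb, u = u)
    x <- x + u %*% L$U
  }
  cache$x_out <- x
  cache
}

# reverse pass: cotangent on final features -> gradient wrt positions (N x 3)
.model_vjp <- function(model, system, neighbors, cache, cot_x) {
  spec <- model$spec; p <- model$params
  n <- n_atoms(system); F <- spec$features
  src <- cache$src; dst <- cache$dst
  nE <- length(src)
  phibar <- matrix(0, nE, spec$n_basis)
  xbar <- cot_x
  for (t in rev(seq_len(spec$layers))) {
    L <- p$layers[[t]]; cl <- cache$layers[[t]]
    ubar <- xbar %*% t(L$U)
    mbar <- ubar * (1 - cl$u^2)
    if (nE) {
      mb_e <- mbar[dst, , drop = FALSE]
      # msg contribution per edge: pb_e * xa_src
      phibar <- phibar + (mb_e * cl$xa[src, , drop = FALSE]) %*% t(L$B)
      xab <- mb_e * cl$pb
      s <- rowsum(xab, group = src)
      xabar <- matrix(0, n, F)
      xabar[as.integer(rownames(s)), ] <- s
      xbar <- xbar + xabar %*% t(L$A)
    }
  }
  grad <- matrix(0, n, 3)
  if (nE) {
    dEdr <- rowSums(phibar * cache$dphi)
    # minimum-image displacement of each directed edge, from the half list
    unit <- rbind(neighbors$rij, -neighbors$rij) / cache$d
    contrib <- unit * dEdr
    for (k in 1:3) {
      grad[, k] <- grad[, k] + tapply2(dst, contrib[, k], n) -
        tapply2(src, contrib[, k], n)
    }
  }
  grad
}

# readout heads from final features
.model_heads <- function(params, cache) {
  x <- cache$x_out; zslot <- cache$zslot
  zE <- drop(x %*% params$wE) + params$bE[zslot]
  zq <- drop(x %*% params$wq) + params$bq[zslot]
  zh <- drop(x %*% params$wh) + params$bh[zslot]
  list(E = zE, q_raw = zq, h = .softplus(zh), zh = zh)
}

#' Predict atomic properties
#'
#' Runs the semilocal model on a structure and returns per-atom energies E_i
#' (eV), raw partial charges q_i (e; project with [project_charges()] before
#' use) and Hirshfeld ratios h_i (strictly positive through a softplus output
#' transform). Outputs are invariant to rigid rotations/translations,
#' equivariant under atom permutation, and depend on the total charge and spin
#' through normalized global features.
#'
#' @param model A [semilocal_model()].
#' @param system An [atomic_system()].
#' @param neighbors Optional neighbor table at `r_local` (built if missing).
#' @return An object of class `atomic_predictions`: list with `E`, `q_raw`,
#'   `h`; the forward cache is attached for internal reuse.
#' @export
predict_atomic <- function(model, system, neighbors = NULL) {
  if (is.null(neighbors)) {
    neighbors <- build_neighbor_table(system, model$spec$r_local)
  }
  cache <- .model_forward(model, system, neighbors)
  heads <- .model_heads(model$params, cache)
  structure(list(E = heads$E, q_raw = heads$q_raw, h = heads$h),
            class = "atomic_predictions",
            cache = cache, neighbors = neighbors, zh = heads$zh)
}

#' Semilocal energy: sum of atomic energies
#'
#' @param predictions An `atomic_predictions` object (or any list with `E`).
#' @return Total semilocal energy in eV.
#' @export
semilocal_energy <- function(predictions) sum(predictions$E)
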