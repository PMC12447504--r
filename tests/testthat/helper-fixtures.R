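# shared test fixtures and independent oracles

# reduced model used throughout the tests (fast, CPU-friendly)
test_spec <- function(seed = 3, layers = 2L) {
  model_spec(r_local = 4.5, layers = layers, features = 16L, n_basis = 8L,
             seed = seed)
}
test_model <- function(seed = 3, layers = 2L) semilocal_model(test_spec(seed, layers))
test_config <- function(spec = test_spec(), ...) ff_config(model = spec, ...)

# random well-separated molecular blob drawn from the supported elements
mk_random_system <- function(n = 10, seed = 1, box = 5.5, min_d = 1.1,
                             charge = 0) {
  set.seed(seed)
  repeat {
    pos <- matrix(stats::runif(n * 3, 0, box), n, 3)
    if (min(dist(pos)) > min_d) break
  }
  atomic_system(pos, sample(c(1L, 6L, 7L, 8L, 16L), n, replace = TRUE),
                charge = charge)
}

# central finite-difference forces of any scalar energy function
fd_forces <- function(system, energy_fn, h = 1e-4) {
  n <- n_atoms(system)
  out <- matrix(0, n, 3)
  for (a in seq_len(n)) for (k in 1:3) {
    sp <- system; sp$positions[a, k] <- sp$positions[a, k] + h
    sm <- system; sm$positions[a, k] <- sm$positions[a, k] - h
    out[a, k] <- -(energy_fn(sp) - energy_fn(sm)) / (2 * h)
  }
  out
}

# brute-force all-pairs neighbor oracle with explicit image enumeration
neighbor_oracle <- function(system, cutoff) {
  n <- n_atoms(system)
  pairs <- 0L
  shifts <- as.matrix(expand.grid(sx = -1:1, sy = -1:1, sz = -1:1))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dr <- system$positions[j, ] - system$positions[i, ]
    if (any(system$pbc)) {
      cand <- sweep(shifts %*% system$cell, 2, -dr, "-")
      d <- min(sqrt(rowSums(cand^2)))
    } else {
      d <- sqrt(sum(dr^2))
    }
    if (d <= cutoff) pairs <- pairs + 1L
  }
  pairs
}

# brute-force orbit oracle: pairwise rooted-ball isomorphism, no refinement
orbit_oracle <- function(graph, depth, include_hydrogens = FALSE) {
  g <- graph$graph
  if (!include_hydrogens) {
    g <- igraph::induced_subgraph(g, which(igraph::V(g)$element != "H"))
  }
  nv <- igraph::vcount(g)
  ball_of <- function(v) {
    nodes <- igraph::ego(g, order = depth, nodes = v)[[1]]
    igraph::V(g)$.oid <- seq_len(nv)
    sub <- igraph::induced_subgraph(g, nodes)
    igraph::V(sub)$col <- match(igraph::V(sub)$element, c("H", "C", "N", "O",
                                                          "F", "P", "S", "Cl")) +
      1000L * as.integer(igraph::V(sub)$.oid == as.integer(v))
    sub
  }
  balls <- lapply(seq_len(nv), ball_of)
  reps <- list()
  for (b in balls) {
    hit <- FALSE
    for (r in reps) {
      if (igraph::isomorphic(b, r, method = "vf2",
                             vertex.color1 = igraph::V(b)$col,
                             vertex.color2 = igraph::V(r)$col)) {
        hit <- TRUE; break
      }
    }
    if (!hit) reps[[length(reps) + 1L]] <- b
  }
  length(reps)
}

# net torque about the origin
net_torque <- function(positions, forces) {
  colSums(cbind(positions[, 2] * forces[, 3] - positions[, 3] * forces[, 2],
                positions[, 3] * forces[, 1] - positions[, 1] * forces[, 3],
                positions[, 1] * forces[, 2] - positions[, 2] * forces[, 1]))
}

random_rotation_matrix <- function(seed = 1) {
  set.seed(seed)
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
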