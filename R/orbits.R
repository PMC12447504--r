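#' Molecular graph with element-labeled nodes
#'
#' @param elements Character vector of element symbols (one per atom).
#' @param bonds 2-column integer matrix of undirected bonds (no self-loops or
#'   duplicates).
#' @return An object of class `molecular_graph` wrapping an igraph.
#' @export
molecular_graph <- function(elements, bonds) {
  bonds <- as.matrix(bonds)
  if (nrow(bonds) && any(bonds[, 1] == bonds[, 2])) stop("self-loops are not allowed")
  key <- paste(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
  if (anyDuplicated(key)) stop("duplicate bonds are not allowed")
  g <- igraph::make_empty_graph(n = length(elements), directed = FALSE)
  if (nrow(bonds)) g <- igraph::add_edges(g, t(bonds))
  igraph::V(g)$element <- elements
  structure(list(graph = g, elements = elements, bonds = bonds),
            class = "molecular_graph")
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat("<molecular_graph> ", length(x$elements), " atoms, ",
      nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}

#' Build a molecular graph from geometry
#'
#' Bonds atoms i, j iff `r_ij <= bond_factor * (r_cov_i + r_cov_j)` using
#' Cordero covalent radii.
#'
#' @param system An [atomic_system()].
#' @param bond_factor Covalent-radius tolerance factor (default 1.2).
#' @return A [molecular_graph()].
#' @export
graph_from_structure <- function(system, bond_factor = 1.2) {
  rc <- covalent_radius(system$numbers)
  cutoff <- bond_factor * 2 * max(rc)
  nbr <- build_neighbor_table(system, cutoff)
  keep <- nbr$d <= bond_factor * (rc[nbr$i] + rc[nbr$j])
  molecular_graph(element_symbol(system$numbers),
                  cbind(nbr$i[keep], nbr$j[keep]))
}

# environment ball of radius `depth` around vertex v; returns the induced
# igraph with a logical root attribute
.env_ball <- function(g, v, depth) {
  nodes <- igraph::ego(g, order = depth, nodes = v)[[1]]
  igraph::V(g)$.orig <- seq_len(igraph::vcount(g))
  sub <- igraph::induced_subgraph(g, nodes)
  igraph::V(sub)$is_root <- as.integer(igraph::V(sub)$.orig == as.integer(v))
  sub
}

# iterative neighborhood-label refinement to fixpoint inside a ball
.refine_signature <- function(ball) {
  lab <- igraph::V(ball)$element
  lab[igraph::V(ball)$is_root == 1] <-
    paste0(lab[igraph::V(ball)$is_root == 1], "*")
  adj <- igraph::adjacent_vertices(ball, igraph::V(ball))
  nclass <- length(unique(lab))
  repeat {
    lab <- vapply(seq_along(lab), function(v) {
      paste0(lab[v], "|", paste(sort(lab[as.integer(adj[[v]])]), collapse = ","))
    }, character(1))
    nc <- length(unique(lab))
    if (nc == nclass) break
    nclass <- nc
  }
  paste(lab[igraph::V(ball)$is_root == 1], ";",
        paste(sort(lab), collapse = " "))
}

.ball_isomorphic <- function(b1, b2) {
  col1 <- match(igraph::V(b1)$element, .ff_elements$symbol) +
    1000L * igraph::V(b1)$is_root
  col2 <- match(igraph::V(b2)$element, .ff_elements$symbol) +
    1000L * igraph::V(b2)$is_root
  igraph::isomorphic(b1, b2, method = "vf2",
                     vertex.color1 = col1, vertex.color2 = col2)
}

#' Count atom-environment orbits
#'
#' An orbit is an equivalence class of atoms whose labeled environments (the
#' rooted induced subgraph of all atoms within `depth` bonds) are isomorphic,
#' pooled across all supplied graphs. Environments are compared through an
#' iterative label-refinement signature; rare signature collisions between
#' non-isomorphic balls are resolved by an exact VF2 isomorphism check. By
#' default the comparison runs on the heavy-atom skeleton (hydrogens
#' implicit, as in molecular graphs derived from line notations); set
#' `include_hydrogens = TRUE` to treat hydrogens as explicit graph nodes.
#'
#' @param graphs A [molecular_graph()] or list of them.
#' @param depth Environment radius in bonds (>= 1; default 2, "up to second
#'   neighbors").
#' @param include_hydrogens Keep hydrogens as graph nodes (default FALSE).
#' @return List with `count` and a `signatures` data.frame (graph, atom,
#'   element, orbit id).
#' @export
orbit_count <- function(graphs, depth = 2, include_hydrogens = FALSE) {
  if (depth < 1) stop("depth must be >= 1")
  if (inherits(graphs, "molecular_graph")) graphs <- list(graphs)
  balls <- list(); sig <- character(0); meta <- list()
  for (gi in seq_along(graphs)) {
    g <- graphs[[gi]]$graph
    atom_ids <- seq_along(graphs[[gi]]$elements)
    if (!include_hydrogens) {
      keep <- igraph::V(g)$element != "H"
      atom_ids <- atom_ids[keep]
      g <- igraph::induced_subgraph(g, which(keep))
    }
    for (v in seq_len(igraph::vcount(g))) {
      b <- .env_ball(g, v, depth)
      balls[[length(balls) + 1L]] <- b
      sig[length(sig) + 1L] <- .refine_signature(b)
      meta[[length(meta) + 1L]] <- data.frame(
        graph = gi, atom = atom_ids[v],
        element = igraph::V(g)$element[v], stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, meta)
  # group by refinement signature, then resolve collisions exactly
  orbit <- integer(length(balls))
  next_id <- 0L
  for (s in unique(sig)) {
    members <- which(sig == s)
    reps <- integer(0)
    for (m in members) {
      placed <- FALSE
      for (r in reps) {
        if (.ball_isomorphic(balls[[m]], balls[[r]])) {
          orbit[m] <- orbit[r]; placed <- TRUE; break
        }
      }
      if (!placed) {
        next_id <- next_id + 1L
        orbit[m] <- next_id
        reps <- c(reps, m)
      }
    }
  }
  meta$orbit <- orbit
  list(count = length(unique(orbit)), signatures = meta)
}

#' Chemical-space coverage estimate
#'
#' Naive product estimate: `n_units * confs_per_unit` total conformations.
#' Values are exact integers as long as they stay below 2^53 (double
#' precision); larger products trigger a warning.
#'
#' @param n_units Number of distinct units (e.g. sequences, or orbits).
#' @param confs_per_unit Conformations needed per unit.
#' @return The product (numeric, exact below 2^53).
#' @export
coverage_estimate <- function(n_units, confs_per_unit) {
  if (n_units < 1 || confs_per_unit < 1 ||
      n_units != round(n_units) || confs_per_unit != round(confs_per_unit)) {
    stop("counts must be positive integers")
  }
  out <- n_units * confs_per_unit
  if (out > 2^53) warning("product exceeds 2^53; no longer an exact integer")
  out
}

#' Size of a sequence space
#'
#' `alphabet^length` distinct sequences (e.g. 20^4 tetrapeptides).
#'
#' @param alphabet Alphabet size.
#' @param length Sequence length.
#' @return Numeric count (exact below 2^53, else a warning).
#' @export
sequence_space_size <- function(alphabet, length) {
  out <- alphabet^length
  if (out > 2^53) warning("count exceeds 2^53; no longer an exact integer")
  out
}
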