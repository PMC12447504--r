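#' @name fixtures
#' @title Deterministic synthetic-structure generators
#' @description Every generator is a pure function of its arguments and seed:
#'   the same spec yields bit-identical output, and generated labels satisfy
#'   the physical consistency their consumers assume (forces are exact
#'   gradients of the generating potential). These stand in for quantum-
#'   mechanical training data at desk scale; they emulate inputs, not labels,
#'   of the production datasets.
NULL

# rigid gas-phase-like water template: O-H 0.9572 Angstrom, H-O-H 104.52 deg
.water_template <- function() {
  ang <- 104.52 * pi / 180
  rbind(c(0, 0, 0),
        c(0.9572, 0, 0),
        c(0.9572 * cos(ang), 0.9572 * sin(ang), 0))
}

.random_rotation <- function() {
  repeat {
    q <- stats::rnorm(4)
    n <- sqrt(sum(q^2))
    if (n > 1e-8) break
  }
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
        c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
        c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv())) {
            rm(".Random.seed", envir = globalenv())
          })
  set.seed(seed)
  expr
}

#' Periodic water box
#'
#' Replicates a rigid water template on a jittered cubic lattice at the
#' requested density, with random molecular orientations. The cell edge
#' follows from `(n * M_water / density)^(1/3)`; an error is raised if the
#' density cannot be met without O-O clashes (< 2.2 Angstrom).
#'
#' @param n_molecules Number of molecules (>= 1).
#' @param density Target density in g/cm^3 (default 0.997, ambient liquid
#'   water).
#' @param seed Integer seed (orientation and jitter).
#' @param jitter Lattice jitter amplitude (Angstrom).
#' @return A periodic [atomic_system()] with 3 * n atoms (O before its two H).
#' @export
make_water_box <- function(n_molecules, density = 0.997, seed = 1,
                           jitter = 0.1) {
  if (n_molecules < 1) stop("n_molecules must be >= 1")
  m_water <- sum(atomic_mass(c(8L, 1L, 1L)))
  # amu/(g/cm^3) -> Angstrom^3 : 1 amu = 1/0.602214076 g/mol per N_A
  vol <- n_molecules * m_water / (density * 0.602214076)
  edge <- vol^(1 / 3)
  m <- ceiling(n_molecules^(1 / 3))
  spacing <- edge / m
  if (spacing < 2.2 + 2 * jitter + 2 * 0.9572) {
    # worst case: two O jittered toward each other plus OH arms; conservative
    if (spacing - 2 * jitter - 0.5 < 2.2) {
      stop("density unachievable without O-O clashes (< 2.2 Angstrom)")
    }
  }
  tmpl <- .water_template()
  tmpl <- tmpl - matrix(colMeans(tmpl), 3, 3, byrow = TRUE)
  .with_seed(seed, {
    pos <- matrix(0, 3 * n_molecules, 3)
    k <- 0
    for (ix in 0:(m - 1)) for (iy in 0:(m - 1)) for (iz in 0:(m - 1)) {
      if (k >= n_molecules) next
      k <- k + 1
      center <- (c(ix, iy, iz) + 0.5) * spacing +
        stats::runif(3, -jitter, jitter)
      rot <- .random_rotation()
      pos[(3 * k - 2):(3 * k), ] <- tmpl %*% t(rot) +
        matrix(center, 3, 3, byrow = TRUE)
    }
    sys <- atomic_system(pos, rep(c(8L, 1L, 1L), n_molecules),
                         cell = diag(3) * edge, pbc = TRUE)
    if (n_molecules > 1) {
      o_idx <- seq(1, 3 * n_molecules, by = 3)
      osys <- atomic_system(pos[o_idx, , drop = FALSE],
                            rep(8L, n_molecules), cell = diag(3) * edge,
                            pbc = TRUE)
      nb <- build_neighbor_table(osys, min(2.2, edge / 2 * 0.999))
      if (any(nb$d < 2.2)) stop("density unachievable without O-O clashes (< 2.2 Angstrom)")
    }
    sys
  })
}

#' Compact water cluster (non-periodic)
#'
#' `n` rigid waters on a small lattice with jitter; a convenient isolated
#' test system (e.g. a trimer for conservation checks).
#'
#' @param n Number of molecules.
#' @param spacing O-O lattice spacing (Angstrom).
#' @param seed Integer seed.
#' @return An [atomic_system()].
#' @export
make_water_cluster <- function(n, spacing = 3.0, seed = 1) {
  tmpl <- .water_template()
  tmpl <- tmpl - matrix(colMeans(tmpl), 3, 3, byrow = TRUE)
  m <- ceiling(n^(1 / 3))
  .with_seed(seed, {
    pos <- matrix(0, 3 * n, 3)
    k <- 0
    for (ix in 0:(m - 1)) for (iy in 0:(m - 1)) for (iz in 0:(m - 1)) {
      if (k >= n) next
      k <- k + 1
      center <- c(ix, iy, iz) * spacing + stats::runif(3, -0.1, 0.1)
      pos[(3 * k - 2):(3 * k), ] <- tmpl %*% t(.random_rotation()) +
        matrix(center, 3, 3, byrow = TRUE)
    }
    atomic_system(pos, rep(c(8L, 1L, 1L), n))
  })
}

#' Rigid dimer scan
#'
#' Centers both monomers at their centers of mass and displaces the second
#' along x by each separation; monomer geometries are identical across
#' frames.
#'
#' @param monomer1,monomer2 [atomic_system()] monomers.
#' @param separations Positive center-of-mass separations (Angstrom).
#' @return An object of class `dimer_scan`: list with `dimers` (list of
#'   combined systems), `monomer1`, `monomer2` (centered), `separations`.
#' @export
make_dimer_scan <- function(monomer1, monomer2, separations) {
  if (any(separations <= 0)) stop("separations must be > 0")
  center <- function(s) {
    m <- atomic_mass(s$numbers)
    s$positions <- s$positions -
      matrix(colSums(s$positions * m) / sum(m), n_atoms(s), 3, byrow = TRUE)
    s
  }
  m1 <- center(monomer1); m2 <- center(monomer2)
  dimers <- lapply(separations, function(s) {
    p2 <- m2$positions + matrix(c(s, 0, 0), n_atoms(m2), 3, byrow = TRUE)
    atomic_system(rbind(m1$positions, p2), c(m1$numbers, m2$numbers),
                  charge = m1$charge + m2$charge)
  })
  structure(list(dimers = dimers, monomer1 = m1, monomer2 = m2,
                 separations = separations), class = "dimer_scan")
}

#' Label structures with a reference generator
#'
#' Attaches reference forces, dipoles and Hirshfeld ratios produced either by
#' the composed potential with pinned parameters (`model` + `config`) or by a
#' caller-supplied analytic generator. Labels are reproducible from the spec
#' and the forces are the exact (analytic) gradients of the generating
#' potential.
#'
#' @param structures List of [atomic_system()] objects.
#' @param model A [semilocal_model()] (the "teacher").
#' @param config An [ff_config()].
#' @param path Optional extended-XYZ output path; per-atom `forces`,
#'   `hirshfeld_ratios` and the per-structure `dipole` are written.
#' @return A [training_batch()].
#' @export
make_labeled_dataset <- function(structures, model, config = ff_config(model = model$spec),
                                 path = NULL) {
  forces <- list(); dipoles <- list(); hirshfeld <- list()
  for (b in seq_along(structures)) {
    br <- evaluate_potential(structures[[b]], model, config)
    forces[[b]] <- br$forces
    dipoles[[b]] <- if (!is.null(br$charges)) {
      dipole_from_charges(structures[[b]], br$charges)
    } else c(0, 0, 0)
    hirshfeld[[b]] <- if (!is.null(br$predictions)) br$predictions$h else
      rep(1, n_atoms(structures[[b]]))
    structures[[b]]$info$forces <- br$forces
    structures[[b]]$info$hirshfeld_ratios <- hirshfeld[[b]]
  }
  if (!is.null(path)) write_extxyz(structures, path)
  training_batch(structures, forces = forces, dipoles = dipoles,
                 hirshfeld = hirshfeld)
}

# --- internal-coordinate (NeRF) atom placement -----------------------------

# place atom d bonded to c, with angle(b,c,d) and dihedral(a,b,c,d) given in
# degrees; a, b, c are coordinates of already-placed reference atoms
.nerf <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- -dihedral * pi / 180   # sign matching the atan2 dihedral convention
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  c + (-bond * cos(ang)) * bc +
    (bond * sin(ang) * cos(dih)) * m +
    (bond * sin(ang) * sin(dih)) * n
}

# idealized polyalanine builder (capped Ac-Ala_n-NMe or free H-Ala_n-OH) in
# an extended conformation; returns positions, elements, names, resids, bonds
.build_polyalanine <- function(n_res, capped = TRUE, phi = -139, psi = 135) {
  atoms <- list(); bonds <- NULL
  add <- function(name, elem, p, resid) {
    atoms[[length(atoms) + 1L]] <<- list(name = name, elem = elem,
                                         p = p, resid = as.integer(resid))
    length(atoms)
  }
  bnd <- function(i, j) bonds <<- rbind(bonds, c(i, j))
  P <- function(i) atoms[[i]]$p
  vir <- c(0.5, 1.2, 0)
  if (capped) {
    iCH3 <- add("CH3", "C", c(0, 0, 0), 0L)
    iC <- add("C", "C", c(1.51, 0, 0), 0L)
    iO <- add("O", "O", .nerf(vir, P(iCH3), P(iC), 1.231, 120.8, 180), 0L)
    bnd(iCH3, iC); bnd(iC, iO)
    prev <- list(refO = iO, CA = iCH3, C = iC)
  } else {
    iN <- add("N", "N", c(0, 0, 0), 1L)
    iCA <- add("CA", "C", c(1.458, 0, 0), 1L)
    bnd(iN, iCA)
  }
  for (r in seq_len(n_res)) {
    if (capped || r > 1) {
      iN <- add("N", "N",
                .nerf(P(prev$refO), P(prev$CA), P(prev$C), 1.329, 116.2, 180), r)
      iHN <- add("H", "H", .nerf(P(prev$CA), P(prev$C), P(iN), 1.01, 119, 0), r)
      iCA <- add("CA", "C",
                 .nerf(P(prev$CA), P(prev$C), P(iN), 1.458, 121.7, 180), r)
      bnd(prev$C, iN); bnd(iN, iHN); bnd(iN, iCA)
      aref <- prev$C
    } else {
      # free N-terminus: N, CA already placed; amine hydrogens after C below
      aref <- NULL
    }
    if (!capped && r == 1) {
      iC <- add("C", "C", .nerf(vir, P(iN), P(iCA), 1.525, 111.2, 0), r)
      iCB <- add("CB", "C", .nerf(vir, P(iN), P(iCA), 1.53, 110.5, 122), r)
      iHA <- add("HA", "H", .nerf(vir, P(iN), P(iCA), 1.09, 108.5, -119), r)
      iH1 <- add("H1", "H", .nerf(P(iC), P(iCA), P(iN), 1.01, 109.5, 60), r)
      iH2 <- add("H2", "H", .nerf(P(iC), P(iCA), P(iN), 1.01, 109.5, 300), r)
      bnd(iN, iH1); bnd(iN, iH2)
    } else {
      iC <- add("C", "C", .nerf(P(aref), P(iN), P(iCA), 1.525, 111.2, phi), r)
      iCB <- add("CB", "C", .nerf(P(aref), P(iN), P(iCA), 1.53, 110.5, phi + 122), r)
      iHA <- add("HA", "H", .nerf(P(aref), P(iN), P(iCA), 1.09, 108.5, phi - 119), r)
    }
    bnd(iCA, iC); bnd(iCA, iCB); bnd(iCA, iHA)
    iOr <- add("O", "O", .nerf(P(iN), P(iCA), P(iC), 1.231, 120.8, psi + 180), r)
    bnd(iC, iOr)
    for (k in 1:3) {
      iHB <- add(paste0("HB", k), "H",
                 .nerf(P(iN), P(iCA), P(iCB), 1.09, 110, c(60, 180, 300)[k]), r)
      bnd(iCB, iHB)
    }
    prev <- list(refO = iOr, CA = iCA, C = iC, N = iN)
  }
  if (capped) {
    rT <- n_res + 1L
    iNT <- add("N", "N",
               .nerf(P(prev$refO), P(prev$CA), P(prev$C), 1.329, 116.2, 180), rT)
    iHT <- add("H", "H", .nerf(P(prev$CA), P(prev$C), P(iNT), 1.01, 119, 0), rT)
    iCT <- add("CH3", "C",
               .nerf(P(prev$CA), P(prev$C), P(iNT), 1.458, 121.7, 180), rT)
    bnd(prev$C, iNT); bnd(iNT, iHT); bnd(iNT, iCT)
    for (k in 1:3) {
      iH <- add(paste0("HT", k), "H",
                .nerf(P(prev$C), P(iNT), P(iCT), 1.09, 109.5, c(60, 180, 300)[k]), rT)
      bnd(iCT, iH)
    }
    # acetyl methyl hydrogens (reference the first residue N)
    firstN <- which(vapply(atoms, function(a) a$name == "N" && a$resid == 1L,
                           logical(1)))[1]
    for (k in 1:3) {
      iH <- add(paste0("HY", k), "H",
                .nerf(P(firstN), P(2L), P(1L), 1.09, 109.5, c(60, 180, 300)[k]), 0L)
      bnd(1L, iH)
    }
  } else {
    # free C-terminus: carboxyl OXT-H on the last residue's C
    iOXT <- add("OXT", "O",
                .nerf(P(prev$N), P(prev$CA), P(prev$C), 1.34, 113, psi), n_res)
    iHXT <- add("HXT", "H",
                .nerf(P(prev$CA), P(prev$C), P(iOXT), 0.97, 106, 180), n_res)
    bnd(prev$C, iOXT); bnd(iOXT, iHXT)
  }
  pos <- do.call(rbind, lapply(atoms, `[[`, "p"))
  list(positions = pos,
       elements = vapply(atoms, `[[`, character(1), "elem"),
       names = vapply(atoms, `[[`, character(1), "name"),
       resids = vapply(atoms, `[[`, integer(1), "resid"),
       bonds = bonds)
}

# toy lipid slab: P headgroup + straight C6 tail with 2 H per carbon
.build_popc_slab <- function(n_side = 2, lx = 8, z_head = 16, seed = 1) {
  dz <- 1.27   # CH2 rise along the chain
  atoms <- NULL; elems <- character(0); bonds <- NULL
  names_ <- character(0); lipid_id <- integer(0)
  ch_pairs <- NULL; head_idx <- integer(0)
  add <- function(e, p, nm, lid) {
    atoms <<- rbind(atoms, p); elems <<- c(elems, e)
    names_ <<- c(names_, nm); lipid_id <<- c(lipid_id, lid)
    length(elems)
  }
  lid <- 0
  for (leaf in c(1, -1)) {
    for (ix in 0:(n_side - 1)) for (iy in 0:(n_side - 1)) {
      lid <- lid + 1
      x0 <- (ix + 0.5) * lx; y0 <- (iy + 0.5) * lx
      iP <- add("P", c(x0, y0, leaf * z_head), "P", lid)
      head_idx <- c(head_idx, iP)
      prev <- iP
      for (c_ in 1:6) {
        zc <- leaf * (z_head - c_ * dz)
        iC <- add("C", c(x0, y0, zc), paste0("C", c_), lid)
        bonds <- rbind(bonds, c(prev, iC))
        for (hh in 1:2) {
          iH <- add("H", c(x0 + ifelse(hh == 1, 1.0, -1.0),
                           y0 + ifelse(c_ %% 2 == 0, 0.4, -0.4), zc),
                    paste0("H", c_, hh), lid)
          bonds <- rbind(bonds, c(iC, iH))
          ch_pairs <- rbind(ch_pairs, c(iC, iH))
        }
        prev <- iC
      }
    }
  }
  cell <- diag(c(n_side * lx, n_side * lx, 2 * (z_head + 10)))
  sys <- atomic_system(atoms, element_number(elems), cell = cell, pbc = TRUE,
                       info = list(atom_names = names_, lipid_id = lipid_id))
  list(system = sys, bonds = bonds, head_idx = head_idx, ch_pairs = ch_pairs,
       n_lipids = lid)
}

#' Curated topology fixtures
#'
#' Small molecules with coordinates, explicit bond lists and residue metadata,
#' built in code from idealized internal-coordinate templates (standard bond
#' lengths/angles, extended backbone conformation).
#'
#' Available names:
#' \describe{
#'   \item{methane}{5 atoms, 4 bonds.}
#'   \item{water}{3 atoms, 2 bonds.}
#'   \item{alanine_dipeptide}{Capped Ac-Ala-NMe, 22 atoms.}
#'   \item{alanine_tetrapeptide}{Uncapped tetra-alanine H-(Ala)4-OH, 43
#'     atoms: the normative fixture for the orbit-coverage analysis (10
#'     heavy-atom orbits at depth 2).}
#'   \item{acala3nme}{Capped Ac-Ala3-NMe, 42 atoms (the MD22-style alanine
#'     tetrapeptide), used for dihedral/MD tests.}
#'   \item{popc_slab_toy}{Toy two-leaflet lipid slab (P head + C6 tail),
#'     periodic, with headgroup indices and C-H pair metadata for bilayer
#'     observables.}
#' }
#'
#' @param name Fixture name.
#' @return List with `system` (an [atomic_system()], residue metadata in
#'   `info`), `bonds` (2-column matrix), and fixture-specific metadata.
#' @export
make_topology_fixture <- function(name) {
  choices <- c("methane", "water", "alanine_dipeptide", "alanine_tetrapeptide",
               "acala3nme", "popc_slab_toy")
  if (!name %in% choices) {
    stop("unknown fixture '", name, "'; choices: ", paste(choices, collapse = ", "))
  }
  if (name == "methane") {
    d <- 1.087
    t <- acos(-1 / 3)
    h1 <- c(0, 0, d)
    h2 <- c(d * sin(t), 0, d * cos(t))
    h3 <- .nerf(h2, h1, c(0, 0, 0), d, 109.471, 120)
    h4 <- .nerf(h2, h1, c(0, 0, 0), d, 109.471, 240)
    pos <- rbind(c(0, 0, 0), h1, h2, h3, h4)
    sys <- atomic_system(pos, c(6L, 1L, 1L, 1L, 1L))
    return(list(system = sys, bonds = cbind(1L, 2:5)))
  }
  if (name == "water") {
    sys <- atomic_system(.water_template(), c(8L, 1L, 1L))
    return(list(system = sys, bonds = rbind(c(1L, 2L), c(1L, 3L))))
  }
  if (name == "popc_slab_toy") {
    return(.build_popc_slab())
  }
  bp <- switch(name,
               alanine_dipeptide = .build_polyalanine(1, capped = TRUE),
               alanine_tetrapeptide = .build_polyalanine(4, capped = FALSE),
               acala3nme = .build_polyalanine(3, capped = TRUE))
  sys <- atomic_system(bp$positions, element_number(bp$elements),
                       info = list(atom_names = bp$names,
                                   res_ids = bp$resids,
                                   res_names = rep("ALA", length(bp$resids))))
  list(system = sys, bonds = bp$bonds)
}
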