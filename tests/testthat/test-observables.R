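test_that("rdf of an ideal gas is flat and a fixed pair gives a lone peak", {
  set.seed(101)
  box <- 12
  frames <- lapply(1:40, function(k) {
    atomic_system(matrix(runif(3 * 120, 0, box), 120, 3), rep(8L, 120),
                  cell = diag(3) * box, pbc = TRUE)
  })
  g <- rdf(trajectory(frames, 1), c("O", "O"), r_max = 5.5, bin_width = 0.25)
  interior <- g$g[g$r > 1]
  expect_lt(max(abs(interior - 1)), 0.12)
  # lone fixed pair at d = 3.05: single occupied bin
  two <- atomic_system(rbind(c(1, 1, 1), c(4.05, 1, 1)), c(8L, 8L),
                       cell = diag(3) * 20, pbc = TRUE)
  g2 <- rdf(trajectory(list(two), 1), c("O", "O"), r_max = 6, bin_width = 0.2)
  expect_equal(g2$r[which(g2$g > 0)], 3.1)   # the bin containing 3.05
  expect_equal(sum(g2$g > 0), 1L)
})

test_that("rdf integrals agree across bin widths", {
  set.seed(102)
  frames <- lapply(1:10, function(k) {
    atomic_system(matrix(runif(3 * 80, 0, 10), 80, 3), rep(8L, 80),
                  cell = diag(3) * 10, pbc = TRUE)
  })
  tr <- trajectory(frames, 1)
  fine <- rdf(tr, c("O", "O"), 4, 0.1)
  coarse <- rdf(tr, c("O", "O"), 4, 0.2)
  # counts over a shared range must agree: integrate 4 pi r^2 rho g dr
  integ <- function(d, w) sum(4 * pi * d$r^2 * d$g * w)
  expect_equal(integ(fine, 0.1), integ(coarse, 0.2), tolerance = 0.02)
  expect_error(rdf(trajectory(list(mk_random_system(5, 1)), 1), c("O", "O"), 4),
               "periodic")
})

test_that("diffusion is zero for frozen atoms and recovered for a random walk", {
  s <- mk_random_system(10, seed = 103)
  frames <- rep(list(s), 30)
  d0 <- self_diffusion(trajectory(frames, 10))
  expect_equal(d0$D, 0, tolerance = 1e-14)
  # discrete random walk: per-step variance sigma^2 per axis
  set.seed(104)
  sigma <- 0.4; dt <- 10; nstep <- 250; nw <- 150
  pos <- matrix(0, nw, 3)
  frames <- vector("list", nstep)
  for (k in seq_len(nstep)) {
    pos <- pos + matrix(rnorm(nw * 3, sd = sigma), nw, 3)
    frames[[k]] <- atomic_system(pos, rep(8L, nw))
  }
  est <- self_diffusion(trajectory(frames, dt), fit_window = c(10, 600))
  d_true <- 3 * sigma^2 / (6 * dt) * 1000     # Angstrom^2/ps
  expect_lt(abs(est$D - d_true) / d_true, 0.05)
  expect_gt(est$r_squared, 0.99)
})

test_that("ballistic motion is flagged by the fit diagnostic", {
  frames <- lapply(1:60, function(k) {
    atomic_system(matrix(c(0.005 * k^2, 0, 0), 1, 3), 8L)
  })
  est <- self_diffusion(trajectory(frames, 1), fit_window = c(1, 59))
  # curved MSD of uniformly accelerated motion: visibly worse line fit than
  # the diffusive case (which exceeds 0.99 above)
  expect_lt(est$r_squared, 0.96)
  expect_error(self_diffusion(trajectory(frames, 1), fit_window = c(100, 200)),
               "fewer than 2")
})

test_that("dihedral angles match hand-computed geometry", {
  # trans (180) and cis (0) butane-like quadruples
  expect_equal(abs(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))),
               180)
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), 0)
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 0, 1)),
               -90, tolerance = 1e-12)
  # a skew case against the explicit atan2 formula
  p <- list(c(0.2, 1.3, -0.4), c(0, 0, 0), c(1.7, 0.1, 0.3), c(2.1, -0.9, 1.4))
  cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  b1 <- p[[2]] - p[[1]]; b2 <- p[[3]] - p[[2]]; b3 <- p[[4]] - p[[3]]
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  ref <- atan2(sum((cross3(n1, b2) / sqrt(sum(b2^2))) * n2),
               sum(n1 * n2)) * 180 / pi
  expect_equal(dihedral_angle(p[[1]], p[[2]], p[[3]], p[[4]]), ref,
               tolerance = 1e-10)
})

test_that("free-energy surfaces follow Boltzmann inversion closed forms", {
  # uniform samples: FES flat up to sampling noise
  set.seed(105)
  phi <- runif(40000, -180, 180); psi <- runif(40000, -180, 180)
  f <- fes_from_angles(phi, psi, 300, bins = 6)
  expect_lt(max(f$fes[is.finite(f$fes)]), 0.15)
  # two states populated 10:1 at 300 K
  phi2 <- c(rep(-60, 1000), rep(60, 100))
  psi2 <- c(rep(-45, 1000), rep(135, 100))
  f2 <- fes_from_angles(phi2, psi2, 300, bins = 36)
  vals <- sort(unique(as.numeric(f2$fes[is.finite(f2$fes)])))
  expect_equal(vals[1], 0)
  expect_equal(vals[2], ff_constants$kb_kcal * 300 * log(10), tolerance = 1e-10)
  expect_equal(vals[2], 1.3726, tolerance = 1e-3)   # ~1.37 kcal/mol
  expect_true(all(is.infinite(f2$fes[f2$counts == 0])))
})

test_that("ramachandran_fes consumes peptide metadata", {
  fx <- make_topology_fixture("acala3nme")
  tr <- trajectory(list(fx$system, fx$system), 100)
  quads <- backbone_dihedrals(fx$system)
  expect_equal(nrow(quads$phi), 3)
  f <- ramachandran_fes(tr, quads, 300, bins = 36)
  expect_equal(sum(f$counts), 2 * 3)
  bare <- atomic_system(fx$system$positions, fx$system$numbers)
  expect_error(ramachandran_fes(trajectory(list(bare), 1)), "metadata")
})

test_that("lagged RMSD vanishes for identical or rigidly moved frames", {
  s <- mk_random_system(8, seed = 106)
  tr <- trajectory(rep(list(s), 5), 1)
  expect_equal(rmsd_lag(tr, 1:3)$rmsd, rep(0, 3), tolerance = 1e-10)
  rot <- transform_system(s, random_rotation_matrix(2), c(5, 5, 5))
  tr2 <- trajectory(list(s, rot), 1)
  expect_lt(rmsd_lag(tr2, 1)$rmsd, 1e-10)
  expect_error(rmsd_lag(tr2, 2), "smaller than the trajectory")
})

test_that("optimal-superposition RMSD matches an independent implementation", {
  set.seed(107)
  a <- matrix(rnorm(12), 4, 3)
  b <- a %*% t(random_rotation_matrix(9)) + matrix(rnorm(12, sd = 0.3), 4, 3)
  sa <- atomic_system(a, rep(6L, 4)); sb <- atomic_system(b, rep(6L, 4))
  got <- rmsd_lag(trajectory(list(sa, sb), 1), 1)$rmsd
  # bio3d's least-squares fit as the oracle
  ref <- bio3d::rmsd(as.numeric(t(a)), as.numeric(t(b)), fit = TRUE)
  expect_equal(got, ref, tolerance = 2e-3)   # bio3d rounds to 3 decimals
})

test_that("power spectra localize a pure cosine and respect the Nyquist limit", {
  dt <- 2.5
  nfr <- 400
  f0 <- 0.02   # 1/fs
  frames <- rep(list(atomic_system(matrix(0, 1, 3), 1L)), nfr)
  vels <- lapply(seq_len(nfr), function(k) {
    matrix(c(cos(2 * pi * f0 * (k - 1) * dt), 0, 0), 1, 3)
  })
  tr <- trajectory(frames, dt, velocities = vels)
  sp <- power_spectrum(tr)
  peak <- sp$wavenumber[which.max(sp$intensity)]
  expect_equal(peak, f0 / ff_constants$c_cm_fs, tolerance = 0.05)
  nyquist <- 1 / (2 * dt) / ff_constants$c_cm_fs
  expect_equal(nyquist, 6671, tolerance = 1e-3)
  expect_lte(max(sp$wavenumber), nyquist)
  expect_error(power_spectrum(trajectory(frames, dt)), "velocities")
})

test_that("white-noise velocities give a flat spectrum within the noise band", {
  set.seed(108)
  nfr <- 600
  frames <- rep(list(atomic_system(matrix(0, 1, 3), 1L)), nfr)
  vels <- lapply(seq_len(nfr), function(k) matrix(rnorm(3, sd = 0.01), 1, 3))
  sp <- power_spectrum(trajectory(frames, 1, velocities = vels))
  inten <- sp$intensity[-1]
  expect_lt(stats::sd(inten) / mean(inten), 0.6)
  expect_gt(min(inten) / mean(inten), 0)
})

test_that("order parameters reach their geometric limits", {
  mk_tr <- function(hvec) {
    s <- atomic_system(rbind(c(0, 0, 0), c(0, 0, 0) + hvec), c(6L, 1L))
    trajectory(list(s), 1)
  }
  expect_equal(lipid_order_parameters(mk_tr(c(0, 0, 1.09)),
                                      rbind(c(1L, 2L)))$s_cd, 1.0)
  expect_equal(lipid_order_parameters(mk_tr(c(1.09, 0, 0)),
                                      rbind(c(1L, 2L)))$s_cd, -0.5)
  # isotropically random orientations average to zero
  set.seed(109)
  n <- 3000
  dirs <- matrix(rnorm(3 * n), n, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  pos <- matrix(0, 2 * n, 3)
  pos[seq(2, 2 * n, 2), ] <- dirs * 1.09
  s <- atomic_system(pos, rep(c(6L, 1L), n))
  pr <- cbind(seq(1, 2 * n, 2), seq(2, 2 * n, 2))
  got <- lipid_order_parameters(trajectory(list(s), 1), pr,
                                carbons = rep(1, n))$s_cd
  expect_lt(abs(got), 0.05)
  expect_error(lipid_order_parameters(trajectory(list(s), 1),
                                      matrix(0L, 0, 2)), "empty")
})

test_that("bilayer metrics recover constructed peaks and do the area arithmetic", {
  set.seed(110)
  lz <- 60
  z1 <- 11.5; z2 <- 48.5
  zs <- c(rnorm(800, z1, 1.0), rnorm(800, z2, 1.0))
  pos <- cbind(runif(1600, 0, 64), runif(1600, 0, 58), zs)
  s <- atomic_system(pos, rep(15L, 1600), cell = diag(c(64, 58, lz)), pbc = TRUE)
  bm <- bilayer_metrics(trajectory(list(s), 1), seq_len(1600), n_lipids = 128)
  expect_lt(abs(bm$d_hh - (z2 - z1)), 0.25)          # within half a bin
  expect_equal(bm$area_per_lipid, 64 * 58 / 64)      # box 64 x 58, 128 lipids
  expect_equal(bm$area_per_lipid, 58.0)
  # doubling the lipid count at fixed box halves the area per lipid
  bm2 <- bilayer_metrics(trajectory(list(s), 1), seq_len(1600), n_lipids = 256)
  expect_equal(bm2$area_per_lipid, bm$area_per_lipid / 2)
  # unimodal profile errors
  uni <- atomic_system(cbind(runif(400, 0, 64), runif(400, 0, 58),
                             rnorm(400, 30, 1)),
                       rep(15L, 400), cell = diag(c(64, 58, lz)), pbc = TRUE)
  expect_error(bilayer_metrics(trajectory(list(uni), 1), 1:400, 128),
               "unimodal")
})

test_that("observables are invariant under a global rotation of every frame", {
  base <- mk_random_system(6, seed = 200)
  frames <- lapply(1:10, function(k) {
    set.seed(200 + k)
    base$positions <- base$positions + matrix(rnorm(18, sd = 0.2), 6, 3)
    base
  })
  tr <- trajectory(frames, 5)
  rot <- random_rotation_matrix(4)
  trr <- trajectory(lapply(frames, transform_system, rotation = rot), 5)
  expect_equal(self_diffusion(tr)$D, self_diffusion(trr)$D, tolerance = 1e-10)
  expect_equal(rmsd_lag(tr, 1:2)$rmsd, rmsd_lag(trr, 1:2)$rmsd,
               tolerance = 1e-10)
})
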