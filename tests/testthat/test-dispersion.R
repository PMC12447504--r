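ref <- free_atom_reference()

test_that("TS scaling is linear in h for alpha and quadratic for C6", {
  z <- supported_elements()
  p1 <- ts_atomic_params(rep(1, 8), z)
  expect_equal(p1$alpha, ref$alpha_free)
  expect_equal(p1$c6, ref$c6_free)
  p08 <- ts_atomic_params(rep(0.8, 8), z)
  expect_equal(p08$alpha, 0.8 * ref$alpha_free)
  expect_equal(p08$c6, 0.64 * ref$c6_free)
  pa <- ts_atomic_params(c(0.5, rep(1, 7)), z)
  pb <- ts_atomic_params(c(1.0, rep(1, 7)), z)
  expect_equal(pb$c6[1] / pa$c6[1], 4)   # doubling h quadruples C6
  expect_error(ts_atomic_params(c(-0.1, rep(1, 7)), z), "positive")
})

test_that("C6 combination rule is symmetric and exact for identical atoms", {
  expect_equal(c6_combination(4.5, 4.5, 6.5, 6.5), 6.5)
  ao <- ref$alpha_free[ref$symbol == "O"]; co <- ref$c6_free[ref$symbol == "O"]
  ah <- ref$alpha_free[ref$symbol == "H"]; ch <- ref$c6_free[ref$symbol == "H"]
  hand <- 2 * ch * co / ((ao / ah) * ch + (ah / ao) * co)
  expect_equal(c6_combination(ah, ao, ch, co), hand, tolerance = 1e-14)
  expect_equal(c6_combination(ah, ao, ch, co), c6_combination(ao, ah, co, ch))
})

test_that("QDO relations satisfy the universal ratio and scale linearly in C6", {
  q <- qdo_higher_orders(6.5, 5.1)
  expect_equal(q$c10 * 6.5 / q$c8^2, 49 / 40, tolerance = 1e-12)
  q2 <- qdo_higher_orders(13.0, 5.1)
  expect_equal(q2$c8 / q$c8, 2, tolerance = 1e-12)
  expect_equal(q2$c10 / q$c10, 2, tolerance = 1e-12)
  # positive across the free-atom table
  for (i in 1:8) for (j in 1:8) {
    c6ij <- c6_combination(ref$alpha_free[i], ref$alpha_free[j],
                           ref$c6_free[i], ref$c6_free[j])
    rv <- bj_damping_radius(ref$alpha_free[i], ref$alpha_free[j], 1)
    qq <- qdo_higher_orders(c6ij, rv)
    expect_gt(qq$c8, 0); expect_gt(qq$c10, 0)
  }
})

test_that("damping radius reproduces its closed form and is linear in gamma", {
  expect_equal(bj_damping_radius(1, 1, 1),
               2 * (137.035999084^(4 / 3))^(1 / 7), tolerance = 1e-10)
  expect_equal(bj_damping_radius(1, 1, 1), 5.1056, tolerance = 1e-4)
  expect_equal(bj_damping_radius(3, 7, 2), 2 * bj_damping_radius(3, 7, 1))
  expect_equal(bj_damping_radius(4, 4, 1.3), bj_damping_radius(4, 4, 1.3))
  # heteronuclear mean equals homonuclear at the mean polarizability
  expect_equal(bj_damping_radius(2, 6, 1), bj_damping_radius(4, 4, 1))
})

test_that("dispersion energy equals an independent double-loop evaluation", {
  s <- atomic_system(rbind(c(0, 0, 0), c(2.8, 0.4, 0), c(1.1, 2.5, 0.7)),
                     c(8L, 6L, 1L))
  h <- c(0.9, 1.05, 0.7)
  gamma <- 1.1
  nbr <- build_neighbor_table(s, 12)
  got <- dispersion_energy(s, nbr, h, gamma, shift = FALSE)
  # scalar brute force in atomic units
  a0 <- ff_constants$bohr_ang
  kfsc <- (1 / ff_constants$fine_structure)^(4 / 3)
  idx <- match(s$numbers, ref$z)
  etot <- 0
  for (i in 1:2) for (j in (i + 1):3) {
    ai <- h[i] * ref$alpha_free[idx[i]]; aj <- h[j] * ref$alpha_free[idx[j]]
    c6i <- h[i]^2 * ref$c6_free[idx[i]]; c6j <- h[j]^2 * ref$c6_free[idx[j]]
    c6 <- 2 * c6i * c6j / ((aj / ai) * c6i + (ai / aj) * c6j)
    rv <- 2 * (kfsc * (ai + aj) / 2)^(1 / 7)
    rd <- gamma * rv
    c8 <- 0.48 * c6 * rv^2
    c10 <- 49 / 40 * c8^2 / c6
    r <- sqrt(sum((s$positions[j, ] - s$positions[i, ])^2)) / a0
    etot <- etot - c6 / (r^6 + rd^6) - c8 / (r^8 + rd^8) - c10 / (r^10 + rd^10)
  }
  expect_equal(got$energy, etot * ff_constants$hartree_ev, tolerance = 1e-12)
})

test_that("pair energy is finite at r = 0 and approaches the multipole asymptote", {
  a0 <- ff_constants$bohr_ang
  two <- function(r) atomic_system(rbind(c(0, 0, 0), c(r, 0, 0)), c(8L, 8L))
  # near-coincident atoms: the damped series value at r = 0
  got0 <- dispersion_energy(two(1e-9), build_neighbor_table(two(1e-9), 20),
                            c(1, 1), 1, shift = FALSE)$energy
  alpha <- ref$alpha_free[ref$symbol == "O"]
  c6 <- ref$c6_free[ref$symbol == "O"]
  rv <- bj_damping_radius(alpha, alpha, 1)
  q <- qdo_higher_orders(c6, rv)
  closed <- -(c6 / rv^6 + q$c8 / rv^8 + q$c10 / rv^10) * ff_constants$hartree_ev
  expect_equal(got0, closed, tolerance = 1e-10)
  expect_true(is.finite(got0))
  # large r: -C6/r^6 dominates (all higher orders and damping negligible)
  r_ang <- 40 * rv * a0
  far <- two(r_ang)
  e_far <- dispersion_energy(far, build_neighbor_table(far, Inf), c(1, 1), 1,
                             shift = FALSE)$energy
  e_c6 <- -c6 / (r_ang / a0)^6 * ff_constants$hartree_ev
  expect_lt(abs(e_far - e_c6) / abs(e_c6), 1e-3)
})

test_that("stronger damping weakens the attraction at fixed geometry", {
  s <- atomic_system(rbind(c(0, 0, 0), c(3.5, 0, 0)), c(6L, 6L))
  nbr <- build_neighbor_table(s, 12)
  e <- vapply(c(0.8, 1.0, 1.2, 1.4), function(g) {
    dispersion_energy(s, nbr, c(1, 1), g, shift = FALSE)$energy
  }, numeric(1))
  expect_true(all(diff(e) > 0))  # toward zero
  expect_true(all(e < 0))
})

test_that("dispersion is invariant under rigid motion and extensive", {
  s <- mk_random_system(6, seed = 31)
  h <- runif(6, 0.6, 1.2)
  e0 <- dispersion_energy(s, build_neighbor_table(s, 12), h)$energy
  rot <- transform_system(s, random_rotation_matrix(5), c(3, -2, 7))
  e1 <- dispersion_energy(rot, build_neighbor_table(rot, 12), h)$energy
  expect_equal(e0, e1, tolerance = 1e-12)
  # duplicate far beyond the cutoff: energy doubles
  far <- atomic_system(rbind(s$positions, s$positions +
                               matrix(c(100, 0, 0), 6, 3, byrow = TRUE)),
                       rep(s$numbers, 2))
  e2 <- dispersion_energy(far, build_neighbor_table(far, 12), rep(h, 2))$energy
  expect_equal(e2, 2 * e0, tolerance = 1e-10)
})

test_that("dispersion forces (fixed h) match finite differences", {
  s <- mk_random_system(6, seed = 33)
  h <- runif(6, 0.6, 1.2)
  an <- dispersion_energy(s, build_neighbor_table(s, 12), h)$forces
  fd <- fd_forces(s, function(x) {
    dispersion_energy(x, build_neighbor_table(x, 12), h)$energy
  })
  expect_lt(max(abs(an - fd)) / max(abs(fd)), 1e-6)
})

test_that("dE/dh matches finite differences in the Hirshfeld ratios", {
  s <- mk_random_system(5, seed = 34)
  h <- runif(5, 0.6, 1.2)
  nbr <- build_neighbor_table(s, 12)
  an <- dispersion_energy(s, nbr, h)$dE_dh
  eps <- 1e-6
  fd <- vapply(1:5, function(i) {
    hp <- h; hp[i] <- hp[i] + eps
    hm <- h; hm[i] <- hm[i] - eps
    (dispersion_energy(s, nbr, hp)$energy -
       dispersion_energy(s, nbr, hm)$energy) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(an - fd)) / max(abs(fd)), 1e-6)
})

test_that("missing Hirshfeld ratios raise an instructive error", {
  s <- mk_random_system(4, seed = 35)
  expect_error(dispersion_energy(s, build_neighbor_table(s, 12), NULL),
               "supply h or predict")
})
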