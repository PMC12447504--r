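test_that("combined loss reproduces trivial closed forms", {
  s1 <- atomic_system(rbind(c(0, 0, 0)), 8L)
  batch <- training_batch(list(s1), forces = list(matrix(0, 1, 3)),
                          dipoles = list(c(0, 0, 0)), hirshfeld = list(1))
  perfect <- list(list(forces = matrix(0, 1, 3), dipole = c(0, 0, 0), h = 1))
  expect_equal(combined_loss(batch, perfect)$loss, 0)
  # single atom, force error (1, 0, 0), lambda_F = 1 only -> loss 1
  pred <- list(list(forces = matrix(c(1, 0, 0), 1, 3), dipole = c(0, 0, 0), h = 1))
  expect_equal(combined_loss(batch, pred, loss_weights(1, 0, 0))$loss, 1)
})

test_that("combined loss equals a brute-force triple loop and scales in lambda", {
  set.seed(81)
  systems <- lapply(1:3, function(k) mk_random_system(3 + k, seed = 80 + k))
  B <- 3
  f_true <- lapply(systems, function(s) matrix(rnorm(n_atoms(s) * 3), ncol = 3))
  mu_true <- lapply(1:B, function(b) rnorm(3))
  h_true <- lapply(systems, function(s) runif(n_atoms(s), 0.5, 1))
  preds <- lapply(1:B, function(b) list(
    forces = f_true[[b]] + matrix(rnorm(n_atoms(systems[[b]]) * 3), ncol = 3),
    dipole = mu_true[[b]] + rnorm(3),
    h = h_true[[b]] + rnorm(n_atoms(systems[[b]]), sd = 0.1)))
  batch <- training_batch(systems, f_true, mu_true, h_true)
  w <- loss_weights(0.7, 0.2, 0.1)
  got <- combined_loss(batch, preds, w)
  hand <- 0
  for (b in 1:B) {
    nb <- n_atoms(systems[[b]])
    sf <- 0
    for (i in 1:nb) for (k in 1:3) {
      sf <- sf + (f_true[[b]][i, k] - preds[[b]]$forces[i, k])^2
    }
    hand <- hand + 0.7 / B * sf / nb +
      0.2 / B * sum((mu_true[[b]] - preds[[b]]$dipole)^2) +
      0.1 / B * sum((h_true[[b]] - preds[[b]]$h)^2) / nb
  }
  expect_equal(got$loss, hand, tolerance = 1e-12)
  # linear in lambda
  got2 <- combined_loss(batch, preds, loss_weights(1.4, 0.4, 0.2))
  expect_equal(got2$loss, 2 * got$loss, tolerance = 1e-12)
  # invariant under batch permutation
  perm <- c(3, 1, 2)
  got3 <- combined_loss(training_batch(systems[perm], f_true[perm],
                                       mu_true[perm], h_true[perm]),
                        preds[perm], w)
  expect_equal(got3$loss, got$loss, tolerance = 1e-12)
})

test_that("missing reference channels with nonzero weight raise errors", {
  s <- list(mk_random_system(4, seed = 85))
  batch <- training_batch(s, forces = list(matrix(0, 4, 3)))
  preds <- list(list(forces = matrix(0, 4, 3), dipole = rep(0, 3), h = rep(1, 4)))
  expect_error(combined_loss(batch, preds, loss_weights(1, 0.1, 0)),
               "no reference dipoles")
  expect_error(combined_loss(batch, preds, loss_weights(1, 0, 0.1)),
               "no reference Hirshfeld")
})

test_that("zero-step training leaves the parameters unchanged", {
  m <- test_model()
  batch <- training_batch(list(mk_random_system(4, seed = 86)),
                          forces = list(matrix(0, 4, 3)))
  out <- train_model(m, batch, loss_weights(1, 0, 0), test_config(), n_steps = 0)
  expect_identical(out$model$params, m$params)
})

test_that("force-only training recovers the teacher's energy head", {
  spec <- test_spec()
  teacher <- semilocal_model(spec)
  cfg <- test_config(spec)
  base <- make_topology_fixture("alanine_dipeptide")$system
  structs <- lapply(1:10, function(k) {
    set.seed(300 + k)
    base$positions <- base$positions +
      matrix(rnorm(length(base$positions), sd = 0.06), n_atoms(base), 3)
    base
  })
  batch <- make_labeled_dataset(structs, teacher, cfg)
  fscale <- sqrt(mean(unlist(lapply(batch$forces, function(f) mean(f^2)))))
  student <- teacher
  set.seed(999)
  student$params$wE <- rnorm(spec$features, sd = 0.3 / sqrt(spec$features))
  student$params$bE <- rnorm(8, sd = 0.1)
  out <- train_model(student, batch, loss_weights(1, 0, 0), cfg,
                     n_steps = 250, lr = 0.03)
  # smoothed loss decreases
  sm <- stats::filter(out$history$loss, rep(1 / 20, 20), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_lt(sm[length(sm)], 0.05 * sm[1])
  # force RMSE well under 10% of the label scale
  rmse <- sqrt(mean(unlist(lapply(seq_along(structs), function(b) {
    (evaluate_potential(structs[[b]], out$model, cfg)$forces -
       batch$forces[[b]])^2
  }))))
  expect_lt(rmse / fscale, 0.1)
  # relative conformer energies recovered; absolute offset not asserted
  e_t <- vapply(structs, function(s) evaluate_potential(s, teacher, cfg)$e_pot,
                numeric(1))
  e_s <- vapply(structs, function(s) evaluate_potential(s, out$model, cfg)$e_pot,
                numeric(1))
  expect_lt(max(abs((e_t - e_t[1]) - (e_s - e_s[1]))), 0.05)
  # determinism: the same call reproduces the same history
  out2 <- train_model(student, batch, loss_weights(1, 0, 0), cfg,
                      n_steps = 250, lr = 0.03)
  expect_identical(out$history$loss, out2$history$loss)
})

test_that("dipole-only training pulls predicted dipoles toward the references", {
  spec <- test_spec()
  teacher <- semilocal_model(spec)
  cfg <- test_config(spec)
  structs <- lapply(1:6, function(k) make_water_cluster(2, seed = 20 + k))
  batch <- make_labeled_dataset(structs, teacher, cfg)
  student <- teacher
  set.seed(77)
  student$params$wq <- rnorm(spec$features, sd = 0.1 / sqrt(spec$features))
  student$params$bq <- rnorm(8, sd = 0.05)
  err <- function(m) mean(vapply(seq_along(structs), function(b) {
    q <- project_charges(predict_atomic(m, structs[[b]])$q_raw, 0)
    sqrt(sum((dipole_from_charges(structs[[b]], q) - batch$dipoles[[b]])^2))
  }, numeric(1)))
  e0 <- err(student)
  out <- train_model(student, batch, loss_weights(0, 1, 0), cfg,
                     n_steps = 300, lr = 0.05)
  expect_lt(err(out$model), 0.05 * e0)
})

test_that("damping calibration recovers the generating hyperparameters", {
  spec <- test_spec()
  m <- semilocal_model(spec)
  w <- make_topology_fixture("water")$system
  scan <- make_dimer_scan(w, w, c(2.8, 3.2, 3.6, 4.2, 5.0))
  cfg_true <- test_config(spec, gamma = 1.2, sigma = 0.8)
  e1 <- evaluate_potential(scan$monomer1, m, cfg_true)$e_pot
  e2 <- evaluate_potential(scan$monomer2, m, cfg_true)$e_pot
  refs <- vapply(scan$dimers, function(d) {
    evaluate_potential(d, m, cfg_true)$e_pot - e1 - e2
  }, numeric(1))
  cal <- calibrate_damping(list(scan), list(refs), m, test_config(spec),
                           gamma_grid = seq(0.8, 1.6, 0.2),
                           sigma_grid = seq(0.4, 1.2, 0.2))
  expect_equal(cal$gamma, 1.2)
  expect_equal(cal$sigma, 0.8)
  # single candidate grid point is returned as-is
  one <- calibrate_damping(list(scan), list(refs), m, test_config(spec),
                           gamma_grid = 0.9, sigma_grid = 1.1)
  expect_equal(one$gamma, 0.9)
  expect_equal(one$sigma, 1.1)
})

test_that("calibration ties break toward the smallest gamma then sigma", {
  spec <- test_spec()
  m <- semilocal_model(spec)
  w <- make_topology_fixture("water")$system
  scan <- make_dimer_scan(w, w, c(250, 300))   # beyond all cutoffs
  refs <- list(c(0, 0))                        # every grid point is exact
  cal <- calibrate_damping(list(scan), refs, m, test_config(spec),
                           gamma_grid = c(1.0, 0.8), sigma_grid = c(1.2, 0.6))
  expect_equal(cal$gamma, 0.8)
  expect_equal(cal$sigma, 0.6)
  expect_error(calibrate_damping(list(), list(), m, test_config(spec)), "empty")
  short <- list(dimers = scan$dimers[1], monomer1 = scan$monomer1,
                monomer2 = scan$monomer2)
  expect_error(calibrate_damping(list(short), refs, m, test_config(spec)),
               ">= 2 separations")
})
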