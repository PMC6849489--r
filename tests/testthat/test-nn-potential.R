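# Descriptor, network training, analytic forces and hyperparameter search.

test_that("inverse-distance descriptor has the fixed pair order and invariances", {
  sp <- descriptor_spec("inverse_distance", 9)
  x <- c(0, 0, 0, 1, 0, 0, 3, 0, 0)  # collinear at 0, 1, 3 Bohr
  d <- compute_descriptor(sp, x)
  expect_equal(d$values, c(1, 1 / 3, 1 / 2))

  # rigid rotation and translation leave it unchanged
  set.seed(1)
  x2 <- flatten_coords(triatomic_geometry(2.3, 2.9, 2.5))
  th <- 0.7
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xm <- matrix(x2, 3, 3, byrow = TRUE)
  xrot <- as.vector(t(xm %*% Rz))
  xtrans <- as.vector(t(sweep(xm, 2, c(1.1, -0.4, 2.2), "+")))
  expect_lt(max(abs(compute_descriptor(sp, xrot)$values - compute_descriptor(sp, x2)$values)), 1e-12)
  expect_lt(max(abs(compute_descriptor(sp, xtrans)$values - compute_descriptor(sp, x2)$values)), 1e-12)

  # analytic Jacobian vs finite differences
  h <- 1e-6
  J <- compute_descriptor(sp, x2)$jacobian
  for (k in 1:9) {
    xp <- x2; xp[k] <- xp[k] + h
    xmn <- x2; xmn[k] <- xmn[k] - h
    fd <- (compute_descriptor(sp, xp)$values - compute_descriptor(sp, xmn)$values) / (2 * h)
    expect_lt(max(abs(J[, k] - fd)), 1e-6)
  }

  expect_error(compute_descriptor(sp, c(0, 0, 0, 1e-5, 0, 0, 3, 0, 0)),
               "coincident")
})

test_that("training loss gradient matches finite differences (incl. force term)", {
  ds <- three_state_dataset(n = 40)
  ts <- training_set(ds, 0.15, seed = 2)
  ns <- asNamespace("mlphotodyn")
  spec <- ns$descriptor_spec("coordinate", 1L)
  mtr <- ns$build_matrices(ts$records[ts$split$train], spec)
  norm <- ns$compute_norm(mtr)
  dat <- ns$standardize_data(mtr, norm)
  hd <- list(energy = mtr$nS, nac = mtr$nP, dip = ncol(mtr$DIP))
  params <- ns$init_params(spec$n_in, c(7, 5), hd, seed = 3)
  w <- list(energy = 1, force = 0.7, nac = 0.3, dipole = 0.2, soc = 0.1)
  lg <- ns$nn_loss_grad(params, dat, w, norm$g_scale, want_grad = TRUE)
  vec <- unlist(params)
  gvec <- unlist(lg$grad)
  h <- 1e-6
  idx <- round(seq(1, length(vec), length.out = 60))
  for (k in idx) {
    pv <- vec; pv[k] <- pv[k] + h
    pm <- vec; pm[k] <- pm[k] - h
    fd <- (ns$nn_loss_grad(utils::relist(pv, params), dat, w, norm$g_scale, FALSE)$total -
           ns$nn_loss_grad(utils::relist(pm, params), dat, w, norm$g_scale, FALSE)$total) / (2 * h)
    expect_lt(abs(fd - gvec[k]), 1e-7)
  }
})

test_that("a large-capacity network memorizes a small dataset", {
  ds <- three_state_dataset(n = 40)
  small <- new_dataset(ds$header, ds$records[seq(1, 40, by = 4)])
  ts <- training_set(small, 0.2, seed = 1)
  # deliberate overfit: early stopping off, long annealed run, judge the
  # train split
  mod <- train_nn(ts, list(hidden = c(60, 60), epochs = 20000, lr = 1e-2,
                           lr_decay = 0.003, early_stopping = FALSE), seed = 2)
  expect_lt(mod$train_rmse[["energy"]], 1e-4)
})

test_that("training is deterministic for a fixed seed", {
  ds <- three_state_dataset(n = 40)
  ts <- training_set(ds, 0.15, seed = 2)
  hp <- list(hidden = c(10, 10), epochs = 200)
  m1 <- train_nn(ts, hp, seed = 9)
  m2 <- train_nn(ts, hp, seed = 9)
  expect_identical(m1$val_rmse, m2$val_rmse)
  expect_identical(m1$params, m2$params)
})

test_that("predictions are deterministic and descriptor-invariant", {
  mod <- triatomic_nn()
  x <- flatten_coords(triatomic_geometry(2.5, 2.7, 2.6))
  p1 <- eval_properties(mod, x)
  p2 <- eval_properties(mod, x)
  expect_identical(p1, p2)
  xm <- matrix(x, 3, 3, byrow = TRUE)
  xtrans <- as.vector(t(sweep(xm, 2, c(0.3, 1.2, -0.7), "+")))
  expect_lt(max(abs(eval_properties(mod, xtrans)$energies - p1$energies)), 1e-12)
})

test_that("analytic forces are the exact gradient of the predicted energy", {
  mod <- triatomic_nn()
  set.seed(8)
  h <- 1e-4
  for (rep in 1:5) {
    x <- random_triatomic_x()
    G <- analytic_forces(mod, x)
    FD <- matrix(0, 2, 9)
    for (k in 1:9) {
      xp <- x; xp[k] <- xp[k] + h
      xm <- x; xm[k] <- xm[k] - h
      FD[, k] <- (eval_properties(mod, xp)$energies - eval_properties(mod, xm)$energies) / (2 * h)
    }
    for (s in 1:2)
      expect_lt(sqrt(sum((G[s, ] - FD[s, ])^2) / sum(FD[s, ]^2)), 1e-5)
    # translational/rotational invariance: zero net force and torque
    for (s in 1:2) {
      Gm <- matrix(G[s, ], 3, 3, byrow = TRUE)
      expect_lt(max(abs(colSums(Gm))), 1e-10)
      xm3 <- matrix(x, 3, 3, byrow = TRUE)
      tq <- colSums(cbind(xm3[, 2] * Gm[, 3] - xm3[, 3] * Gm[, 2],
                          xm3[, 3] * Gm[, 1] - xm3[, 1] * Gm[, 3],
                          xm3[, 1] * Gm[, 2] - xm3[, 2] * Gm[, 1]))
      expect_lt(max(abs(tq)), 1e-10)
    }
  }
})

test_that("the NN force field is conservative (closed-loop work ~ 0)", {
  mod <- three_state_nn()
  # work integral of state-1 force around a closed loop in R
  path <- c(seq(0.5, 1.5, length.out = 400), seq(1.5, 0.5, length.out = 400))
  g <- vapply(path, function(x) eval_properties(mod, x)$gradients[1, 1], numeric(1))
  work <- sum((g[-1] + g[-length(g)]) / 2 * diff(path))
  expect_lt(abs(work), 1e-8)
})

test_that("force-loss weighting improves held-out gradients", {
  ds <- three_state_dataset(n = 80)
  ts <- training_set(ds, 0.2, seed = 4)
  hp0 <- list(hidden = c(24, 24), epochs = 1200, weights = list(force = 0))
  hp1 <- list(hidden = c(24, 24), epochs = 1200, weights = list(force = 1))
  m0 <- train_nn(ts, hp0, seed = 6)
  m1 <- train_nn(ts, hp1, seed = 6)
  expect_lt(m1$val_rmse[["force"]], m0$val_rmse[["force"]])
})

test_that("random grid search ranks candidates and is reproducible", {
  ds <- three_state_dataset(n = 40)
  ts <- training_set(ds, 0.2, seed = 3)
  space <- list(hidden = list(c(24, 24), c(1, 1)), epochs = list(400))
  r1 <- random_grid_search(ts, space, n_trials = 4, seed = 2)
  r2 <- random_grid_search(ts, space, n_trials = 4, seed = 2)
  expect_identical(r1$trials$val_energy_rmse, r2$trials$val_energy_rmse)
  # the degenerate width-1 trunk cannot win against the real architecture
  expect_equal(unlist(r1$best_hyperparams$hidden), c(24, 24))
  one <- random_grid_search(ts, list(hidden = list(c(8, 8)), epochs = list(150)),
                            n_trials = 1, seed = 1)
  expect_equal(nrow(one$trials), 1)
  expect_error(random_grid_search(ts, list(), 2), "empty")
})

test_that("validation error decreases with training-set size on average", {
  sizes <- c(30, 120)
  err <- vapply(sizes, function(n) {
    ds <- three_state_dataset(n = 240)
    sub <- new_dataset(ds$header,
                       ds$records[round(seq(1, 240, length.out = n))])
    ts <- training_set(sub, 0.2, seed = 1)
    mean(vapply(1:2, function(s)
      train_nn(ts, list(hidden = c(24, 24), epochs = 1200),
               seed = s)$val_rmse[["energy"]], numeric(1)))
  }, numeric(1))
  expect_lt(err[2], err[1])
})
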