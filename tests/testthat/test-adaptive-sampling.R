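# Normal-mode initial sets, ensemble disagreement, threshold schedule and
# the adaptive loop.

test_that("normal-mode scan recovers the analytic frequency and counts", {
  m <- model_three_state()
  k <- m$params$k
  mass <- m$params$mass
  hess <- numerical_hessian(m, 0, 1)
  scan <- normal_mode_scan(0, hess, mass, amplitudes = c(-1, 0, 1))
  omega_ref <- sqrt(k / mass)
  # numerical Hessian of the coupled ground state differs from the bare
  # diabat by the coupling-induced curvature; compare against the exact
  # second derivative instead
  h <- 1e-3
  d2 <- (eval_properties(m, h)$energies[1] - 2 * eval_properties(m, 0)$energies[1] +
         eval_properties(m, -h)$energies[1]) / h^2
  expect_equal(scan$omega[1], sqrt(d2 / mass), tolerance = 1e-6)
  expect_equal(length(scan$geometries), 3)

  # amplitude grid {0}: just the (deduplicated) equilibrium
  scan0 <- normal_mode_scan(0, hess, mass, amplitudes = 0)
  expect_equal(length(scan0$geometries), 1)
  expect_equal(scan0$geometries[[1]], 0)

  # counting bound on a Cartesian model: <= n_amp * n_modes (+ equilibrium)
  mc <- model_conical_triatomic()
  x0 <- flatten_coords(triatomic_geometry(2.6, 2.6, 2.2))
  hc <- numerical_hessian(mc, x0, 1)
  amps <- c(-1.5, -0.5, 0, 0.5, 1.5)
  sc <- normal_mode_scan(x0, hc, mc$masses, amps)
  n_modes <- length(sc$omega)
  expect_equal(n_modes, 3)  # triatomic: 3N - 6 = 3 vibrations
  expect_lte(length(sc$geometries), length(amps) * n_modes)

  # pure translations: no vibrational modes at all
  expect_error(normal_mode_scan(x0, matrix(0, 9, 9), mc$masses, 0), "no vibrational")
})

test_that("disagreement is the pooled RMS deviation from the member mean", {
  mk <- function(e) elecprops(e, matrix(0, length(e), 1),
                              matrix(0, length(e) * (length(e) - 1) / 2, 1))
  expect_equal(unname(disagreement(list(mk(c(0, 1)), mk(c(0, 1))))["energies"]), 0)
  d <- disagreement(list(mk(0), mk(0.01)))
  expect_equal(unname(d["energies"]), 0.005)
  d3 <- disagreement(list(mk(0), mk(0), mk(3)))
  expect_equal(unname(d3["energies"]), sqrt(2))
  expect_error(disagreement(list(mk(0))), "at least two")
})

test_that("threshold schedule decays by exactly 0.95 per pre-freeze trigger and freezes", {
  sched <- threshold_schedule(c(energies = 1e-3, gradients = 1e-2),
                              decay = 0.95, freeze_time_fs = 1e4)
  theta0 <- sched$thresholds
  # below thresholds: trusted, unchanged
  r <- check_and_adapt(c(energies = 1e-4, gradients = 1e-3), sched, 100)
  expect_equal(r$decision, "trusted")
  expect_identical(r$schedule$thresholds, theta0)

  # k pre-freeze triggers: theta = theta0 * 0.95^k exactly
  k <- 7
  for (i in seq_len(k))
    sched <- check_and_adapt(c(energies = 1, gradients = 0), sched, 1000 * i)$schedule
  expect_equal(sched$thresholds, theta0 * 0.95^k, tolerance = 1e-14)
  expect_equal(sched$n_triggers, k)

  # past the freeze time thresholds are kept, but retraining is still needed
  r2 <- check_and_adapt(c(energies = 1, gradients = 0), sched, 1.1e4)
  expect_equal(r2$decision, "retrain_needed")
  expect_identical(r2$schedule$thresholds, theta0 * 0.95^k)

  # any single violated property triggers even if the others are reliable
  r3 <- check_and_adapt(c(energies = 0, gradients = 1), sched, 10)
  expect_equal(r3$decision, "retrain_needed")
  expect_equal(r3$violated, "gradients")
})

test_that("infinite thresholds yield zero provider calls", {
  m <- model_three_state()
  hess <- numerical_hessian(m, 0, 1)
  scan <- normal_mode_scan(0, hess, m$masses, seq(-3, 3, by = 1))
  ds <- evaluate_dataset(m, scan$geometries, source = "normal_mode")
  ts <- training_set(ds, 0.3, seed = 1)
  res <- adaptive_run(ts, m, config = list(
    n_traj = 1, t_max_fs = 10, initial_state = 3,
    sampling = list(type = "wigner", x_eq = 0, hessian = hess),
    hyperparams = list(hidden = c(8, 8), epochs = 100),
    thresholds = c(energies = Inf, gradients = Inf, nacs = Inf)), seed = 2)
  expect_equal(res$n_added, 0)
  expect_equal(length(res$training_set$records), length(ds$records))
})

test_that("adaptive loop converges on the 1-D model and passes a replay audit", {
  m <- model_three_state()
  hess <- numerical_hessian(m, 0, 1)
  scan <- normal_mode_scan(0, hess, m$masses, seq(-3, 3, by = 1))
  ds <- evaluate_dataset(m, scan$geometries, source = "normal_mode")
  ts <- training_set(ds, 0.3, seed = 1)
  res <- adaptive_run(ts, m, config = list(
    n_traj = 3, dt_fs = 0.5, t_max_fs = 50, initial_state = 3,
    sampling = list(type = "wigner", x_eq = 0, hessian = hess),
    hyperparams = list(hidden = c(32, 32), epochs = 1000, eval_every = 20),
    freeze_time_fs = 60, max_new_points = 60, max_restarts = 40,
    min_clear_streak = 3, validation_fraction = 0.2), seed = 3)
  # the training set grew, every appended record is phase-logged, and the
  # event log records each addition
  expect_gt(res$n_added, 0)
  added <- res$training_set$records[-seq_along(ds$records)]
  expect_true(all(vapply(added, function(r) r$source == "adaptive", logical(1))))
  expect_true(all(vapply(added, function(r) !is.null(r$phase), logical(1))))
  expect_equal(sum(res$events$action == "added+retrained"), res$n_added)
  # threshold bookkeeping matches the exact decay law
  pre <- sum(res$schedule$history$triggered &
             res$schedule$history$time_fs < 60)
  theta0 <- initial_thresholds(
    train_ensemble(ts, list(hidden = c(32, 32), epochs = 1000, eval_every = 20),
                   2, seed = 3), 3)
  expect_equal(res$schedule$thresholds, theta0 * 0.95^pre, tolerance = 1e-12)

  # replay audit: fresh trajectories with the final ensemble exceed the
  # final thresholds at fewer than 1% of steps
  thr <- res$schedule$thresholds
  exceed <- 0; total <- 0
  for (k in 1:3) {
    init <- initialize_trajectory(res$ensemble,
                                  list(type = "wigner", x_eq = 0, hessian = hess),
                                  3, seed = 9000 + k)
    run_trajectory(res$ensemble, init, dt_fs = 0.5, t_max_fs = 50,
                   seed = 9000 + k,
                   monitor = function(t_fs, x, p) {
                     total <<- total + 1
                     common <- intersect(names(thr), names(p$disagreement))
                     if (any(p$disagreement[common] > thr[common]))
                       exceed <<- exceed + 1
                     FALSE
                   })
  }
  expect_lt(exceed / total, 0.01)
})
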