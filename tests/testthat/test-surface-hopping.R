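# FSSH driver: nuclear integrator, electronic propagator, hop machinery,
# trajectory-level conservation laws.

aut_per_fs <- 1 / au_units()[["fs_per_aut"]]

test_that("initialization sets coefficients and reproducible initial conditions", {
  m <- model_three_state()
  init <- initialize_trajectory(m, list(type = "fixed", x = 0.2, v = 0.001), 3)
  expect_equal(init$coeff, complex(real = c(0, 0, 1)))
  expect_equal(init$active, 3L)

  hess <- numerical_hessian(m, 0, 1)
  i1 <- initialize_trajectory(m, list(type = "wigner", x_eq = 0, hessian = hess), 3, seed = 5)
  i2 <- initialize_trajectory(m, list(type = "wigner", x_eq = 0, hessian = hess), 3, seed = 5)
  expect_identical(i1, i2)
  expect_error(initialize_trajectory(m, list(type = "nope"), 1), "unknown sampling")
  expect_error(initialize_trajectory(m, list(type = "fixed", x = 0), 9), "invalid initial state")
})

test_that("Wigner sampling reproduces the harmonic ground-state width", {
  m <- model_three_state()
  k <- m$params$k
  mass <- m$params$mass
  omega <- sqrt(k / mass)
  hess <- matrix(k, 1, 1)
  draws <- withr::with_seed(11, wigner_sample(0, hess, mass, n = 10000))
  xs <- vapply(draws, function(d) d$x, numeric(1))
  vs <- vapply(draws, function(d) d$v, numeric(1))
  expect_lt(abs(stats::var(xs) - 1 / (2 * mass * omega)) / (1 / (2 * mass * omega)), 0.05)
  expect_lt(abs(stats::var(vs) - omega / (2 * mass)) / (omega / (2 * mass)), 0.05)
})

test_that("velocity Verlet: free motion exact, harmonic period and dt^2 drift", {
  m <- model_three_state()
  mass <- m$params$mass
  omega <- sqrt(m$params$k / mass)
  period_fs <- 2 * pi / omega * au_units()[["fs_per_aut"]]

  # uncoupled flat surface: uniform linear motion
  flat <- diabatic_model("flat", 2, 1, function(x)
    list(H = diag(c(0, 1)), dH = array(0, c(2, 2, 1))), masses = mass)
  init <- initialize_trajectory(flat, list(type = "fixed", x = 0, v = 1e-3), 1)
  tr <- run_trajectory(flat, init, dt_fs = 0.5, t_max_fs = 50, seed = 1)
  t_end <- tr$frames$time_fs[nrow(tr$frames)]
  expect_equal(tr$final$x, 1e-3 * t_end * aut_per_fs, tolerance = 1e-12)

  # harmonic oscillation on the ground state: one period returns the start
  init <- initialize_trajectory(m, list(type = "fixed", x = 0.4, v = 0), 1)
  dt <- period_fs / 1000
  tr <- run_trajectory(m, init, dt_fs = dt, t_max_fs = period_fs, seed = 1)
  expect_lt(abs(tr$final$x - 0.4) / 0.4, 1e-3)

  # energy drift scales as dt^2
  drift <- function(dt_fs) {
    init <- initialize_trajectory(m, list(type = "fixed", x = 0.5, v = 0.001), 1)
    tr <- run_trajectory(m, init, dt_fs = dt_fs, t_max_fs = 50, seed = 1)
    max(abs(tr$frames$etot - tr$frames$etot[1]))
  }
  d1 <- drift(0.5)
  d2 <- drift(0.25)
  expect_lt(d2 / d1, 0.35)   # ~0.25 expected for a second-order integrator
  expect_gt(d2 / d1, 0.15)
})

test_that("electronic propagation: free phases, Rabi oscillation, unitarity", {
  # no coupling: populations constant, phases advance by -E dt
  c0 <- complex(real = c(sqrt(0.3), sqrt(0.7)))
  E <- c(0.1, 0.25)
  dt <- 10
  es <- electronic_step(c0, E, E, matrix(0, 2, 2), matrix(0, 2, 2), dt,
                        active = 2, n_substeps = 7)
  expect_equal(Mod(es$coeff)^2, Mod(c0)^2, tolerance = 1e-12)
  rel <- es$coeff[2] / es$coeff[1]
  expect_equal(Arg(rel), Arg(c0[2] / c0[1]) - (E[2] - E[1]) * dt, tolerance = 1e-10)

  # degenerate two-level with constant coupling: P2 = sin^2(kappa t)
  kappa <- 0.02
  VD <- vd_mat(2, 1, 2, kappa)
  cc <- complex(real = c(1, 0))
  tt <- 40
  es2 <- electronic_step(cc, c(0, 0), c(0, 0), VD, VD, tt, 1, n_substeps = 50)
  expect_equal(Mod(es2$coeff[2])^2, sin(kappa * tt)^2, tolerance = 1e-8)

  # norm conservation over many substeps
  es3 <- electronic_step(cc, c(0.05, 0.2), c(0.05, 0.2), VD, VD, 1000, 1,
                         n_substeps = 1e4)
  expect_lt(abs(sum(Mod(es3$coeff)^2) - 1), 1e-8)
})

test_that("hop probabilities follow the fewest-switches formula", {
  # all population on the active state: zero probability everywhere
  c0 <- complex(real = c(1, 0, 0))
  VD <- matrix(0.01, 3, 3); VD[lower.tri(VD)] <- -0.01; diag(VD) <- 0
  expect_equal(hop_probabilities(c0, VD, 1, 1), rep(0, 3))

  # negative flux clips to zero
  c1 <- complex(real = c(sqrt(0.5), sqrt(0.5)))
  g <- hop_probabilities(c1, vd_mat(2, 1, 2, -0.01), 1, 1)
  expect_equal(g[2], 0)
  # positive flux matches the closed form
  g2 <- hop_probabilities(c1, vd_mat(2, 1, 2, 0.01), 1, 1)
  expect_equal(g2[2], 2 * 1 * 0.5 * 0.01 / 0.5)
})

test_that("frozen-coefficient hop counts match the integrated flux (binomial)", {
  # fixed coefficients and coupling; draw many single-step hops
  c0 <- complex(real = c(sqrt(0.8), sqrt(0.2)))
  vd <- vd_mat(2, 1, 2, 0.004)
  dt <- 1
  g <- hop_probabilities(c0, vd, dt, 1)
  n <- 1e4
  hops <- withr::with_seed(21, {
    sum(vapply(seq_len(n), function(i) {
      r <- attempt_hop(1, g, c(0, 0), v = 1, masses_au = 2000, time_fs = 0)
      !is.null(r$event) && r$event$outcome == "accepted"
    }, logical(1)))
  })
  p <- g[2]
  expect_lt(abs(hops / n - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("hops respect energy conservation and frustration", {
  mass <- 2000
  # probability 1 to a lower state: accepted, kinetic energy increases by -dE
  r <- withr::with_seed(2, attempt_hop(2, c(1, 0), energies = c(-0.01, 0),
                                       v = 0.002, masses_au = mass, time_fs = 1))
  expect_equal(r$active, 1L)
  ke0 <- 0.5 * mass * 0.002^2
  ke1 <- 0.5 * mass * r$v^2
  expect_equal(ke1 - ke0, 0.01, tolerance = 1e-12)

  # forbidden uphill hop: frustrated, velocities unchanged
  r2 <- withr::with_seed(2, attempt_hop(1, c(0, 1), energies = c(0, 1),
                                        v = 0.002, masses_au = mass, time_fs = 1))
  expect_equal(r2$active, 1L)
  expect_equal(r2$v, 0.002)
  expect_equal(r2$event$outcome, "frustrated")

  # zero probabilities: no event at all
  r3 <- attempt_hop(1, c(0, 0), c(0, 1), 0.002, mass, 1)
  expect_null(r3$event)
})

test_that("velocity rescaling handles the zero and projected cases", {
  mass <- rep(2000, 3)
  v <- c(0.001, 0, 0)
  expect_equal(rescale_velocity(v, mass, 0), v)
  # projected rescaling with zero velocity along the direction: frustrated
  expect_null(rescale_velocity(v, mass, 1e-4, direction = c(0, 1, 0)))
})

test_that("trajectories are bit-reproducible and conserve norm", {
  ens <- three_state_ensemble()
  hess <- numerical_hessian(model_three_state(), 0, 1)
  samp <- list(type = "wigner", x_eq = 0, hessian = hess)
  i1 <- initialize_trajectory(ens, samp, 3, seed = 4)
  t1 <- run_trajectory(ens, i1, dt_fs = 0.5, t_max_fs = 30, seed = 4)
  t2 <- run_trajectory(ens, initialize_trajectory(ens, samp, 3, seed = 4),
                       dt_fs = 0.5, t_max_fs = 30, seed = 4)
  expect_identical(t1$frames, t2$frames)
  expect_lt(max(abs(t1$frames$norm - 1)), 1e-8)
})

test_that("zero-coupling dynamics never hops; t_max = 0 keeps only frame 0", {
  m <- model_avoided_crossing(C = 0)
  init <- initialize_trajectory(m, list(type = "fixed", x = -1.5, v = 0.003), 2)
  tr <- run_trajectory(m, init, dt_fs = 0.5, t_max_fs = 100, seed = 3)
  expect_true(all(tr$frames$active == 2))
  expect_equal(length(tr$hops), 0)

  tr0 <- run_trajectory(m, init, dt_fs = 0.5, t_max_fs = 0, seed = 3)
  expect_equal(nrow(tr0$frames), 1)
})

test_that("population tables partition to one and scale as root-n", {
  m <- model_three_state()
  hess <- numerical_hessian(m, 0, 1)
  samp <- list(type = "wigner", x_eq = 0, hessian = hess)
  one <- run_ensemble_of_trajectories(m, 1, samp, 3, t_max_fs = 20, seed = 2)
  pops <- as.matrix(one$populations[, c("n_S0", "n_S1", "n_S2")])
  expect_true(all(pops %in% c(0, 1)))
  expect_equal(unname(rowSums(pops)), rep(1, nrow(pops)))
})
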