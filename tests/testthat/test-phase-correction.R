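# Wavefunction-phase tracking and sign correction of off-diagonal
# electronic properties.

test_that("overlap matrix reflects sign flips and rotations", {
  U <- diag(3)
  expect_equal(overlap(U, U), diag(3))
  Ub <- U; Ub[, 2] <- -Ub[, 2]
  expect_equal(diag(overlap(U, Ub)), c(1, -1, 1))
  th <- pi / 2
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_lt(max(abs(diag(overlap(diag(2), rot)))), 1e-12)
  expect_error(overlap(diag(2), diag(3)), "dimension")
})

test_that("detect_phases decides by threshold and leaves mixed states undecided", {
  p <- detect_phases(diag(c(0.99, -0.98)), 0.5)
  expect_equal(p$signs, c(1L, -1L))
  expect_true(all(p$decided))

  p2 <- detect_phases(diag(c(0.99, 0.1)), 0.5)
  expect_true(p2$decided[1])
  expect_false(p2$decided[2])

  p3 <- detect_phases(diag(c(0.3, -0.01)), 0)  # threshold 0: sign alone decides
  expect_true(all(p3$decided))
  expect_equal(p3$signs, c(1L, -1L))
})

test_that("apply_phase is the identity for +1, flips pairs, and is an involution", {
  m <- model_three_state()
  props <- eval_properties(m, 0.9)
  expect_identical(apply_phase(props, phase_vector(c(1, 1, 1))), props)

  p <- phase_vector(c(1, -1, 1))
  flipped <- apply_phase(props, p)
  expect_equal(flipped$energies, props$energies)
  expect_equal(flipped$gradients, props$gradients)
  expect_equal(flipped$nacs[1, ], -props$nacs[1, ])  # pair (1,2)
  expect_equal(flipped$nacs[2, ], props$nacs[2, ])   # pair (1,3)
  expect_equal(flipped$nacs[3, ], -props$nacs[3, ])  # pair (2,3)
  expect_equal(flipped$dipoles[1, 2, 1], -props$dipoles[1, 2, 1])
  expect_equal(diag(flipped$dipoles[, , 1]), diag(props$dipoles[, , 1]))
  expect_identical(apply_phase(flipped, p), props)

  expect_error(apply_phase(props, phase_vector(c(1, NA, 1))), "undecided")
})

test_that("track_phases composes segment phases across bisection", {
  det <- model_avoided_crossing()
  p0 <- track_phases(0.1, 0.1, det)
  expect_equal(p0$signs, c(1L, 1L))
  # widely separated geometries across the crossing need bisection but must
  # compose to the relative sign of the deterministic convention endpoints
  pw <- track_phases(-2, 2, det, max_bisections = 12)
  expect_true(all(pw$decided))
  Ua <- eval_properties(det, -2)$eigvecs
  Ub <- eval_properties(det, 2)$eigvecs
  # prediction from dense direct tracking: chain tiny steps
  xs <- seq(-2, 2, length.out = 200)
  sg <- c(1L, 1L)
  Uprev <- Ua
  for (x in xs[-1]) {
    Un <- eval_properties(det, x)$eigvecs
    sg <- sg * detect_phases(overlap(Uprev, Un), 0.5)$signs
    Uprev <- Un
  }
  expect_equal(pw$signs, sg)
})

test_that("phase tracking through a randomizing provider cancels midpoint signs", {
  rnd <- model_avoided_crossing(randomize_phase = TRUE, phase_seed = 13)
  det <- model_avoided_crossing()
  # endpoints from stored (deterministic) eigenvectors; midpoints evaluated
  # through the randomizing provider: the random midpoint signs must cancel
  Ua <- eval_properties(det, -1.2)$eigvecs
  Ub <- eval_properties(det, 1.2)$eigvecs
  p1 <- track_phases(-1.2, 1.2, rnd, eigvecs_ref = Ua, eigvecs_new = Ub,
                     max_bisections = 12)
  p2 <- track_phases(-1.2, 1.2, det, eigvecs_ref = Ua, eigvecs_new = Ub,
                     max_bisections = 12)
  expect_equal(p1$signs, p2$signs)
})

test_that("tracking failure names the undecided states", {
  det <- model_avoided_crossing()
  expect_error(track_phases(-2, 2, det, max_bisections = 0),
               "undecided states")
})

test_that("dataset phase correction restores smooth coupling curves", {
  ds <- three_state_dataset()  # randomized then corrected (helper)
  det <- model_three_state()
  xs <- vapply(ds$records, function(r) r$x, numeric(1))
  # independent oracle: deterministic-provider curves made sign-continuous by
  # chaining nearest-neighbor eigenvector overlaps along the scan (the fixed
  # largest-component convention itself flips at the crossings)
  smooth_ref <- smooth_reference_curves(det, xs)
  for (pair in 1:3) {
    corrected <- vapply(ds$records, function(r) r$props$nacs[pair, 1], numeric(1))
    reference <- smooth_ref$nacs[, pair]
    s <- sign(sum(corrected * reference))   # one global sign is unobservable
    expect_lt(max(abs(corrected - s * reference)), 1e-10)
  }
})

test_that("phase correction is idempotent and handles a single record", {
  det <- model_three_state()
  rnd <- model_three_state(randomize_phase = TRUE, phase_seed = 31)
  ds <- evaluate_dataset(rnd, as.list(seq(-0.5, 2.5, length.out = 15)))
  once <- phase_correct_dataset(ds, det)
  twice <- phase_correct_dataset(once, det)
  for (r in seq_along(ds$records))
    expect_equal(twice$records[[r]]$props$nacs, once$records[[r]]$props$nacs)

  one <- evaluate_dataset(det, list(0.7))
  cone <- phase_correct_dataset(one, det)
  expect_equal(cone$records[[1]]$phase, c(1L, 1L, 1L))
  expect_equal(cone$records[[1]]$props$nacs, one$records[[1]]$props$nacs)
})

test_that("diagonal observables are bit-identical through correction", {
  ds_raw <- local({
    m <- model_three_state(randomize_phase = TRUE, phase_seed = 21)
    evaluate_dataset(m, as.list(seq(0, 2, length.out = 25)))
  })
  corr <- phase_correct_dataset(ds_raw, model_three_state())
  for (r in seq_along(ds_raw$records)) {
    expect_identical(corr$records[[r]]$props$energies,
                     ds_raw$records[[r]]$props$energies)
    expect_identical(corr$records[[r]]$props$gradients,
                     ds_raw$records[[r]]$props$gradients)
    expect_identical(diag(corr$records[[r]]$props$dipoles[, , 1]),
                     diag(ds_raw$records[[r]]$props$dipoles[, , 1]))
  }
})
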