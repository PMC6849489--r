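# Shared fixtures: bundled models and small trained networks, built once per
# test run and cached in this environment (training is deterministic, so the
# cache only saves time, never changes results).

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# Dense 1-D scan dataset of the three-state decay model, phase-randomized
# then phase-corrected -- the canonical training input.
three_state_dataset <- function(n = 240, randomize = TRUE) {
  cached(sprintf("ts3_ds_%d_%d", n, randomize), {
    m <- model_three_state(randomize_phase = randomize, phase_seed = 11)
    ds <- evaluate_dataset(m, as.list(seq(-1.5, 4.8, length.out = n)),
                           source = "normal_mode")
    phase_correct_dataset(ds, model_three_state())
  })
}

# A small but accurate NN on the three-state model.
three_state_nn <- function() {
  cached("ts3_nn", {
    ts <- training_set(three_state_dataset(), 0.1, seed = 5)
    train_nn(ts, list(hidden = c(40, 40), epochs = 2500), seed = 1)
  })
}

three_state_ensemble <- function() {
  cached("ts3_ens", {
    ts <- training_set(three_state_dataset(), 0.1, seed = 5)
    train_ensemble(ts, list(hidden = c(40, 40), epochs = 2500), 2, seed = 1)
  })
}

# Triatomic CI model: internal-coordinate grid plus near-seam enrichment.
triatomic_dataset <- function() {
  cached("tri_ds", {
    mc <- model_conical_triatomic()
    set.seed(3)
    g <- expand.grid(r1 = seq(2.2, 3.0, length.out = 6),
                     r2 = seq(2.2, 3.0, length.out = 6),
                     r3 = seq(2.0, 3.3, length.out = 7))
    geoms <- lapply(seq_len(nrow(g)), function(i) {
      r <- as.numeric(g[i, ]) + runif(3, -0.04, 0.04)
      flatten_coords(triatomic_geometry(r[1], r[2], r[3]))
    })
    near <- lapply(1:140, function(i) {
      r <- mc$params$meci_internal + rnorm(3, 0, 0.12)
      flatten_coords(triatomic_geometry(r[1], r[2], r[3]))
    })
    evaluate_dataset(mc, c(geoms, near), source = "manual")
  })
}

triatomic_nn <- function() {
  cached("tri_nn", {
    ts <- training_set(triatomic_dataset(), 0.1, seed = 2)
    train_nn(ts, list(hidden = c(50, 50), epochs = 4000,
                      weights = list(nac = 0.02)), seed = 1)
  })
}

# Sign-continuous off-diagonal property curves from a deterministic-sign
# provider: chain per-step phases from nearest-neighbor eigenvector overlaps
# along a scan (parallel transport). Independent of track_phases().
smooth_reference_curves <- function(provider, xs) {
  n <- provider$n_states
  pr <- state_pairs(n)
  nac <- matrix(0, length(xs), nrow(pr))
  tdip <- if (!is.null(provider$dipole_fun)) matrix(0, length(xs), nrow(pr)) else NULL
  sg <- rep(1, n)
  Uprev <- NULL
  for (i in seq_along(xs)) {
    p <- eval_properties(provider, xs[i])
    if (!is.null(Uprev))
      sg <- sg * detect_phases(overlap(Uprev, p$eigvecs), 0.5)$signs
    Uprev <- p$eigvecs
    pp <- sg[pr[, 1]] * sg[pr[, 2]]
    nac[i, ] <- p$nacs[, 1] * pp
    if (!is.null(tdip))
      tdip[i, ] <- p$dipoles[cbind(pr, 1)] * pp
  }
  list(nacs = nac, tdips = tdip)
}

# Antisymmetric v.d coupling matrix with [i, j] = val (beware column-major
# matrix() filling: set elements explicitly).
vd_mat <- function(n, i, j, val) {
  M <- matrix(0, n, n)
  M[i, j] <- val
  M[j, i] <- -val
  M
}

random_triatomic_x <- function() {
  r <- c(runif(2, 2.3, 2.9), runif(1, 2.1, 3.1))
  flatten_coords(triatomic_geometry(r[1], r[2], r[3]))
}
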