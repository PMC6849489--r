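# Fewest-switches surface hopping: classical nuclei on the active adiabatic
# surface (velocity Verlet), quantum electronic coefficients propagated with
# the exact substep propagator, stochastic hops from the fewest-switches
# probabilities, with kinetic-energy gating and velocity rescaling.
#
# Electronic equation (atomic units): i dc_i/dt = E_i c_i - i sum_j (v.d_ij) c_j,
# i.e. c' = exp(-i dt H_eff) c with Hermitian H_eff = diag(E) - i (v.d).

#' Harmonic-oscillator ground-state Wigner sample
#'
#' Draws positions and velocities from the ground-state Wigner distribution
#' of the harmonic model defined by a Hessian: independent Gaussians per
#' vibrational mode with \eqn{\sigma_Q = \sqrt{1/(2\omega)}} and
#' \eqn{\sigma_P = \sqrt{\omega/2}} in mass-weighted coordinates.
#' Translational/rotational modes are excluded.
#'
#' @param x_eq Flat equilibrium coordinates (Bohr).
#' @param hessian Hessian at `x_eq` (Hartree/Bohr^2).
#' @param masses_au Per-dof masses (a.u.).
#' @param n Number of samples.
#' @param freq_cut Frequency cutoff separating vibrations from
#'   translations/rotations.
#' @return List of `n` lists with elements `x` and `v` (a.u.). Uses the
#'   current RNG stream.
#' @export
wigner_sample <- function(x_eq, hessian, masses_au, n = 1, freq_cut = 1e-3) {
  nm <- normal_modes(hessian, masses_au, freq_cut)
  sq <- sqrt(masses_au)
  lapply(seq_len(n), function(i) {
    x <- x_eq; v <- numeric(length(x_eq))
    for (k in seq_len(nm$n_modes)) {
      Q <- stats::rnorm(1, 0, sqrt(1 / (2 * nm$omega[k])))
      P <- stats::rnorm(1, 0, sqrt(nm$omega[k] / 2))
      x <- x + Q * nm$displacements[, k]
      # mass-weighted momentum -> velocity: v = M^{-1/2} L P
      v <- v + P * nm$displacements[, k]
    }
    list(x = x, v = v)
  })
}

#' Initialize a surface-hopping trajectory
#'
#' Sets the electronic coefficients to the basis vector of the initial state
#' (vertical excitation) and draws positions/velocities from the sampling
#' spec: either fixed phase-space coordinates or harmonic ground-state Wigner
#' sampling.
#'
#' @param provider An `es_provider` (used for masses and state count).
#' @param sampling Either `list(type = "fixed", x = ..., v = ...)` or
#'   `list(type = "wigner", x_eq = ..., hessian = ...)` (Hessian computed
#'   numerically on the provider's ground state when omitted).
#' @param initial_state Active state at t = 0 (1-based; state k is the
#'   electronic state S_(k-1)).
#' @param seed RNG seed for the initial-condition draw.
#' @return A trajectory state: list with `time_fs`, `x`, `v`, `coeff`
#'   (complex), `active`, `hops`.
#' @export
initialize_trajectory <- function(provider, sampling, initial_state, seed = 1) {
  nS <- provider$n_states
  if (initial_state < 1 || initial_state > nS) stop("invalid initial state")
  if (is.null(sampling) || is.null(sampling$type))
    stop("invalid sampling spec: need list(type = ...)")
  ic <- switch(sampling$type,
    fixed = list(x = sampling$x, v = sampling$v %||% numeric(length(sampling$x))),
    wigner = {
      hess <- sampling$hessian %||% numerical_hessian(provider, sampling$x_eq, 1)
      local_seed(seed, wigner_sample(sampling$x_eq, hess, provider$masses, 1)[[1]])
    },
    stop("unknown sampling type: ", sampling$type))
  coeff <- complex(real = rep(0, nS))
  coeff[initial_state] <- 1 + 0i
  list(time_fs = 0, x = as.numeric(ic$x), v = as.numeric(ic$v),
       coeff = coeff, active = as.integer(initial_state),
       hops = list())
}

#' One velocity-Verlet nuclear step
#'
#' @param x,v Positions and velocities (a.u.).
#' @param grad Gradient of the active-state energy at `x` (Hartree/Bohr).
#' @param masses_au Per-dof masses.
#' @param dt Time step (a.u.).
#' @param grad_new_fun Function of the new positions returning the gradient
#'   there (for the velocity half-step).
#' @return List with `x`, `v` and whatever `grad_new_fun` attached via
#'   `attr(, "props")`.
#' @export
nuclear_step <- function(x, v, grad, masses_au, dt, grad_new_fun) {
  if (any(!is.finite(grad))) stop("non-finite force; aborting trajectory")
  a <- -grad / masses_au
  x_new <- x + v * dt + 0.5 * a * dt^2
  g_new <- grad_new_fun(x_new)
  a_new <- -as.numeric(g_new) / masses_au
  v_new <- v + 0.5 * (a + a_new) * dt
  out <- list(x = x_new, v = v_new)
  attr(out, "props") <- attr(g_new, "props")
  out
}

# Hermitian effective Hamiltonian from energies and v.d couplings
# (vd: antisymmetric real matrix with [i, j] = v . d_ij).
electronic_hamiltonian <- function(energies, vd) {
  H <- diag(complex(real = energies))
  H <- H - 1i * vd
  H
}

#' Propagate electronic coefficients across one nuclear step
#'
#' Splits the nuclear step into `n_substeps`, linearly interpolates energies
#' and the scalar couplings v.d across it, and applies the exact (unitary)
#' substep propagator via eigendecomposition of the Hermitian effective
#' Hamiltonian. Also accumulates the fewest-switches hop probabilities out of
#' the active state.
#'
#' @param coeff Complex coefficient vector.
#' @param e0,e1 Energies at the start/end of the step (Hartree).
#' @param vd0,vd1 Antisymmetric v.d matrices at the start/end.
#' @param dt Nuclear step (a.u.).
#' @param active Active state index.
#' @param n_substeps Electronic substeps (default 20).
#' @return List with `coeff` (norm-preserving) and `g`, the accumulated hop
#'   probabilities per target state (clipped to `[0, 1]`, sum <= 1).
#' @export
electronic_step <- function(coeff, e0, e1, vd0, vd1, dt, active,
                            n_substeps = 20) {
  n <- length(coeff)
  g <- numeric(n)
  dtau <- dt / n_substeps
  for (m in seq_len(n_substeps)) {
    f <- (m - 0.5) / n_substeps
    E <- (1 - f) * e0 + f * e1
    VD <- (1 - f) * vd0 + f * vd1
    H <- electronic_hamiltonian(E - mean(E), VD)   # drop mean phase
    ed <- eigen(H, symmetric = TRUE)
    ph <- exp(-1i * ed$values * dtau)
    coeff <- ed$vectors %*% (ph * (Conj(t(ed$vectors)) %*% coeff))
    coeff <- as.vector(coeff)
    pa <- Re(Conj(coeff[active]) * coeff[active])
    if (pa > 1e-12) {
      for (j in seq_len(n)) {
        if (j == active) next
        flux <- 2 * dtau * Re(coeff[j] * Conj(coeff[active])) * VD[active, j]
        if (flux > 0) g[j] <- g[j] + flux / pa
      }
    }
  }
  g <- pmin(pmax(g, 0), 1)
  if (sum(g) > 1) g <- g / sum(g)
  list(coeff = coeff, g = g)
}

#' Fewest-switches hop probabilities (single evaluation)
#'
#' \eqn{g_{a\to j} = \max(0,\; 2\,dt\, \mathrm{Re}[c_j c_a^*] (v\cdot d_{aj})
#' / |c_a|^2)}, clipped to `[0, 1]` and renormalized down if the sum exceeds
#' one.
#'
#' @param coeff Complex coefficients.
#' @param vd Antisymmetric v.d matrix.
#' @param dt Time interval (a.u.).
#' @param active Active state.
#' @return Per-state probability vector (0 for the active state).
#' @export
hop_probabilities <- function(coeff, vd, dt, active) {
  n <- length(coeff)
  g <- numeric(n)
  pa <- Re(Conj(coeff[active]) * coeff[active])
  if (pa < 1e-12) {
    warning("active-state population numerically depleted; probabilities 0")
    return(g)
  }
  for (j in seq_len(n)) {
    if (j == active) next
    g[j] <- max(0, 2 * dt * Re(coeff[j] * Conj(coeff[active])) * vd[active, j] / pa)
  }
  g <- pmin(g, 1)
  if (sum(g) > 1) g <- g / sum(g)
  g
}

#' Rescale velocities after a hop
#'
#' Adjusts the kinetic energy by `-dE` (the potential-energy jump) by scaling
#' either the full velocity vector or only its projection on a given
#' direction (e.g. the NAC vector). Returns NULL when the available kinetic
#' energy along the rescaling direction cannot absorb the jump (frustrated
#' hop; the caller keeps the old state).
#'
#' @param v Velocities (a.u.).
#' @param masses_au Per-dof masses.
#' @param dE Potential-energy change E_new - E_old (Hartree).
#' @param direction Optional rescaling direction (defaults to the full
#'   velocity vector).
#' @return Rescaled velocity vector, or NULL if frustrated.
#' @export
rescale_velocity <- function(v, masses_au, dE, direction = NULL) {
  if (is.null(direction)) {
    ke <- 0.5 * sum(masses_au * v^2)
    if (ke + 1e-15 < dE) return(NULL)
    if (ke <= 0) return(if (abs(dE) < 1e-15) v else NULL)
    v * sqrt(max(1 - dE / ke, 0))
  } else {
    d <- direction / sqrt(sum(direction^2))
    # split in mass-weighted coordinates so energy bookkeeping is exact
    vpar_len <- sum(v * d * masses_au) / sum(d^2 * masses_au)
    vpar <- vpar_len * d
    vperp <- v - vpar
    ke_par <- 0.5 * sum(masses_au * vpar^2)
    if (ke_par + 1e-15 < dE) return(NULL)
    if (ke_par <= 0) return(if (abs(dE) < 1e-15) v else NULL)
    vperp + vpar * sqrt(max(1 - dE / ke_par, 0))
  }
}

#' Attempt a stochastic hop
#'
#' Draws one uniform number against the cumulative hop probabilities; a
#' selected hop is accepted only if the kinetic energy can absorb the
#' potential-energy jump (velocities rescaled to conserve total energy),
#' otherwise it is logged as frustrated and the active state kept.
#'
#' @param active Current active state.
#' @param g Per-state hop probabilities.
#' @param energies Adiabatic energies at the current geometry.
#' @param v,masses_au Velocities and masses.
#' @param time_fs Current time, for the event log.
#' @param direction Optional rescaling direction.
#' @return List with `active`, `v` and `event` (NULL if no hop was drawn, or
#'   a record with `outcome` `"accepted"`/`"frustrated"`).
#' @export
attempt_hop <- function(active, g, energies, v, masses_au, time_fs,
                        direction = NULL) {
  r <- stats::runif(1)
  cum <- cumsum(g)
  target <- which(r < cum)[1]
  if (is.na(target) || g[target] <= 0)
    return(list(active = active, v = v, event = NULL))
  dE <- energies[target] - energies[active]
  v_new <- rescale_velocity(v, masses_au, dE, direction)
  if (is.null(v_new)) {
    ev <- list(time_fs = time_fs, from = active, to = target, draw = r,
               outcome = "frustrated")
    return(list(active = active, v = v, event = ev))
  }
  ev <- list(time_fs = time_fs, from = active, to = target, draw = r,
             outcome = "accepted")
  list(active = target, v = v_new, event = ev)
}

# v.d matrix from props and velocities.
vd_matrix <- function(props, v) {
  n <- length(props$energies)
  VD <- matrix(0, n, n)
  pr <- props$pairs
  for (p in seq_len(nrow(pr))) {
    val <- sum(v * props$nacs[p, ])
    VD[pr[p, 1], pr[p, 2]] <- val
    VD[pr[p, 2], pr[p, 1]] <- -val
  }
  VD
}

# Align the sign of a provider's output with the previous step's eigenvectors
# (local phase tracking along a trajectory). Only possible when the provider
# exposes eigenvectors; NN predictions are already smooth and skip this.
align_props_phase <- function(props, prev_eigvecs) {
  if (is.null(props$eigvecs) || is.null(prev_eigvecs)) return(props)
  d <- diag(crossprod(prev_eigvecs, props$eigvecs))
  signs <- ifelse(d >= 0, 1L, -1L)
  if (all(signs == 1L)) return(props)
  apply_phase(props, phase_vector(signs))
}

#' Run one surface-hopping trajectory
#'
#' @param provider An `es_provider` (analytic model, `nn_model` or
#'   `nn_ensemble`); model providers get on-the-fly phase alignment of their
#'   eigenvectors between steps so couplings stay sign-continuous.
#' @param init Trajectory state from [initialize_trajectory()].
#' @param dt_fs Nuclear time step in fs (default 0.5).
#' @param t_max_fs Propagation time in fs.
#' @param n_substeps Electronic substeps per nuclear step.
#' @param seed Seed of the hop RNG (trajectories are bit-reproducible given
#'   seed, dt and provider).
#' @param decoherence Optional energy-based decoherence damping constant in
#'   Hartree (e.g. 0.1); default NULL = plain fewest switches.
#' @param monitor Optional callback `function(time_fs, x, props)`; returning
#'   TRUE aborts the trajectory (used by adaptive sampling). The returned
#'   object is then flagged `aborted`.
#' @param record_every Store every k-th frame (default 1).
#' @return Object of class `"trajectory"`: list with `frames` (data frame of
#'   time, active state, energies, populations, kinetic/total energy),
#'   `positions` (matrix), `hops` (list of hop events), `aborted`.
#' @export
run_trajectory <- function(provider, init, dt_fs = 0.5, t_max_fs = 100,
                           n_substeps = 20, seed = 1, decoherence = NULL,
                           monitor = NULL, record_every = 1L) {
  dt <- dt_fs * .aut_per_fs
  n_steps <- max(0L, as.integer(round(t_max_fs / dt_fs)))
  masses <- provider$masses
  nS <- provider$n_states
  x <- init$x; v <- init$v; coeff <- init$coeff; active <- init$active
  local_seed(seed, {
    props <- eval_properties(provider, x)
    prev_U <- props$eigvecs
    frames <- vector("list", n_steps + 1L)
    positions <- matrix(0, n_steps + 1L, length(x))
    hops <- init$hops
    aborted <- FALSE
    snap <- function(t_fs, x, v, coeff, active, props) {
      ekin <- 0.5 * sum(masses * v^2)
      c(time_fs = t_fs, active = active, ekin = ekin,
        epot = props$energies[active],
        etot = ekin + props$energies[active],
        stats::setNames(props$energies, paste0("e", seq_len(nS) - 1L)),
        stats::setNames(Re(Conj(coeff) * coeff), paste0("p", seq_len(nS) - 1L)),
        norm = sum(Re(Conj(coeff) * coeff)))
    }
    frames[[1]] <- snap(0, x, v, coeff, active, props)
    positions[1, ] <- x
    step <- 0L
    while (step < n_steps) {
      step <- step + 1L
      t_fs <- step * dt_fs
      res <- nuclear_step(x, v, props$gradients[active, ], masses, dt,
                          grad_new_fun = function(xn) {
                            pn <- eval_properties(provider, xn)
                            pn <- align_props_phase(pn, prev_U)
                            gr <- pn$gradients[active, ]
                            attr(gr, "props") <- pn
                            gr
                          })
      props_new <- attr(res, "props")
      vd0 <- vd_matrix(props, v)
      vd1 <- vd_matrix(props_new, res$v)
      es <- electronic_step(coeff, props$energies, props_new$energies,
                            vd0, vd1, dt, active, n_substeps)
      coeff <- es$coeff
      hop <- attempt_hop(active, es$g, props_new$energies, res$v, masses, t_fs)
      if (!is.null(hop$event)) hops[[length(hops) + 1L]] <- hop$event
      active <- hop$active
      x <- res$x; v <- hop$v
      if (!is.null(decoherence))
        coeff <- decohere(coeff, active, props_new$energies,
                          0.5 * sum(masses * v^2), dt, decoherence)
      props <- props_new
      prev_U <- props$eigvecs %||% prev_U
      frames[[step + 1L]] <- snap(t_fs, x, v, coeff, active, props)
      positions[step + 1L, ] <- x
      if (!is.null(monitor) && isTRUE(monitor(t_fs, x, props))) {
        aborted <- TRUE
        break
      }
    }
    keep <- seq_len(step + 1L)
    keep <- keep[(keep - 1L) %% record_every == 0L | keep == step + 1L]
    frames_df <- as.data.frame(do.call(rbind, frames[keep]))
    structure(list(frames = frames_df, positions = positions[keep, , drop = FALSE],
                   hops = hops, aborted = aborted, dt_fs = dt_fs, seed = seed,
                   final = list(x = x, v = v, coeff = coeff, active = active)),
              class = "trajectory")
  })
}

# Energy-based decoherence damping (off by default): damps non-active
# coefficients with time constant 1/|E_i - E_a| * (1 + C/ekin).
decohere <- function(coeff, active, energies, ekin, dt, C = 0.1) {
  n <- length(coeff)
  for (i in seq_len(n)) {
    if (i == active) next
    gap <- abs(energies[i] - energies[active])
    if (gap < 1e-12) next
    tau <- (1 + C / max(ekin, 1e-8)) / gap
    coeff[i] <- coeff[i] * exp(-dt / tau)
  }
  pa_rest <- sum(Re(Conj(coeff[-active]) * coeff[-active]))
  pa <- Re(Conj(coeff[active]) * coeff[active])
  if (pa > 0) coeff[active] <- coeff[active] * sqrt(max(1 - pa_rest, 0) / pa)
  coeff
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames, dt = %g fs, %d hop events%s\n",
              nrow(x$frames), x$dt_fs, length(x$hops),
              if (x$aborted) " (aborted)" else ""))
  invisible(x)
}

#' Run an ensemble of trajectories and tabulate populations
#'
#' Classical populations: the fraction of trajectories whose active state is
#' i at each time. Quantum populations (mean |c_i|^2) are tabulated
#' alongside for diagnostics.
#'
#' @param provider An `es_provider`.
#' @param n_traj Number of trajectories.
#' @param sampling Sampling spec (see [initialize_trajectory()]).
#' @param initial_state Initial active state (1-based).
#' @param dt_fs,t_max_fs,n_substeps,decoherence Passed to
#'   [run_trajectory()].
#' @param seed Base seed; trajectory k uses `seed + k`.
#' @param keep_trajectories Keep the individual trajectory objects.
#' @return List with `populations` (data frame: `time_fs`, one `n_S*` column
#'   per state, `count`), `quantum_populations`, optional `trajectories`,
#'   and `n_hops`.
#' @export
run_ensemble_of_trajectories <- function(provider, n_traj, sampling,
                                         initial_state, dt_fs = 0.5,
                                         t_max_fs = 100, n_substeps = 20,
                                         decoherence = NULL, seed = 1,
                                         keep_trajectories = FALSE) {
  stopifnot(n_traj >= 1)
  nS <- provider$n_states
  acc <- NULL; qacc <- NULL; count <- NULL
  trajs <- if (keep_trajectories) vector("list", n_traj) else NULL
  n_hops <- 0L
  for (k in seq_len(n_traj)) {
    init <- initialize_trajectory(provider, sampling, initial_state,
                                  seed = seed + k)
    tr <- run_trajectory(provider, init, dt_fs = dt_fs, t_max_fs = t_max_fs,
                         n_substeps = n_substeps, seed = seed + k,
                         decoherence = decoherence)
    fr <- tr$frames
    if (is.null(acc)) {
      acc <- matrix(0, nrow(fr), nS)
      qacc <- matrix(0, nrow(fr), nS)
      count <- integer(nrow(fr))
      times <- fr$time_fs
    }
    nrow_k <- min(nrow(fr), nrow(acc))
    for (i in seq_len(nrow_k)) acc[i, fr$active[i]] <- acc[i, fr$active[i]] + 1
    qacc[seq_len(nrow_k), ] <- qacc[seq_len(nrow_k), ] +
      as.matrix(fr[seq_len(nrow_k), paste0("p", seq_len(nS) - 1L)])
    count[seq_len(nrow_k)] <- count[seq_len(nrow_k)] + 1L
    n_hops <- n_hops + sum(vapply(tr$hops, function(h) h$outcome == "accepted", logical(1)))
    if (keep_trajectories) trajs[[k]] <- tr
  }
  pops <- data.frame(time_fs = times, sweep(acc, 1, pmax(count, 1L), "/"),
                     count = count)
  names(pops)[2:(nS + 1)] <- paste0("n_S", seq_len(nS) - 1L)
  qpops <- data.frame(time_fs = times, sweep(qacc, 1, pmax(count, 1L), "/"))
  names(qpops)[2:(nS + 1)] <- paste0("q_S", seq_len(nS) - 1L)
  out <- list(populations = pops, quantum_populations = qpops, n_hops = n_hops)
  if (keep_trajectories) out$trajectories <- trajs
  out
}
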