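# Training-set construction and active learning: normal-mode scans for the
# initial set, ensemble-disagreement thresholds with multiplicative decay for
# its adaptive expansion during dynamics.

#' Numerical Hessian of a provider's state energy
#'
#' Symmetrized central finite differences of the analytic gradients.
#'
#' @param provider An `es_provider`.
#' @param x Flat coordinates (Bohr).
#' @param state State index (default 1, the ground state).
#' @param h Finite-difference step (Bohr).
#' @return Symmetric n_dof x n_dof matrix (Hartree/Bohr^2).
#' @export
numerical_hessian <- function(provider, x, state = 1, h = 1e-3) {
  nd <- length(x)
  H <- matrix(0, nd, nd)
  for (k in seq_len(nd)) {
    xp <- x; xp[k] <- xp[k] + h
    xm <- x; xm[k] <- xm[k] - h
    gp <- eval_properties(provider, xp)$gradients[state, ]
    gm <- eval_properties(provider, xm)$gradients[state, ]
    H[k, ] <- (gp - gm) / (2 * h)
  }
  (H + t(H)) / 2
}

# Mass-weighted normal modes. Returns frequencies (a.u.) and Cartesian
# displacement directions M^{-1/2} L for modes above the frequency cutoff.
normal_modes <- function(hessian, masses_au, freq_cut = 1e-3) {
  sq <- sqrt(masses_au)
  Hmw <- hessian / tcrossprod(sq)
  e <- eigen((Hmw + t(Hmw)) / 2, symmetric = TRUE)
  ord <- order(e$values)
  lam <- e$values[ord]
  L <- e$vectors[, ord, drop = FALSE]
  keep <- which(lam > freq_cut^2)
  if (length(keep) == 0) stop("no vibrational modes above the frequency cutoff")
  omega <- sqrt(lam[keep])
  disp <- sweep(L[, keep, drop = FALSE], 1, sq, "/")
  list(omega = omega, displacements = disp, n_modes = length(keep))
}

#' Normal-mode scan around an equilibrium geometry
#'
#' Diagonalizes the mass-weighted Hessian, discards translational/rotational
#' (near-zero-frequency) modes and displaces the equilibrium geometry along
#' each vibrational mode by the given dimensionless amplitudes; amplitude 1
#' corresponds to one unit of \eqn{1/\sqrt{\omega}} in the mass-weighted
#' normal coordinate (about \eqn{\sqrt 2} ground-state widths). Duplicate
#' geometries (amplitude 0 on every mode) are emitted once.
#'
#' @param x_eq Flat equilibrium coordinates (Bohr).
#' @param hessian n_dof x n_dof Hessian (Hartree/Bohr^2).
#' @param masses_au Per-dof masses (atomic units).
#' @param amplitudes Numeric vector of dimensionless displacement amplitudes.
#' @param freq_cut Angular-frequency cutoff in a.u. (default 1e-3, ~220 cm^-1) below which modes count as
#'   translation/rotation.
#' @return List with `geometries` (list of flat coordinate vectors), `mode`
#'   and `amplitude` bookkeeping vectors, and the mode frequencies `omega`
#'   (a.u.).
#' @export
normal_mode_scan <- function(x_eq, hessian, masses_au, amplitudes,
                             freq_cut = 1e-3) {
  nm <- normal_modes(hessian, masses_au, freq_cut)
  geoms <- list(); mode <- integer(0); amp <- numeric(0)
  seen_eq <- FALSE
  for (k in seq_len(nm$n_modes)) {
    for (a in amplitudes) {
      if (a == 0) {
        if (seen_eq) next
        seen_eq <- TRUE
        geoms[[length(geoms) + 1L]] <- x_eq
        mode <- c(mode, 0L); amp <- c(amp, 0)
      } else {
        dx <- a / sqrt(nm$omega[k]) * nm$displacements[, k]
        geoms[[length(geoms) + 1L]] <- x_eq + dx
        mode <- c(mode, k); amp <- c(amp, a)
      }
    }
  }
  list(geometries = geoms, mode = mode, amplitude = amp, omega = nm$omega)
}

#' Ensemble-disagreement threshold schedule
#'
#' Per-property thresholds compared against the ensemble disagreement at
#' every dynamics step. On a trigger before `freeze_time_fs` the thresholds
#' decay by the factor `decay` (default 0.95); after the freeze time they are
#' kept at their previous value even when new points are added.
#'
#' @param thresholds Named positive numeric vector (names matching
#'   [disagreement()] output, e.g. `energies`, `gradients`, `nacs`).
#' @param decay Multiplicative decay per pre-freeze trigger.
#' @param freeze_time_fs Simulation time after which thresholds stop
#'   decaying (default 10 ps).
#' @param decay_scope `"all"` decays every property's threshold on any
#'   trigger; `"violated"` only the exceeded ones.
#' @return Object of class `"threshold_schedule"` with a `history` log.
#' @export
threshold_schedule <- function(thresholds, decay = 0.95,
                               freeze_time_fs = 1e4,
                               decay_scope = c("all", "violated")) {
  if (any(thresholds <= 0) || is.null(names(thresholds)))
    stop("thresholds must be a named vector of positive values")
  structure(list(thresholds = thresholds, decay = decay,
                 freeze_time_fs = freeze_time_fs,
                 decay_scope = match.arg(decay_scope),
                 n_triggers = 0L,
                 history = data.frame()),
            class = "threshold_schedule")
}

#' Compare disagreements to thresholds and adapt the schedule
#'
#' Retraining is requested as soon as any single property exceeds its
#' threshold, even if every other property is predicted reliably. On a
#' trigger before the freeze time, thresholds are multiplied by the decay
#' factor; past it they are left unchanged.
#'
#' @param disagreements Named vector from [disagreement()].
#' @param schedule A [threshold_schedule()].
#' @param sim_time_fs Current simulation time (fs).
#' @return List with `decision` (`"trusted"` or `"retrain_needed"`),
#'   `violated` (property names) and the updated `schedule`.
#' @export
check_and_adapt <- function(disagreements, schedule, sim_time_fs) {
  common <- intersect(names(schedule$thresholds), names(disagreements))
  violated <- common[disagreements[common] > schedule$thresholds[common]]
  triggered <- length(violated) > 0
  if (triggered) {
    schedule$n_triggers <- schedule$n_triggers + 1L
    if (sim_time_fs < schedule$freeze_time_fs) {
      scope <- if (schedule$decay_scope == "all") names(schedule$thresholds) else violated
      schedule$thresholds[scope] <- schedule$thresholds[scope] * schedule$decay
    }
  }
  schedule$history <- rbind(schedule$history, data.frame(
    time_fs = sim_time_fs,
    property = if (triggered) paste(violated, collapse = "+") else NA_character_,
    triggered = triggered,
    theta_energies = unname(schedule$thresholds["energies"]),
    stringsAsFactors = FALSE))
  list(decision = if (triggered) "retrain_needed" else "trusted",
       violated = violated, schedule = schedule)
}

#' Initial thresholds from ensemble validation errors
#'
#' Sets each property threshold to the worst member validation RMSE of that
#' property times a safety factor.
#'
#' @param ensemble An [nn_ensemble()].
#' @param safety_factor Multiplier on the validation RMSE (default 3).
#' @return Named vector suitable for [threshold_schedule()].
#' @export
initial_thresholds <- function(ensemble, safety_factor = 3) {
  keys <- c(energies = "energy", gradients = "force", nacs = "nac",
            dipoles = "dipole", socs = "soc")
  out <- c()
  for (nm in names(keys)) {
    vals <- vapply(ensemble$members, function(m) {
      v <- m$val_rmse[keys[[nm]]]
      if (is.na(v)) NA_real_ else unname(v)
    }, numeric(1))
    if (!any(is.na(vals))) out[nm] <- max(vals) * safety_factor
  }
  out
}

#' Adaptive-sampling loop
#'
#' Propagates surface-hopping trajectories with the ensemble mean; whenever
#' the member disagreement exceeds a threshold, the offending geometry is
#' recomputed with the reference provider, phase-corrected against the
#' training set's reference record, appended to the training set, and the
#' ensemble is retrained before the trajectory is restarted. Thresholds
#' decay multiplicatively on every trigger until the cumulative simulated
#' time across the run exceeds `freeze_time_fs`; after that, points are
#' still added and the ensemble retrained, but the thresholds are kept at
#' their previous value, which lets the loop converge (trajectories complete
#' without triggers once the visited region is covered).
#'
#' @param initial_ts A [training_set()] (phase-corrected).
#' @param provider The reference `es_provider` (e.g. a bundled model).
#' @param config List of options: `n_traj` (trajectory budget),
#'   `dt_fs`, `t_max_fs`, `initial_state`, `sampling` (spec for
#'   [initialize_trajectory()]), `hyperparams`, `n_members`,
#'   `safety_factor`, `decay`, `freeze_time_fs`, `max_new_points`,
#'   `max_restarts` (per trajectory), `thresholds` (override the
#'   validation-derived initial thresholds), `min_clear_streak` (keep
#'   running extra trajectories, up to `max_extra_traj`, until this many in
#'   a row complete without a single trigger -- the loop's convergence
#'   criterion; 0 disables).
#' @param seed Master seed (dynamics RNG; member training seeds derive from
#'   it).
#' @return List with the final `training_set`, final `ensemble`, final
#'   `schedule`, the `events` log (one row per threshold trigger) and
#'   `trajectories` (list of completed trajectory objects).
#' @export
adaptive_run <- function(initial_ts, provider, config = list(), seed = 1) {
  cfg <- utils::modifyList(list(
    n_traj = 1L, dt_fs = 0.5, t_max_fs = 100, initial_state = provider$n_states,
    sampling = NULL, hyperparams = list(), n_members = 2L,
    safety_factor = 3, decay = 0.95, freeze_time_fs = 1e4,
    max_new_points = 50L, max_restarts = 25L, thresholds = NULL,
    min_clear_streak = 0L, max_extra_traj = 30L,
    validation_fraction = 0.1), config)
  ts <- initial_ts
  ens <- train_ensemble(ts, cfg$hyperparams, cfg$n_members, seed = seed)
  thr <- cfg$thresholds %||% initial_thresholds(ens, cfg$safety_factor)
  sched <- threshold_schedule(thr, decay = cfg$decay,
                              freeze_time_fs = cfg$freeze_time_fs)
  events <- list()
  trajs <- list()
  added <- 0L
  cum_fs <- 0   # cumulative simulated time; the freeze clock of the schedule
  refit <- function(ts, sd) train_ensemble(ts, cfg$hyperparams, cfg$n_members, seed = sd)
  streak <- 0L   # consecutive trajectories completed without any trigger
  itraj <- 0L
  repeat {
    itraj <- itraj + 1L
    if (itraj > cfg$n_traj &&
        (streak >= cfg$min_clear_streak || itraj > cfg$n_traj + cfg$max_extra_traj))
      break
    restarts <- 0L
    repeat {
      trigger <- new.env(parent = emptyenv())
      monitor <- function(step_time_fs, x, props) {
        d <- props$disagreement
        if (is.null(d)) return(FALSE)
        res <- check_and_adapt(d, sched, cum_fs + step_time_fs)
        sched <<- res$schedule
        if (res$decision == "retrain_needed") {
          trigger$x <- x; trigger$time_fs <- step_time_fs
          trigger$violated <- res$violated
          trigger$disagreement <- d
          return(TRUE)
        }
        FALSE
      }
      init <- initialize_trajectory(
        provider = ens, sampling = cfg$sampling,
        initial_state = cfg$initial_state,
        seed = seed + 1000L * itraj + restarts)
      tr <- run_trajectory(ens, init, dt_fs = cfg$dt_fs, t_max_fs = cfg$t_max_fs,
                           seed = seed + 1000L * itraj + restarts,
                           monitor = monitor)
      cum_fs <- cum_fs + max(tr$frames$time_fs)
      if (is.null(trigger$x)) {
        trajs[[length(trajs) + 1L]] <- tr
        streak <- if (restarts == 0L) streak + 1L else 1L
        break
      }
      # provider -> phase correction -> append -> retrain (in that order)
      ref_idx <- ts$header$phase_reference %||% 1L
      refrec <- ts$records[[ref_idx]]
      newrec <- tryCatch({
        props <- eval_properties(provider, trigger$x)
        p <- track_phases(refrec$x, trigger$x, provider,
                          eigvecs_ref = refrec$props$eigvecs,
                          eigvecs_new = props$eigvecs)
        list(x = trigger$x, props = apply_phase(props, p),
             phase = p$signs, source = "adaptive")
      }, error = function(e) {
        events[[length(events) + 1L]] <<- data.frame(
          time_fs = trigger$time_fs, traj = itraj,
          property = paste(trigger$violated, collapse = "+"),
          action = paste("skipped:", conditionMessage(e)),
          stringsAsFactors = FALSE)
        NULL
      })
      if (!is.null(newrec)) {
        ts$records[[length(ts$records) + 1L]] <- newrec
        ts <- training_set(list(records = ts$records, header = ts$header),
                           validation_fraction = cfg$validation_fraction,
                           seed = seed + added)
        added <- added + 1L
        ens <- refit(ts, seed + 10L * added)
        events[[length(events) + 1L]] <- data.frame(
          time_fs = trigger$time_fs, traj = itraj,
          property = paste(trigger$violated, collapse = "+"),
          action = "added+retrained", stringsAsFactors = FALSE)
      }
      restarts <- restarts + 1L
      if (added >= cfg$max_new_points || restarts >= cfg$max_restarts) {
        trajs[[length(trajs) + 1L]] <- tr
        streak <- 0L
        break
      }
    }
    if (added >= cfg$max_new_points) break
  }
  list(training_set = ts, ensemble = ens, schedule = sched,
       events = if (length(events)) do.call(rbind, events) else data.frame(),
       trajectories = trajs, n_added = added, simulated_fs = cum_fs)
}
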