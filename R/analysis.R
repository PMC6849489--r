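# Population analysis: comparison metrics between methods and first-order
# sequential kinetics fits for excited-state decay time constants.

#' Mean absolute error between two population tables
#'
#' Mean absolute difference over all (time, state) cells. The tables must
#' share a time grid (use [resample_populations()] first otherwise).
#'
#' @param pop_a,pop_b Data frames with a `time_fs` column and one population
#'   column per state (as produced by [run_ensemble_of_trajectories()]).
#' @return Scalar MAE.
#' @export
population_mae <- function(pop_a, pop_b) {
  ca <- grep("^n_S", names(pop_a), value = TRUE)
  cb <- grep("^n_S", names(pop_b), value = TRUE)
  if (length(ca) == 0) ca <- setdiff(names(pop_a), c("time_fs", "count"))
  if (length(cb) == 0) cb <- setdiff(names(pop_b), c("time_fs", "count"))
  if (length(ca) != length(cb))
    stop("population tables have different state counts")
  if (nrow(pop_a) != nrow(pop_b) ||
      max(abs(pop_a$time_fs - pop_b$time_fs)) > 1e-9)
    stop("population tables are on different time grids; resample first")
  mean(abs(as.matrix(pop_a[ca]) - as.matrix(pop_b[cb])))
}

#' Resample a population table onto a new time grid
#'
#' Linear interpolation per state column.
#'
#' @param pop Population data frame with `time_fs`.
#' @param times New time grid (fs), within the original range.
#' @return Resampled data frame.
#' @export
resample_populations <- function(pop, times) {
  cols <- setdiff(names(pop), c("time_fs", "count"))
  out <- data.frame(time_fs = times)
  for (cn in cols)
    out[[cn]] <- stats::approx(pop$time_fs, pop[[cn]], xout = times, rule = 2)$y
  out
}

# Closed-form sequential first-order kinetics A -> B -> C.
# Near-degenerate time constants switch to the analytic limit
# P_B = (t/tau) exp(-t/tau).
sequential_kinetics <- function(t, tau1, tau2) {
  pa <- exp(-t / tau1)
  if (abs(tau1 - tau2) < 1e-6 * max(tau1, tau2)) {
    pb <- (t / tau1) * exp(-t / tau1)
  } else {
    pb <- tau2 / (tau2 - tau1) * (exp(-t / tau2) - exp(-t / tau1))
  }
  cbind(A = pa, B = pb, C = 1 - pa - pb)
}

#' Fit sequential-decay time constants to population curves
#'
#' Weighted least-squares fit of the closed-form solution of the sequential
#' first-order scheme A -> B -> C,
#' \deqn{P_A = e^{-t/\tau_1},\quad
#'       P_B = \frac{\tau_2}{\tau_2-\tau_1}(e^{-t/\tau_2} - e^{-t/\tau_1}),
#'       \quad P_C = 1 - P_A - P_B,}
#' fitting all three curves jointly with binomial weights
#' (\eqn{\sigma^2 = p(1-p)/n}, floored). The degenerate limit
#' \eqn{\tau_1 = \tau_2} is handled analytically. Optimization is over
#' \eqn{\log\tau} with a small multi-start.
#'
#' @param populations Data frame with `time_fs` and (optionally) `count`.
#' @param states Character or integer vector naming the columns holding
#'   P_A, P_B, P_C in that order (A = initially populated state).
#' @param n_traj Trajectory count for the binomial weights; taken from a
#'   `count` column when present, else 200.
#' @return List with `tau1_fs`, `tau2_fs`, standard errors `se`, the
#'   `fitted` table and `rss`. Non-decaying input (P_A stays ~1) is flagged
#'   with `tau1_fs = Inf`.
#' @export
fit_time_constants <- function(populations, states, n_traj = NULL) {
  t <- populations$time_fs
  P <- as.matrix(populations[states])
  if (any(abs(rowSums(P) - 1) > 0.05))
    stop("populations do not sum to ~1; not a normalized 3-state table")
  n <- n_traj %||% (if ("count" %in% names(populations)) populations$count else 200)
  w <- 1 / pmax(P * (1 - P) / n, 1e-4)
  if (min(P[, 1]) > 0.99) {
    return(list(tau1_fs = Inf, tau2_fs = NA_real_, se = c(NA, NA),
                non_decaying = TRUE))
  }
  obj <- function(lt) {
    M <- sequential_kinetics(t, exp(lt[1]), exp(lt[2]))
    sum(w * (P - M)^2)
  }
  # multi-start over decades around the observed decay scale
  t_half <- t[which(P[, 1] < 0.5)[1]]
  if (is.na(t_half)) t_half <- max(t) / 2
  starts <- expand.grid(lt1 = log(t_half * c(0.3, 1, 3)),
                        lt2 = log(t_half * c(0.5, 2, 8)))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    o <- tryCatch(stats::optim(as.numeric(starts[s, ]), obj, method = "Nelder-Mead",
                               control = list(maxit = 2000, reltol = 1e-12)),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("time-constant fit failed to converge")
  o <- stats::optim(best$par, obj, method = "BFGS",
                    control = list(maxit = 500, reltol = 1e-14))
  if (o$value <= best$value) best <- o
  tau <- exp(best$par)
  # Gauss-Newton standard errors on tau via the Jacobian of the residuals
  jac <- function(lt) {
    h <- 1e-6
    base <- as.vector(sequential_kinetics(t, exp(lt[1]), exp(lt[2])))
    vapply(1:2, function(k) {
      ltp <- lt; ltp[k] <- ltp[k] + h
      (as.vector(sequential_kinetics(t, exp(ltp[1]), exp(ltp[2]))) - base) / h
    }, numeric(length(base)))
  }
  Jm <- jac(best$par)
  wv <- as.vector(w)
  res <- as.vector(P - sequential_kinetics(t, tau[1], tau[2]))
  dof <- max(length(res) - 2, 1)
  s2 <- sum(wv * res^2) / dof
  JtWJ <- crossprod(Jm, Jm * wv)
  cov_lt <- tryCatch(s2 * solve(JtWJ), error = function(e) matrix(NA, 2, 2))
  se <- sqrt(pmax(diag(cov_lt), 0)) * tau  # delta method: d tau/d log tau = tau
  list(tau1_fs = tau[1], tau2_fs = tau[2], se = unname(se),
       fitted = data.frame(time_fs = t, sequential_kinetics(t, tau[1], tau[2])),
       rss = best$value, non_decaying = FALSE)
}

#' Population report: overlay plot, pairwise MAE and time constants
#'
#' @param pops Named list of population data frames (shared time grid).
#' @param states Columns (in A, B, C order) to fit time constants on; NULL
#'   skips the fits.
#' @param file Optional PDF path for the overlay plot (vector graphics); no
#'   plot is produced when NULL.
#' @param log_time Plot a logarithmic time axis.
#' @return List with `mae` (pairwise matrix), `time_constants` (per input)
#'   and `file`.
#' @export
population_report <- function(pops, states = NULL, file = NULL,
                              log_time = FALSE) {
  stopifnot(length(pops) >= 1)
  nms <- names(pops) %||% paste0("run", seq_along(pops))
  mae <- matrix(0, length(pops), length(pops), dimnames = list(nms, nms))
  if (length(pops) > 1)
    for (a in seq_along(pops)) for (b in seq_along(pops))
      if (a != b) mae[a, b] <- population_mae(pops[[a]], pops[[b]])
  tcs <- NULL
  if (!is.null(states))
    tcs <- lapply(pops, function(p)
      tryCatch(fit_time_constants(p, states), error = function(e) NULL))
  if (!is.null(file)) {
    grDevices::pdf(file, width = 7, height = 5)
    on.exit(grDevices::dev.off())
    cols <- grep("^n_S", names(pops[[1]]), value = TRUE)
    lty <- 1
    graphics::plot(NULL, xlim = range(pops[[1]]$time_fs[pops[[1]]$time_fs > 0 | !log_time]),
                   ylim = c(0, 1), xlab = "time (fs)", ylab = "population",
                   log = if (log_time) "x" else "")
    palette <- grDevices::hcl.colors(max(3, length(cols)), "Dark 3")
    for (p in seq_along(pops)) {
      for (s in seq_along(cols))
        graphics::lines(pops[[p]]$time_fs, pops[[p]][[cols[s]]],
                        col = palette[s], lty = p, lwd = 1.5)
      lty <- lty + 1
    }
    graphics::legend("topright", legend = c(cols, nms),
                     col = c(palette[seq_along(cols)], rep("grey30", length(nms))),
                     lty = c(rep(1, length(cols)), seq_along(nms)), bty = "n")
  }
  list(mae = mae, time_constants = tcs, file = file)
}
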