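# Optimization of stationary points on model or NN surfaces: state minima by
# quasi-Newton descent on the predicted energy, minimum-energy conical
# intersections (MECIs) by a gradient-only penalty method that needs no NAC
# at the optimizer level -- exactly the energies-and-gradients interface the
# NN provides.

#' Optimize a state minimum
#'
#' BFGS line-search descent on E_state using the provider's analytic
#' gradients. For translation/rotation-invariant Cartesian surfaces the
#' optimizer simply leaves those flat directions untouched.
#'
#' @param provider An `es_provider`.
#' @param state State index (1-based).
#' @param x_start Flat starting coordinates (Bohr).
#' @param tol Gradient-norm convergence tolerance (Hartree/Bohr).
#' @param max_iter Maximum BFGS iterations.
#' @return List with `x`, `energy`, `grad_norm`, `iterations`, `converged`.
#'   Error (with the last iterate attached) if not converged.
#' @export
optimize_minimum <- function(provider, state, x_start, tol = 1e-6,
                             max_iter = 200) {
  fn <- function(x) eval_properties(provider, x)$energies[state]
  gr <- function(x) eval_properties(provider, x)$gradients[state, ]
  g0 <- gr(x_start)
  if (sqrt(sum(g0^2)) < tol) {
    return(list(x = x_start, energy = fn(x_start), grad_norm = sqrt(sum(g0^2)),
                iterations = 0L, converged = TRUE))
  }
  opt <- stats::optim(x_start, fn, gr, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-14))
  gn <- sqrt(sum(gr(opt$par)^2))
  conv <- gn < tol
  if (!conv && opt$convergence != 0)
    stop("minimum optimization did not converge (grad norm ",
         format(gn), "); last iterate attached", call. = FALSE)
  list(x = opt$par, energy = opt$value, grad_norm = gn,
       iterations = opt$counts[["function"]], converged = conv)
}

#' Optimize a minimum-energy conical intersection (penalty method)
#'
#' Minimizes the penalty objective
#' \deqn{f = (E_i + E_j)/2 + \sigma \Delta^2 / (\Delta + \alpha),\quad
#'       \Delta = E_j - E_i,}
#' increasing sigma on a schedule until the gap falls below `gap_tol`. Only
#' energies and gradients are required; the NAC direction is never needed.
#' On an NN surface the converged gap is strictly positive (the network is
#' differentiable everywhere, so it smooths the cone tip) but falls below
#' `gap_tol`.
#'
#' @param provider An `es_provider`.
#' @param states Pair `c(i, j)` with i < j adjacent.
#' @param x_start Flat starting coordinates (Bohr).
#' @param sigma0 Initial penalty strength (default 3.5).
#' @param alpha Penalty smoothing parameter in Hartree (default 0.02).
#' @param growth Multiplicative sigma growth per outer cycle (default 1.5).
#' @param gap_tol Target energy gap in Hartree.
#' @param tol Convergence tolerance on the projected mean-energy gradient.
#' @param max_outer Maximum penalty cycles.
#' @return List with `x`, `energies`, `gap`, `mean_energy`,
#'   `projected_grad_norm`, `sigma_final`, `schedule` (per-cycle log),
#'   `converged`. Error with diagnostics on non-convergence.
#' @export
optimize_meci <- function(provider, states, x_start, sigma0 = 3.5,
                          alpha = 0.02, growth = 1.5, gap_tol = 1e-3,
                          tol = 1e-4, max_outer = 30) {
  i <- states[1]; j <- states[2]
  stopifnot(i < j)
  x <- x_start
  sigma <- sigma0
  sched <- list()
  converged <- FALSE
  for (cycle in seq_len(max_outer)) {
    fn <- function(x) {
      e <- eval_properties(provider, x)$energies
      d <- e[j] - e[i]
      (e[i] + e[j]) / 2 + sigma * d^2 / (d + alpha)
    }
    gr <- function(x) {
      p <- eval_properties(provider, x)
      d <- p$energies[j] - p$energies[i]
      dpen <- sigma * (d^2 + 2 * alpha * d) / (d + alpha)^2
      (p$gradients[i, ] + p$gradients[j, ]) / 2 +
        dpen * (p$gradients[j, ] - p$gradients[i, ])
    }
    obj_start <- fn(x)
    opt <- stats::optim(x, fn, gr, method = "BFGS",
                        control = list(maxit = 300, reltol = 1e-14))
    x <- opt$par
    p <- eval_properties(provider, x)
    gap <- p$energies[j] - p$energies[i]
    gmean <- (p$gradients[i, ] + p$gradients[j, ]) / 2
    gdiff <- p$gradients[j, ] - p$gradients[i, ]
    nrm <- sqrt(sum(gdiff^2))
    gproj <- if (nrm > 1e-12) gmean - sum(gmean * gdiff) / nrm^2 * gdiff else gmean
    pg <- sqrt(sum(gproj^2))
    sched[[cycle]] <- c(cycle = cycle, sigma = sigma, gap = gap,
                        proj_grad = pg, objective_start = obj_start,
                        objective = opt$value)
    if (gap < gap_tol && pg < tol) { converged <- TRUE; break }
    sigma <- sigma * growth
  }
  if (!converged)
    stop(sprintf("MECI optimization not converged: final gap %.3e Ha, sigma %.1f",
                 gap, sigma), call. = FALSE)
  list(x = x, energies = p$energies, gap = gap,
       mean_energy = (p$energies[i] + p$energies[j]) / 2,
       projected_grad_norm = pg, sigma_final = sigma,
       schedule = as.data.frame(do.call(rbind, sched)), converged = TRUE)
}

#' Gap statistics near a conical intersection
#'
#' Selects the geometries whose reference energy gap is below `gap_cut_ev`
#' (default 0.8 eV) and reports the mean signed difference between the
#' surrogate and reference gaps there (positive = surrogate overestimates,
#' the expected signature of NN smoothing at the cone), with a bootstrap
#' confidence interval.
#'
#' @param geometries List of flat coordinate vectors.
#' @param reference,surrogate Two `es_provider`s evaluable on all
#'   geometries.
#' @param states Pair `c(i, j)`.
#' @param gap_cut_ev Selection cut on the reference gap (eV).
#' @param n_boot Bootstrap resamples for the CI.
#' @param conf Confidence level.
#' @param seed Bootstrap seed.
#' @return List with `count`, `mean_diff_ev`, `sd_diff_ev`, `ci_ev`,
#'   `ref_gaps_ev`, `sur_gaps_ev`. Error if no geometry passes the cut.
#' @export
gap_statistics <- function(geometries, reference, surrogate, states,
                           gap_cut_ev = 0.8, n_boot = 1000, conf = 0.95,
                           seed = 1) {
  i <- states[1]; j <- states[2]
  ref <- vapply(geometries, function(x) {
    e <- eval_properties(reference, x)$energies
    (e[j] - e[i]) * .ev_per_hartree
  }, numeric(1))
  sel <- which(ref < gap_cut_ev)
  if (length(sel) == 0)
    stop("no geometry has a reference gap below the cut of ", gap_cut_ev, " eV")
  sur <- vapply(geometries[sel], function(x) {
    e <- eval_properties(surrogate, x)$energies
    (e[j] - e[i]) * .ev_per_hartree
  }, numeric(1))
  diffs <- sur - ref[sel]
  boots <- local_seed(seed, vapply(seq_len(n_boot), function(b)
    mean(diffs[sample.int(length(diffs), replace = TRUE)]), numeric(1)))
  alpha <- (1 - conf) / 2
  list(count = length(sel), mean_diff_ev = mean(diffs),
       sd_diff_ev = stats::sd(diffs),
       ci_ev = unname(stats::quantile(boots, c(alpha, 1 - alpha))),
       ref_gaps_ev = ref[sel], sur_gaps_ev = sur)
}

#' Two-dimensional potential-energy scan around a geometry
#'
#' Tabulates all state energies on a 2-D grid spanned by two displacement
#' directions (e.g. around a MECI, to visualize the seam). Failed
#' evaluations are recorded as NA and the scan continues.
#'
#' @param provider An `es_provider`.
#' @param x_center Flat center coordinates (Bohr).
#' @param dir1,dir2 Displacement direction vectors (Bohr; applied as
#'   `x_center + a*dir1 + b*dir2`).
#' @param grid1,grid2 Numeric grids of scan amplitudes `a` and `b`.
#' @return Long-format data frame with columns `a`, `b` and one energy
#'   column per state (Hartree).
#' @export
seam_scan <- function(provider, x_center, dir1, dir2, grid1, grid2) {
  nS <- provider$n_states
  rows <- list()
  for (a in grid1) for (b in grid2) {
    e <- tryCatch(eval_properties(provider, x_center + a * dir1 + b * dir2)$energies,
                  error = function(err) rep(NA_real_, nS))
    rows[[length(rows) + 1L]] <- c(a = a, b = b,
                                   stats::setNames(e, paste0("e", seq_len(nS) - 1L)))
  }
  as.data.frame(do.call(rbind, rows))
}
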