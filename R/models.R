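#' Diagonalize an electronic Hamiltonian
#'
#' Returns adiabatic energies in ascending order and orthonormal eigenvectors.
#' With `deterministic_sign = TRUE` each eigenvector is normalized to a fixed
#' sign convention (its largest-magnitude component made positive), so
#' repeated calls at the same geometry are bitwise identical.
#'
#' @param H Symmetric, finite numeric matrix.
#' @param deterministic_sign Apply the fixed sign convention (default TRUE).
#' @return List with `energies` (ascending) and `vectors` (orthonormal
#'   columns, `H %*% U == U %*% diag(E)`).
#' @export
#' @examples
#' adiabatize(matrix(c(0, 0.1, 0.1, 1), 2, 2))
adiabatize <- function(H, deterministic_sign = TRUE) {
  if (!is.matrix(H) || nrow(H) != ncol(H) || !all(is.finite(H)))
    stop("H must be a finite square matrix")
  if (max(abs(H - t(H))) > 1e-10 * max(1, max(abs(H))))
    stop("H must be symmetric")
  e <- eigen((H + t(H)) / 2, symmetric = TRUE)
  ord <- order(e$values)
  E <- e$values[ord]
  U <- e$vectors[, ord, drop = FALSE]
  if (deterministic_sign) {
    for (k in seq_len(ncol(U))) {
      m <- which.max(abs(U[, k]))
      if (U[m, k] < 0) U[, k] <- -U[, k]
    }
  }
  list(energies = E, vectors = U)
}

# Deterministic counter-based sign stream for eigenvector phase
# randomization. Independent of R's global RNG so that model providers never
# perturb the dynamics RNG stream; exact-integer LCG arithmetic in doubles.
phase_sign_stream <- function(seed, counter, n) {
  x <- (as.double(seed) * 69069 + as.double(counter) * 104729 + 12345) %% 2^31
  out <- integer(n)
  for (k in seq_len(n)) {
    x <- (69069 * x + 12345) %% 2^31
    out[k] <- if (x < 2^30) -1L else 1L
  }
  out
}

#' Analytic diabatic model Hamiltonian provider
#'
#' Wraps a matrix-valued function H(R) with analytic derivatives into an
#' electronic-structure provider: [eval_properties()] diagonalizes H,
#' obtains gradients by the Hellmann-Feynman theorem
#' \eqn{G_i = U_i^T (\partial H/\partial R) U_i} and NAC vectors as
#' \eqn{d_{ij} = U_i^T (\partial H/\partial R) U_j / (E_j - E_i)}.
#'
#' With `randomize_phase = TRUE` every evaluation multiplies each eigenvector
#' by an independent random sign (from a seeded stream separate from the
#' dynamics RNG), flipping all off-diagonal properties accordingly. This
#' reproduces the arbitrary wavefunction phases of real quantum-chemistry
#' output, the phenomenon the phase-correction module removes.
#'
#' @param name Model name.
#' @param n_states Number of electronic states.
#' @param n_dof Number of nuclear degrees of freedom (3N Cartesian, or 1 for
#'   one-dimensional models).
#' @param hfun Function of the flat coordinate vector returning
#'   `list(H = <n_states x n_states>, dH = <n_states x n_states x n_dof>)`.
#' @param masses Per-dof masses in atomic units (electron masses).
#' @param dipole_fun Optional function returning an n x n x n_comp diabatic
#'   dipole operator array.
#' @param soc_fun Optional function returning a symmetric n x n diabatic SOC
#'   matrix (zero diagonal).
#' @param randomize_phase Randomize eigenvector signs per call.
#' @param phase_seed Seed of the phase-randomization stream.
#' @param degeneracy_floor Minimum |E_j - E_i| (Hartree) used in the NAC
#'   denominator; gaps below it are flagged and the NAC capped.
#' @param atoms Optional element labels (Cartesian models), enabling
#'   geometry-based helpers.
#' @param params Optional list of model parameters, kept for provenance.
#' @return An object of class `c("diabatic_model", "es_provider")`.
#' @export
diabatic_model <- function(name, n_states, n_dof, hfun, masses,
                           dipole_fun = NULL, soc_fun = NULL,
                           randomize_phase = FALSE, phase_seed = 1L,
                           degeneracy_floor = 1e-8, atoms = NULL,
                           params = list()) {
  stopifnot(n_states >= 2, n_dof >= 1, length(masses) == n_dof)
  env <- new.env(parent = emptyenv())
  env$counter <- 0L
  structure(list(
    name = name, n_states = n_states, n_dof = n_dof, hfun = hfun,
    masses = masses, dipole_fun = dipole_fun, soc_fun = soc_fun,
    randomize_phase = randomize_phase, phase_seed = as.integer(phase_seed),
    degeneracy_floor = degeneracy_floor, atoms = atoms, params = params,
    state = env
  ), class = c("diabatic_model", "es_provider"))
}

#' @export
print.diabatic_model <- function(x, ...) {
  cat(sprintf("<diabatic_model '%s'> %d states, %d dof, randomize_phase=%s\n",
              x$name, x$n_states, x$n_dof, x$randomize_phase))
  invisible(x)
}

#' Evaluate electronic properties at a geometry
#'
#' Generic provider interface shared by analytic diabatic models, trained
#' neural-network models and NN ensembles.
#'
#' @param provider An `es_provider` (diabatic model, `nn_model` or
#'   `nn_ensemble`).
#' @param x Flat coordinate vector (Bohr) of length `provider$n_dof`, or a
#'   `geometry`.
#' @param ... Passed to methods.
#' @return An [elecprops()] object.
#' @export
eval_properties <- function(provider, x, ...) UseMethod("eval_properties")

#' @rdname eval_properties
#' @export
eval_properties.diabatic_model <- function(provider, x, ...) {
  if (inherits(x, "geometry")) x <- flatten_coords(x)
  if (length(x) != provider$n_dof || !all(is.finite(x)))
    stop("coordinate vector must be finite and of length n_dof")
  hd <- provider$hfun(x)
  ad <- adiabatize(hd$H, deterministic_sign = TRUE)
  n <- provider$n_states
  nd <- provider$n_dof
  E <- ad$energies
  U <- ad$vectors
  pr <- state_pairs(n)
  grads <- matrix(0, n, nd)
  nacs <- matrix(0, nrow(pr), nd)
  degenerate <- rep(FALSE, nrow(pr))
  for (k in seq_len(nd)) {
    Mk <- crossprod(U, hd$dH[, , k] %*% U)
    grads[, k] <- diag(Mk)
    for (p in seq_len(nrow(pr))) {
      dE <- E[pr[p, 2]] - E[pr[p, 1]]
      if (abs(dE) < provider$degeneracy_floor) {
        dE <- provider$degeneracy_floor
        degenerate[p] <- TRUE
      }
      nacs[p, k] <- Mk[pr[p, 1], pr[p, 2]] / dE
    }
  }
  dip <- NULL
  if (!is.null(provider$dipole_fun)) {
    dd <- provider$dipole_fun(x)
    dip <- array(0, dim(dd))
    for (cc in seq_len(dim(dd)[3]))
      dip[, , cc] <- crossprod(U, dd[, , cc] %*% U)
  }
  soc <- NULL
  if (!is.null(provider$soc_fun)) {
    soc <- crossprod(U, provider$soc_fun(x) %*% U)
    diag(soc) <- 0
  }
  props <- elecprops(E, grads, nacs, dipoles = dip, socs = soc, eigvecs = U,
                     degenerate_pairs = degenerate)
  if (isTRUE(provider$randomize_phase)) {
    provider$state$counter <- provider$state$counter + 1L
    signs <- phase_sign_stream(provider$phase_seed, provider$state$counter, n)
    props <- apply_phase(props, phase_vector(signs))
  }
  props
}

# ---------------------------------------------------------------------------
# Bundled models
# ---------------------------------------------------------------------------

#' Bundled one-dimensional two-state avoided-crossing model
#'
#' A Tully-style single avoided crossing: diabatic energies
#' \eqn{\pm A \tanh(B R)} coupled by a Gaussian \eqn{C e^{-D R^2}}, with a
#' smooth dipole operator and a small scalar SOC operator so every property
#' head of the NN can be exercised. The adiabatic gap minimum (2C) sits at
#' R = 0, where the NAC peaks. Mass defaults to 2000 electron masses
#' (proton-like reduced mass).
#'
#' @param A,B,C,D Model parameters (Hartree / Bohr based).
#' @param mass Mass in atomic units.
#' @param randomize_phase,phase_seed Passed to [diabatic_model()].
#' @return A `diabatic_model` with `n_states = 2`, `n_dof = 1`.
#' @export
model_avoided_crossing <- function(A = 0.01, B = 1.6, C = 0.005, D = 1.0,
                                   mass = 2000, randomize_phase = FALSE,
                                   phase_seed = 1L) {
  hfun <- function(x) {
    R <- x[1]
    th <- tanh(B * R)
    v12 <- C * exp(-D * R^2)
    H <- matrix(c(A * th, v12, v12, -A * th), 2, 2)
    sech2 <- 1 / cosh(B * R)^2
    d12 <- -2 * C * D * R * exp(-D * R^2)
    dH <- array(c(A * B * sech2, d12, d12, -A * B * sech2), c(2, 2, 1))
    list(H = H, dH = dH)
  }
  dipole_fun <- function(x) {
    R <- x[1]
    array(c(1 + 0.1 * R, 0.2 * exp(-R^2 / 4),
            0.2 * exp(-R^2 / 4), -1 - 0.1 * R), c(2, 2, 1))
  }
  soc_fun <- function(x) {
    s <- 1e-4 * (1 + 0.1 * x[1])
    matrix(c(0, s, s, 0), 2, 2)
  }
  diabatic_model("avoided_crossing_1d", 2L, 1L, hfun, masses = mass,
                 dipole_fun = dipole_fun, soc_fun = soc_fun,
                 randomize_phase = randomize_phase, phase_seed = phase_seed,
                 params = list(A = A, B = B, C = C, D = D, mass = mass))
}

#' Bundled one-dimensional three-state sequential-decay model
#'
#' Three displaced harmonic diabats coupled pairwise by Gaussians centered at
#' the diabatic crossing points, mimicking S2 -> S1 -> S0 internal-conversion
#' kinetics after vertical excitation: a wavepacket launched on the highest
#' state at the ground-state minimum slides through the S2/S1 and then the
#' S1/S0 coupling regions. The harmonic frequency (omega = sqrt(k/m)
#' ~ 0.004 a.u., period ~38 fs) is low enough that a 0.5 fs velocity-Verlet
#' step conserves energy tightly.
#'
#' @param k Force constant (Hartree/Bohr^2).
#' @param shifts Minima positions of the three diabats (Bohr).
#' @param offsets Vertical offsets of the three diabats (Hartree).
#' @param coupling Gaussian coupling amplitudes `c(V12, V23, V13)` (Hartree);
#'   each pair of diabats is coupled at its crossing point so every diabatic
#'   crossing is avoided.
#' @param width Gaussian coupling width (Bohr).
#' @param mass Mass in atomic units.
#' @param randomize_phase,phase_seed Passed to [diabatic_model()].
#' @return A `diabatic_model` with `n_states = 3`, `n_dof = 1`.
#' @export
model_three_state <- function(k = 0.032, shifts = c(0, 1, 2),
                              offsets = c(0, 0.02, 0.04),
                              coupling = c(0.005, 0.005, 0.002), width = 0.4,
                              mass = 2000, randomize_phase = FALSE,
                              phase_seed = 1L) {
  # diabatic crossing points V_ii = V_jj for every pair
  cross <- function(i, j) {
    # 0.5 k [(R-si)^2 - (R-sj)^2] = oj - oi  -> linear in R
    si <- shifts[i]; sj <- shifts[j]
    (si^2 - sj^2 - (offsets[j] - offsets[i]) / (0.5 * k)) / (2 * (si - sj))
  }
  xc <- c(cross(1, 2), cross(2, 3), cross(1, 3))
  pair_of <- rbind(c(1, 2), c(2, 3), c(1, 3))
  hfun <- function(x) {
    R <- x[1]
    H <- matrix(0, 3, 3)
    dH <- array(0, c(3, 3, 1))
    for (i in 1:3) {
      H[i, i] <- 0.5 * k * (R - shifts[i])^2 + offsets[i]
      dH[i, i, 1] <- k * (R - shifts[i])
    }
    for (p in 1:3) {
      i <- pair_of[p, 1]; j <- pair_of[p, 2]
      g <- coupling[p] * exp(-(R - xc[p])^2 / (2 * width^2))
      H[i, j] <- H[j, i] <- g
      dH[i, j, 1] <- dH[j, i, 1] <- -g * (R - xc[p]) / width^2
    }
    list(H = H, dH = dH)
  }
  dipole_fun <- function(x) {
    R <- x[1]
    M <- matrix(0, 3, 3)
    diag(M) <- c(0.5, -0.5, 0.8) + 0.1 * R
    M[1, 2] <- M[2, 1] <- 0.3 * exp(-R^2 / 8)
    M[2, 3] <- M[3, 2] <- 0.2 * exp(-(R - 1)^2 / 8)
    M[1, 3] <- M[3, 1] <- 0.05
    array(M, c(3, 3, 1))
  }
  diabatic_model("three_state_decay_1d", 3L, 1L, hfun, masses = mass,
                 dipole_fun = dipole_fun,
                 randomize_phase = randomize_phase, phase_seed = phase_seed,
                 params = list(k = k, shifts = shifts, offsets = offsets,
                               coupling = coupling, width = width, mass = mass,
                               crossings = xc))
}

#' Bundled triatomic two-state conical-intersection model
#'
#' A Cartesian (9 degree-of-freedom) two-state model built from the three
#' interatomic distances of a triatomic molecule. Both diabats are harmonic
#' in the bond lengths; they differ in the equilibrium of the third bond and
#' by a vertical offset, and are coupled by
#' \eqn{V_{12} = \gamma (r_{12} - r_{13})}, which vanishes on the symmetric
#' plane r12 = r13. The degeneracy seam is therefore the line
#' r12 = r13, r23 = r23* with
#' \eqn{r_{23}^* = (b + c)/2 + \Delta / (k_3 (c - b))}; the minimum-energy
#' conical intersection lies at r12 = r13 = a, r23 = r23*, a genuine conical
#' intersection with linear splitting along both branching-plane directions.
#'
#' @param k Bond force constant of the two equivalent bonds (Hartree/Bohr^2).
#' @param k3 Force constant of the third bond.
#' @param a Equilibrium length of bonds 1-2 and 1-3 (Bohr).
#' @param b,cc Equilibrium lengths of bond 2-3 on the two diabats (Bohr).
#' @param delta Vertical offset of the second diabat (Hartree).
#' @param gamma Diabatic coupling strength (Hartree/Bohr).
#' @param randomize_phase,phase_seed Passed to [diabatic_model()].
#' @return A `diabatic_model` with `n_states = 2`, `n_dof = 9`; its `params`
#'   record the closed-form seam (`r23_star`) and MECI internal coordinates.
#' @export
model_conical_triatomic <- function(k = 0.3, k3 = 0.15, a = 2.6, b = 2.2,
                                    cc = 3.0, delta = 0.02, gamma = 0.02,
                                    randomize_phase = FALSE, phase_seed = 1L) {
  atoms <- c("C", "C", "C")
  masses <- rep(.atomic_masses[["C"]] * .me_per_amu, 9L)  # per dof
  r23_star <- (b + cc) / 2 + delta / (k3 * (cc - b))
  hfun <- function(x) {
    xm <- matrix(x, 3, 3, byrow = TRUE)
    pairs <- rbind(c(1, 2), c(1, 3), c(2, 3))
    r <- numeric(3)
    drdx <- matrix(0, 3, 9)  # rows: pair, cols: flat dof
    for (p in 1:3) {
      i <- pairs[p, 1]; j <- pairs[p, 2]
      d <- xm[i, ] - xm[j, ]
      r[p] <- sqrt(sum(d^2))
      u <- d / r[p]
      drdx[p, (3 * i - 2):(3 * i)] <- u
      drdx[p, (3 * j - 2):(3 * j)] <- -u
    }
    common <- 0.5 * k * (r[1] - a)^2 + 0.5 * k * (r[2] - a)^2
    v11 <- common + 0.5 * k3 * (r[3] - b)^2
    v22 <- common + 0.5 * k3 * (r[3] - cc)^2 + delta
    v12 <- gamma * (r[1] - r[2])
    H <- matrix(c(v11, v12, v12, v22), 2, 2)
    # dH/dr per pair, then chain rule through drdx
    dH <- array(0, c(2, 2, 9))
    dv11_dr <- c(k * (r[1] - a), k * (r[2] - a), k3 * (r[3] - b))
    dv22_dr <- c(k * (r[1] - a), k * (r[2] - a), k3 * (r[3] - cc))
    dv12_dr <- c(gamma, -gamma, 0)
    for (kk in 1:9) {
      dH[1, 1, kk] <- sum(dv11_dr * drdx[, kk])
      dH[2, 2, kk] <- sum(dv22_dr * drdx[, kk])
      dH[1, 2, kk] <- dH[2, 1, kk] <- sum(dv12_dr * drdx[, kk])
    }
    list(H = H, dH = dH)
  }
  diabatic_model("conical_triatomic", 2L, 9L, hfun, masses = masses,
                 randomize_phase = randomize_phase, phase_seed = phase_seed,
                 atoms = atoms,
                 params = list(k = k, k3 = k3, a = a, b = b, cc = cc,
                               delta = delta, gamma = gamma,
                               r23_star = r23_star,
                               meci_internal = c(a, a, r23_star),
                               min_internal = c(a, a, b)))
}
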