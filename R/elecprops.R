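#' Per-geometry electronic properties
#'
#' The common currency between providers (analytic models or neural networks)
#' and the dynamics/training machinery: adiabatic energies, per-state energy
#' gradients, nonadiabatic coupling (NAC) vectors for ordered state pairs
#' i < j, dipole moments, optional scalar spin-orbit couplings (SOCs) and,
#' for model providers, the diabatic-to-adiabatic eigenvector matrix.
#'
#' NACs are stored once per pair i < j; the antisymmetric partner
#' \eqn{d_{ji} = -d_{ij}} is implied. All quantities are in atomic units.
#'
#' @param energies Numeric vector of adiabatic energies (Hartree), ascending.
#' @param gradients n_states x n_dof matrix of \eqn{\partial E_i/\partial R}
#'   (Hartree/Bohr).
#' @param nacs n_pairs x n_dof matrix of NAC vectors (1/Bohr), pair order from
#'   [state_pairs()].
#' @param dipoles Optional n_states x n_states x n_comp array of permanent
#'   (diagonal) and transition (off-diagonal) dipole moments (a.u.).
#' @param socs Optional symmetric n_states x n_states matrix of scalar SOCs
#'   (Hartree), zero diagonal.
#' @param eigvecs Optional n_states x n_states matrix whose columns are the
#'   adiabatic eigenvectors in the diabatic basis.
#' @param degenerate_pairs Logical vector flagging pairs whose energy gap fell
#'   below the provider's degeneracy floor (NAC magnitude capped there).
#' @return An object of class `"elecprops"`.
#' @export
elecprops <- function(energies, gradients, nacs, dipoles = NULL, socs = NULL,
                      eigvecs = NULL, degenerate_pairs = NULL) {
  n <- length(energies)
  stopifnot(is.matrix(gradients), nrow(gradients) == n)
  pr <- state_pairs(n)
  stopifnot(is.matrix(nacs), nrow(nacs) == nrow(pr))
  structure(list(
    energies = energies, gradients = gradients, nacs = nacs,
    pairs = pr, dipoles = dipoles, socs = socs, eigvecs = eigvecs,
    degenerate_pairs = degenerate_pairs %||% rep(FALSE, nrow(pr))
  ), class = "elecprops")
}

#' @export
print.elecprops <- function(x, ...) {
  cat(sprintf("<elecprops> %d states, %d dof\n", length(x$energies),
              ncol(x$gradients)))
  cat("  E (Ha):", paste(sprintf("%.6f", x$energies), collapse = "  "), "\n")
  invisible(x)
}

#' Expand stored NACs to a full antisymmetric matrix for one degree of freedom
#'
#' @param props An `elecprops`.
#' @param dof Degree-of-freedom index.
#' @return Antisymmetric n_states x n_states matrix with `[i, j]` equal to the
#'   `dof`-th component of \eqn{d_{ij}}.
#' @export
nac_matrix <- function(props, dof) {
  n <- length(props$energies)
  M <- matrix(0, n, n)
  pr <- props$pairs
  for (p in seq_len(nrow(pr))) {
    M[pr[p, 1], pr[p, 2]] <- props$nacs[p, dof]
    M[pr[p, 2], pr[p, 1]] <- -props$nacs[p, dof]
  }
  M
}
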