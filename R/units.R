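# Internal unit system: Hartree, Bohr, electron mass, hbar = 1 (atomic units).
# File I/O and user-facing interfaces use Angstrom, fs and eV.

#' Unit conversion constants
#'
#' Named vector of the fixed conversion constants used throughout the package.
#' Internally everything is computed in atomic units (Hartree, Bohr,
#' electron masses, \eqn{\hbar = 1}); geometries are exchanged in Angstrom,
#' times in femtoseconds and energies in electronvolt at the interfaces.
#'
#' @return Named numeric vector with elements `ang_per_bohr`, `fs_per_aut`
#'   (femtoseconds per atomic time unit), `ev_per_hartree` and `me_per_amu`
#'   (electron masses per unified atomic mass unit).
#' @export
#' @examples
#' au_units()[["ev_per_hartree"]]
au_units <- function() {
  c(
    ang_per_bohr   = 0.52917721067,
    fs_per_aut     = 0.02418884254,
    ev_per_hartree = 27.211386245988,
    me_per_amu     = 1822.888486209
  )
}

.ang_per_bohr <- 0.52917721067
.bohr_per_ang <- 1 / 0.52917721067
.fs_per_aut <- 0.02418884254
.aut_per_fs <- 1 / 0.02418884254
.ev_per_hartree <- 27.211386245988
.me_per_amu <- 1822.888486209

# Standard atomic weights (amu) for the elements the bundled models and the
# XYZ reader need to know about.
.atomic_masses <- c(
  H = 1.008, D = 2.014, He = 4.0026, Li = 6.94, Be = 9.0122, B = 10.81,
  C = 12.011, N = 14.007, O = 15.999, F = 18.998, Ne = 20.180,
  Na = 22.990, Mg = 24.305, Al = 26.982, Si = 28.085, P = 30.974,
  S = 32.06, Cl = 35.45, Ar = 39.948, X = 1.0
)

# Run expr with the global RNG set from `seed`, restoring the caller's RNG
# state afterwards so library internals never perturb user-level streams.
local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Ordered state pairs i < j (row-wise), the canonical storage order for
# couplings; matches the lexicographic pair order of the descriptor.
state_pairs <- function(n_states) {
  if (n_states < 2) return(matrix(integer(0), 0, 2))
  idx <- which(upper.tri(matrix(0, n_states, n_states)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  colnames(idx) <- c("i", "j")
  idx
}

`%||%` <- function(a, b) if (is.null(a)) b else a
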