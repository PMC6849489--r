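# Wavefunction-phase bookkeeping: electronic eigenvectors are defined only up
# to a sign, so off-diagonal properties (NACs, transition dipoles, SOCs)
# computed at nearby geometries can flip sign arbitrarily. Tracking overlaps
# along geometry paths and applying per-state sign corrections makes those
# curves smooth and therefore learnable.

#' Per-state phase (sign) vector
#'
#' @param signs Integer/numeric vector with entries +1 or -1 (NA allowed for
#'   undecided states when `decided` is given).
#' @param decided Logical vector; states with `FALSE` carry no sign.
#' @return Object of class `"phase_vector"` with fields `signs` and `decided`.
#' @export
phase_vector <- function(signs, decided = NULL) {
  if (is.null(decided)) decided <- !is.na(signs)
  signs <- as.integer(signs)
  if (any(decided & !(signs %in% c(-1L, 1L))))
    stop("decided phases must be +1 or -1")
  signs[!decided] <- NA_integer_
  structure(list(signs = signs, decided = decided), class = "phase_vector")
}

#' @export
print.phase_vector <- function(x, ...) {
  s <- ifelse(x$decided, sprintf("%+d", x$signs), "?")
  cat("<phase_vector>", paste(s, collapse = " "), "\n")
  invisible(x)
}

# Elementwise product of phase vectors (undecided propagates).
compose_phases <- function(a, b) {
  phase_vector(a$signs * b$signs, a$decided & b$decided)
}

#' Overlap matrix between two sets of electronic eigenvectors
#'
#' \eqn{S_{kl} = U_{a,k}^T U_{b,l}}: for orthonormal inputs computed at nearby
#' geometries the diagonal carries values close to +1 or -1, from which phase
#' changes can be read off.
#'
#' @param eigvecs_a,eigvecs_b Matrices with orthonormal eigenvector columns of
#'   equal dimension.
#' @return The overlap matrix.
#' @export
overlap <- function(eigvecs_a, eigvecs_b) {
  if (!is.matrix(eigvecs_a) || !is.matrix(eigvecs_b) ||
      any(dim(eigvecs_a) != dim(eigvecs_b)))
    stop("eigenvector sets must be matrices of identical dimension")
  crossprod(eigvecs_a, eigvecs_b)
}

#' Decide per-state phases from an overlap matrix
#'
#' State k is decided with sign(S_kk) iff |S_kk| >= `decision_threshold`;
#' otherwise it is left undecided (geometries too far apart, or the state has
#' rotated into another one).
#'
#' @param S Overlap matrix from [overlap()].
#' @param decision_threshold Minimum |diagonal overlap| to decide a state
#'   (default 0.5).
#' @return A [phase_vector()].
#' @export
detect_phases <- function(S, decision_threshold = 0.5) {
  d <- diag(S)
  decided <- abs(d) >= decision_threshold
  signs <- ifelse(d >= 0, 1L, -1L)
  phase_vector(ifelse(decided, signs, NA_integer_), decided)
}

#' Apply a phase correction to electronic properties
#'
#' Multiplies every off-diagonal element ij (NACs, transition dipoles, SOCs)
#' by \eqn{p_i p_j} and every eigenvector column by \eqn{p_i}. Energies,
#' gradients and permanent dipoles are untouched: diagonal observables square
#' the phase away. Applying the same phase twice is the identity.
#'
#' @param props An [elecprops()].
#' @param p A fully decided [phase_vector()].
#' @return The corrected `elecprops`.
#' @export
apply_phase <- function(props, p) {
  if (!all(p$decided))
    stop("refusing to apply an undecided phase vector (states: ",
         paste(which(!p$decided), collapse = ", "), ")")
  n <- length(props$energies)
  stopifnot(length(p$signs) == n)
  s <- as.numeric(p$signs)
  pr <- props$pairs
  for (q in seq_len(nrow(pr)))
    props$nacs[q, ] <- props$nacs[q, ] * s[pr[q, 1]] * s[pr[q, 2]]
  if (!is.null(props$dipoles)) {
    for (cc in seq_len(dim(props$dipoles)[3])) {
      M <- props$dipoles[, , cc]
      M <- M * tcrossprod(s)
      diag(M) <- diag(props$dipoles[, , cc])
      props$dipoles[, , cc] <- M
    }
  }
  if (!is.null(props$socs)) {
    props$socs <- props$socs * tcrossprod(s)
    diag(props$socs) <- 0
  }
  if (!is.null(props$eigvecs))
    props$eigvecs <- sweep(props$eigvecs, 2, s, "*")
  props
}

#' Track wavefunction phases between two geometries
#'
#' Computes the overlap between the eigenvector sets of two geometries. If
#' every state is decided (|diagonal overlap| above the threshold) the phase
#' vector is returned directly; otherwise the straight-line path between the
#' geometries is bisected recursively, the provider is evaluated at the
#' midpoint, and the per-segment phase vectors are chained by elementwise
#' product. Random eigenvector signs at the midpoints cancel in the product,
#' so tracking is well-defined even for phase-randomizing providers.
#'
#' @param geom_ref,geom_new Flat coordinate vectors (Bohr).
#' @param provider An `es_provider` exposing eigenvectors.
#' @param eigvecs_ref,eigvecs_new Optional stored endpoint eigenvectors (e.g.
#'   from dataset records); evaluated from `provider` when omitted.
#' @param decision_threshold Passed to [detect_phases()].
#' @param max_bisections Maximum recursion depth before giving up.
#' @return A fully decided [phase_vector()] relating `geom_new` to
#'   `geom_ref`; error if states remain undecided at the deepest level.
#' @export
track_phases <- function(geom_ref, geom_new, provider,
                         eigvecs_ref = NULL, eigvecs_new = NULL,
                         decision_threshold = 0.5, max_bisections = 10) {
  if (is.null(eigvecs_ref))
    eigvecs_ref <- eval_properties(provider, geom_ref)$eigvecs
  if (is.null(eigvecs_new))
    eigvecs_new <- eval_properties(provider, geom_new)$eigvecs
  if (is.null(eigvecs_ref) || is.null(eigvecs_new))
    stop("provider does not expose eigenvectors; phase tracking impossible")
  rec <- function(xa, Ua, xb, Ub, depth) {
    p <- detect_phases(overlap(Ua, Ub), decision_threshold)
    if (all(p$decided)) return(p)
    if (depth >= max_bisections)
      stop("phase tracking failed after ", max_bisections,
           " bisections; undecided states: ",
           paste(which(!p$decided), collapse = ", "))
    xm <- (xa + xb) / 2
    Um <- eval_properties(provider, xm)$eigvecs
    compose_phases(rec(xa, Ua, xm, Um, depth + 1L),
                   rec(xm, Um, xb, Ub, depth + 1L))
  }
  rec(as.numeric(geom_ref), eigvecs_ref, as.numeric(geom_new), eigvecs_new, 0L)
}

#' Phase-correct a whole training dataset
#'
#' Tracks the phases of every record's wavefunctions from a single reference
#' record and applies the per-record sign corrections, establishing one
#' virtual global phase convention across the training set so that
#' off-diagonal property curves become smooth functions of geometry.
#'
#' @param dataset A dataset created with [new_dataset()].
#' @param provider The provider that generated the records (used for midpoint
#'   evaluations during tracking).
#' @param reference_index Record establishing the phase convention
#'   (default: the dataset header's `phase_reference`, else 1).
#' @param decision_threshold,max_bisections Passed to [track_phases()].
#' @return The corrected dataset; each record gains a `phase` field logging
#'   the applied signs, and the header records the reference index.
#' @export
phase_correct_dataset <- function(dataset, provider, reference_index = NULL,
                                  decision_threshold = 0.5,
                                  max_bisections = 10) {
  nr <- length(dataset$records)
  if (nr == 0) stop("empty dataset")
  ref <- reference_index %||% dataset$header$phase_reference %||% 1L
  if (ref < 1 || ref > nr) stop("invalid reference index ", ref)
  refrec <- dataset$records[[ref]]
  for (r in seq_len(nr)) {
    rec <- dataset$records[[r]]
    if (r == ref) {
      p <- phase_vector(rep(1L, length(rec$props$energies)))
    } else {
      p <- tryCatch(
        track_phases(refrec$x, rec$x, provider,
                     eigvecs_ref = refrec$props$eigvecs,
                     eigvecs_new = rec$props$eigvecs,
                     decision_threshold = decision_threshold,
                     max_bisections = max_bisections),
        error = function(e) stop("phase correction failed at record ", r,
                                 ": ", conditionMessage(e)))
    }
    rec$props <- apply_phase(rec$props, p)
    rec$phase <- p$signs
    dataset$records[[r]] <- rec
  }
  dataset$header$phase_reference <- ref
  dataset
}
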