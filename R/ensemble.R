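#' Ensemble of independently trained NN models
#'
#' Two or more networks trained on the same training set with different
#' seeds. Predictions used for propagation are the member mean; the spread
#' between members (see [disagreement()]) is the uncertainty signal that
#' drives adaptive sampling and audits production dynamics.
#'
#' @param members List of `nn_model` objects (>= 2) with identical state and
#'   dof counts.
#' @return Object of class `c("nn_ensemble", "es_provider")`.
#' @export
nn_ensemble <- function(members) {
  if (length(members) < 2) stop("an ensemble needs at least two members")
  ns <- vapply(members, function(m) m$n_states, integer(1))
  nd <- vapply(members, function(m) m$n_dof, integer(1))
  if (length(unique(ns)) != 1 || length(unique(nd)) != 1)
    stop("ensemble members disagree on state/dof counts")
  structure(list(members = members, n_states = ns[1], n_dof = nd[1],
                 masses = members[[1]]$masses),
            class = c("nn_ensemble", "es_provider"))
}

#' @export
print.nn_ensemble <- function(x, ...) {
  cat(sprintf("<nn_ensemble> %d members, %d states, %d dof\n",
              length(x$members), x$n_states, x$n_dof))
  invisible(x)
}

#' Train an NN ensemble
#'
#' @param ts A [training_set()].
#' @param hyperparams Shared hyperparameters (see [train_nn()]).
#' @param n_members Ensemble size (default 2).
#' @param seed Base seed; member k trains with `seed + k`.
#' @return An [nn_ensemble()].
#' @export
train_ensemble <- function(ts, hyperparams = list(), n_members = 2, seed = 1) {
  nn_ensemble(lapply(seq_len(n_members), function(k)
    train_nn(ts, hyperparams = hyperparams, seed = seed + k)))
}

#' Ensemble disagreement per property
#'
#' For each property, the root-mean-square deviation of the member
#' predictions from the member mean, pooled over all components of that
#' property. Identical members give 0; two members differing by delta in a
#' scalar give delta/2.
#'
#' @param preds List of [elecprops()] predictions at one geometry (>= 2).
#' @return Named numeric vector (energies, gradients, nacs, and dipoles/socs
#'   when present).
#' @export
disagreement <- function(preds) {
  if (length(preds) < 2) stop("need at least two member predictions")
  pool <- function(get) {
    vals <- lapply(preds, get)
    if (any(vapply(vals, is.null, logical(1)))) return(NULL)
    sh <- lapply(vals, function(v) dim(v) %||% length(v))
    if (length(unique(vapply(sh, paste, character(1), collapse = "x"))) != 1)
      stop("mismatched prediction shapes across members")
    M <- do.call(rbind, lapply(vals, as.vector))
    dev <- sweep(M, 2, colMeans(M))
    sqrt(mean(dev^2))
  }
  out <- c(energies = pool(function(p) p$energies),
           gradients = pool(function(p) p$gradients),
           nacs = pool(function(p) p$nacs))
  d <- pool(function(p) p$dipoles)
  if (!is.null(d)) out <- c(out, dipoles = d)
  s <- pool(function(p) p$socs)
  if (!is.null(s)) out <- c(out, socs = s)
  out
}

#' @rdname eval_properties
#' @export
eval_properties.nn_ensemble <- function(provider, x, ...) {
  preds <- lapply(provider$members, eval_properties, x = x)
  avg <- preds[[1]]
  nm <- length(preds)
  avg$energies <- Reduce(`+`, lapply(preds, `[[`, "energies")) / nm
  avg$gradients <- Reduce(`+`, lapply(preds, `[[`, "gradients")) / nm
  avg$nacs <- Reduce(`+`, lapply(preds, `[[`, "nacs")) / nm
  if (!is.null(avg$dipoles))
    avg$dipoles <- Reduce(`+`, lapply(preds, `[[`, "dipoles")) / nm
  if (!is.null(avg$socs))
    avg$socs <- Reduce(`+`, lapply(preds, `[[`, "socs")) / nm
  avg$disagreement <- disagreement(preds)
  avg
}
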