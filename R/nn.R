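# Feed-forward NN surrogate for the electronic-structure provider.
#
# One network predicts all states jointly: a shared trunk on the descriptor
# with shifted-softplus activations feeds one linear head per property block
# (energies, NAC vectors, dipoles, optional SOCs). Forces are NEVER a
# separate head: they are the exact analytic derivative of the energy head
# through the descriptor Jacobian, which makes the predicted force field
# conservative and energy-conserving in dynamics. Training the force loss
# therefore requires differentiating the input-gradient of the network with
# respect to the weights; this is done with an explicit forward-tangent /
# reverse pass (Hessian-vector products), implemented below in plain matrix
# algebra and guarded by finite-difference tests.

ssp <- function(x) pmax(x, 0) + log1p(exp(-abs(x))) - log(2)
dssp <- function(x) stats::plogis(x)
d2ssp <- function(x) { s <- stats::plogis(x); s * (1 - s) }

default_hyperparams <- function() {
  list(
    hidden = c(50, 50),
    lr = 5e-3,
    lr_decay = 1,       # <1: lr decays exponentially to lr*lr_decay at the last epoch
    epochs = 3000,
    eval_every = 10,
    patience = 40,      # evaluation checks without val improvement
    early_stopping = TRUE,  # FALSE: keep the final-epoch weights (e.g. for
                            # deliberate memorization runs)
    weights = list(energy = 1, force = 1, nac = 0.1, dipole = 0.1, soc = 0.1)
  )
}

merge_hyperparams <- function(hp) {
  def <- default_hyperparams()
  for (nm in names(hp)) {
    if (!nm %in% names(def)) stop("unknown hyperparameter: ", nm)
    if (nm == "weights") {
      for (w in names(hp$weights)) {
        if (!w %in% names(def$weights)) stop("unknown loss weight: ", w)
        def$weights[[w]] <- hp$weights[[w]]
      }
    } else def[[nm]] <- hp[[nm]]
  }
  def
}

# ---------------------------------------------------------------------------
# Training set
# ---------------------------------------------------------------------------

#' Assemble a training set from a dataset
#'
#' Splits the (phase-corrected) records of a dataset into disjoint training
#' and validation sets.
#'
#' @param dataset Dataset from [new_dataset()] (records carry flat
#'   coordinates `x` and [elecprops()] `props`).
#' @param validation_fraction Fraction of records held out for validation
#'   (at least one record).
#' @param seed Seed for the random split.
#' @return Object of class `"training_set"` with fields `records`, `header`,
#'   and `split` (`$train`, `$val` index vectors).
#' @export
training_set <- function(dataset, validation_fraction = 0.1, seed = 1) {
  n <- length(dataset$records)
  if (n < 2) stop("need at least two records to form a train/validation split")
  n_val <- max(1L, round(validation_fraction * n))
  if (n_val >= n) stop("validation fraction leaves no training records")
  idx <- local_seed(seed, sample.int(n))
  structure(list(records = dataset$records, header = dataset$header,
                 split = list(train = sort(idx[seq_len(n - n_val)]),
                              val = sort(idx[(n - n_val + 1L):n]))),
            class = "training_set")
}

# Stack records into dense design matrices (raw units).
build_matrices <- function(records, spec) {
  n <- length(records)
  nS <- length(records[[1]]$props$energies)
  nD <- spec$n_dof
  nP <- nS * (nS - 1) / 2
  D <- matrix(0, n, spec$n_in)
  J <- vector("list", nD)             # per dof: n x n_in
  for (k in seq_len(nD)) J[[k]] <- matrix(0, n, spec$n_in)
  E <- matrix(0, n, nS)
  G <- array(0, c(n, nS, nD))
  NAC <- matrix(0, n, nP * nD)
  has_dip <- !is.null(records[[1]]$props$dipoles)
  n_comp <- if (has_dip) dim(records[[1]]$props$dipoles)[3] else 0L
  dip_pairs <- which(upper.tri(matrix(0, nS, nS), diag = TRUE), arr.ind = TRUE)
  dip_pairs <- dip_pairs[order(dip_pairs[, 1], dip_pairs[, 2]), , drop = FALSE]
  DIP <- if (has_dip) matrix(0, n, nrow(dip_pairs) * n_comp) else NULL
  has_soc <- !is.null(records[[1]]$props$socs)
  SOC <- if (has_soc) matrix(0, n, nP) else NULL
  pr <- state_pairs(nS)
  for (r in seq_len(n)) {
    rec <- records[[r]]
    ds <- compute_descriptor(spec, rec$x)
    D[r, ] <- ds$values
    for (k in seq_len(nD)) J[[k]][r, ] <- ds$jacobian[, k]
    E[r, ] <- rec$props$energies
    G[r, , ] <- rec$props$gradients
    NAC[r, ] <- as.vector(t(rec$props$nacs))      # pair-major, dof within
    if (has_dip) {
      v <- numeric(0)
      for (q in seq_len(nrow(dip_pairs)))
        v <- c(v, rec$props$dipoles[dip_pairs[q, 1], dip_pairs[q, 2], ])
      DIP[r, ] <- v
    }
    if (has_soc)
      SOC[r, ] <- rec$props$socs[pr]
  }
  list(D = D, J = J, E = E, G = G, NAC = NAC, DIP = DIP, SOC = SOC,
       n = n, nS = nS, nD = nD, nP = nP, n_comp = n_comp,
       dip_pairs = dip_pairs)
}

# Normalization statistics from the training matrices.
compute_norm <- function(m) {
  sd0 <- function(v) { s <- stats::sd(as.vector(v)); if (!is.finite(s) || s == 0) 1 else s }
  list(
    x_mu = colMeans(m$D),
    x_sd = apply(m$D, 2, function(col) { s <- stats::sd(col); if (!is.finite(s) || s == 0) 1 else s }),
    e_mu = mean(m$E), e_sd = sd0(m$E),
    g_scale = sd0(m$G),
    nac_scale = sd0(m$NAC),
    dip_mu = if (!is.null(m$DIP)) colMeans(m$DIP) else NULL,
    dip_scale = if (!is.null(m$DIP)) sd0(sweep(m$DIP, 2, colMeans(m$DIP))) else NULL,
    soc_scale = if (!is.null(m$SOC)) sd0(m$SOC) else NULL
  )
}

# Standardize matrices and pre-fold the descriptor standardization and the
# energy scale into the Jacobian (Jt[[k]][r, m] = e_sd * J / x_sd[m]), so the
# raw Cartesian gradient is Ghat %*% "Jt" exactly.
standardize_data <- function(m, norm) {
  Dh <- sweep(sweep(m$D, 2, norm$x_mu), 2, norm$x_sd, "/")
  Jt <- lapply(m$J, function(Jk) sweep(Jk, 2, norm$x_sd, "/") * norm$e_sd)
  list(
    D = Dh, Jt = Jt,
    E = (m$E - norm$e_mu) / norm$e_sd,
    G = m$G,                                    # raw; loss divides by g_scale
    NAC = m$NAC / norm$nac_scale,
    DIP = if (!is.null(m$DIP)) sweep(sweep(m$DIP, 2, norm$dip_mu), 2, norm$dip_scale, "/") else NULL,
    SOC = if (!is.null(m$SOC)) m$SOC / norm$soc_scale else NULL,
    n = m$n, nS = m$nS, nD = m$nD, nP = m$nP, n_comp = m$n_comp
  )
}

# ---------------------------------------------------------------------------
# Parameters, forward and backward passes
# ---------------------------------------------------------------------------

init_params <- function(n_in, hidden, heads_dims, seed) {
  local_seed(seed, {
    dims <- c(n_in, hidden)
    W <- vector("list", length(hidden)); b <- vector("list", length(hidden))
    for (l in seq_along(hidden)) {
      W[[l]] <- matrix(stats::rnorm(dims[l + 1] * dims[l], sd = sqrt(1 / dims[l])),
                       dims[l + 1], dims[l])
      b[[l]] <- rep(0, dims[l + 1])
    }
    hL <- hidden[length(hidden)]
    heads <- lapply(heads_dims, function(out) {
      list(W = matrix(stats::rnorm(out * hL, sd = sqrt(1 / hL)), out, hL),
           b = rep(0, out))
    })
    list(W = W, b = b, heads = heads)
  })
}

nn_forward_trunk <- function(params, D) {
  L <- length(params$W)
  Z <- vector("list", L); A <- vector("list", L)
  Aprev <- D
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(Aprev %*% t(params$W[[l]]), 2, params$b[[l]], "+")
    A[[l]] <- ssp(Z[[l]])
    Aprev <- A[[l]]
  }
  list(Z = Z, A = A)
}

head_out <- function(head, AL) sweep(AL %*% t(head$W), 2, head$b, "+")

# Batch gradient of the standardized energy of state i with respect to the
# standardized descriptor (n x n_in).
grad_std_energy <- function(params, Z, i) {
  L <- length(params$W)
  n <- nrow(Z[[L]])
  cur <- matrix(params$heads$energy$W[i, ], n, ncol(Z[[L]]), byrow = TRUE)
  for (l in L:1) {
    cur <- dssp(Z[[l]]) * cur
    cur <- cur %*% params$W[[l]]
  }
  cur
}

zero_like <- function(params) {
  list(W = lapply(params$W, function(w) w * 0),
       b = lapply(params$b, function(x) x * 0),
       heads = lapply(params$heads, function(h) list(W = h$W * 0, b = h$b * 0)))
}

# Loss and full weight-gradient. `dat` is standardized data from
# standardize_data(); `w` the per-property loss weights; g_scale the raw
# force-residual scale.
nn_loss_grad <- function(params, dat, w, g_scale, want_grad = TRUE) {
  L <- length(params$W)
  n <- dat$n; nS <- dat$nS; nD <- dat$nD
  fw <- nn_forward_trunk(params, dat$D)
  AL <- fw$A[[L]]
  g <- if (want_grad) zero_like(params) else NULL
  loss <- list()

  # --- standard (zeroth-order) heads ------------------------------------
  head_dY <- list()
  Epred <- head_out(params$heads$energy, AL)
  eres <- Epred - dat$E
  loss$energy <- mean(eres^2)
  head_dY$energy <- 2 * w$energy * eres / length(eres)
  if (!is.null(params$heads$nac)) {
    Yn <- head_out(params$heads$nac, AL)
    nres <- Yn - dat$NAC
    loss$nac <- mean(nres^2)
    head_dY$nac <- 2 * w$nac * nres / length(nres)
  }
  if (!is.null(params$heads$dip)) {
    Yd <- head_out(params$heads$dip, AL)
    dres <- Yd - dat$DIP
    loss$dipole <- mean(dres^2)
    head_dY$dip <- 2 * w$dipole * dres / length(dres)
  }
  if (!is.null(params$heads$soc)) {
    Ys <- head_out(params$heads$soc, AL)
    sres <- Ys - dat$SOC
    loss$soc <- mean(sres^2)
    head_dY$soc <- 2 * w$soc * sres / length(sres)
  }

  # --- force loss through the analytic derivative of the energy head ----
  U_adj <- NULL
  if (w$force > 0) {
    U_adj <- vector("list", nS)
    fcoef <- 2 * w$force / (n * nS * nD * g_scale^2)
    loss_f <- 0
    for (i in seq_len(nS)) {
      Ghat <- grad_std_energy(params, fw$Z, i)       # n x n_in (std units)
      Gpred <- matrix(0, n, nD)
      for (k in seq_len(nD)) Gpred[, k] <- rowSums(Ghat * dat$Jt[[k]])
      Ri <- Gpred - matrix(dat$G[, i, ], n, nD)
      loss_f <- loss_f + sum(Ri^2)
      if (want_grad) {
        Ui <- matrix(0, n, ncol(Ghat))
        for (k in seq_len(nD)) Ui <- Ui + dat$Jt[[k]] * Ri[, k]
        U_adj[[i]] <- fcoef * Ui
      }
    }
    loss$force <- loss_f / (n * nS * nD * g_scale^2)
  }

  total <- w$energy * loss$energy +
    (if (!is.null(loss$force)) w$force * loss$force else 0) +
    (if (!is.null(loss$nac)) w$nac * loss$nac else 0) +
    (if (!is.null(loss$dipole)) w$dipole * loss$dipole else 0) +
    (if (!is.null(loss$soc)) w$soc * loss$soc else 0)
  if (!want_grad) return(list(total = total, parts = loss))
  if (!is.finite(total)) stop("training diverged: non-finite loss")

  # --- reverse pass for the zeroth-order heads ---------------------------
  dAL <- matrix(0, n, ncol(AL))
  for (nm in names(head_dY)) {
    dY <- head_dY[[nm]]
    g$heads[[nm]]$W <- g$heads[[nm]]$W + crossprod(dY, AL)
    g$heads[[nm]]$b <- g$heads[[nm]]$b + colSums(dY)
    dAL <- dAL + dY %*% params$heads[[nm]]$W
  }
  dA <- dAL
  for (l in L:1) {
    dZ <- dssp(fw$Z[[l]]) * dA
    Aprev <- if (l > 1) fw$A[[l - 1]] else dat$D
    g$W[[l]] <- g$W[[l]] + crossprod(dZ, Aprev)
    g$b[[l]] <- g$b[[l]] + colSums(dZ)
    if (l > 1) dA <- dZ %*% params$W[[l]]
  }

  # --- second-order pass: d/dtheta of the input-gradient ------------------
  # For each state, the force-loss gradient is a Hessian-vector product: the
  # derivative w.r.t. the weights of the directional derivative of E_i along
  # the (fixed) adjoint direction U_i in descriptor space. Forward-tangent
  # pass with tangent U_i, then reverse through that extended graph (needs
  # the second derivative of the activation).
  if (w$force > 0) {
    sp1 <- lapply(fw$Z, dssp)
    sp2 <- lapply(fw$Z, d2ssp)
    for (i in seq_len(nS)) {
      U <- U_adj[[i]]
      Tl <- vector("list", L); Adot <- vector("list", L)
      tang <- U
      for (l in seq_len(L)) {
        Tl[[l]] <- tang %*% t(params$W[[l]])
        Adot[[l]] <- sp1[[l]] * Tl[[l]]
        tang <- Adot[[l]]
      }
      # seed: sum over records of Edot_i = Adot_L %*% w_Ei
      g$heads$energy$W[i, ] <- g$heads$energy$W[i, ] + colSums(Adot[[L]])
      dAdot <- matrix(params$heads$energy$W[i, ], n, ncol(AL), byrow = TRUE)
      dA2 <- matrix(0, n, ncol(AL))
      for (l in L:1) {
        dT <- sp1[[l]] * dAdot
        dZ <- sp2[[l]] * Tl[[l]] * dAdot + sp1[[l]] * dA2
        Adot_prev <- if (l > 1) Adot[[l - 1]] else U
        A_prev <- if (l > 1) fw$A[[l - 1]] else dat$D
        g$W[[l]] <- g$W[[l]] + crossprod(dT, Adot_prev) + crossprod(dZ, A_prev)
        g$b[[l]] <- g$b[[l]] + colSums(dZ)
        if (l > 1) {
          dAdot <- dT %*% params$W[[l]]
          dA2 <- dZ %*% params$W[[l]]
        }
      }
    }
  }
  list(total = total, parts = loss, grad = g)
}

# ---------------------------------------------------------------------------
# Adam optimizer on the nested parameter structure
# ---------------------------------------------------------------------------

adam_init <- function(params) list(m = zero_like(params), v = zero_like(params), t = 0L)

adam_step <- function(params, grad, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  upd <- function(p, gmat, m, v) {
    m <- beta1 * m + (1 - beta1) * gmat
    v <- beta2 * v + (1 - beta2) * gmat^2
    mh <- m / (1 - beta1^st$t)
    vh <- v / (1 - beta2^st$t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  for (l in seq_along(params$W)) {
    u <- upd(params$W[[l]], grad$W[[l]], st$m$W[[l]], st$v$W[[l]])
    params$W[[l]] <- u$p; st$m$W[[l]] <- u$m; st$v$W[[l]] <- u$v
    u <- upd(params$b[[l]], grad$b[[l]], st$m$b[[l]], st$v$b[[l]])
    params$b[[l]] <- u$p; st$m$b[[l]] <- u$m; st$v$b[[l]] <- u$v
  }
  for (h in names(params$heads)) {
    u <- upd(params$heads[[h]]$W, grad$heads[[h]]$W, st$m$heads[[h]]$W, st$v$heads[[h]]$W)
    params$heads[[h]]$W <- u$p; st$m$heads[[h]]$W <- u$m; st$v$heads[[h]]$W <- u$v
    u <- upd(params$heads[[h]]$b, grad$heads[[h]]$b, st$m$heads[[h]]$b, st$v$heads[[h]]$b)
    params$heads[[h]]$b <- u$p; st$m$heads[[h]]$b <- u$m; st$v$heads[[h]]$b <- u$v
  }
  list(params = params, state = st)
}

# ---------------------------------------------------------------------------
# Training
# ---------------------------------------------------------------------------

#' Train a multi-output NN potential
#'
#' Full-batch Adam on the weighted sum of per-property mean-square losses.
#' The force loss is computed through the analytic derivative of the energy
#' head (never a separate force head), so the trained network's forces are by
#' construction the exact gradient field of its energies. Early stopping
#' keeps the weights with the best validation loss. Deterministic for a fixed
#' seed.
#'
#' @param ts A [training_set()].
#' @param hyperparams Named list overriding the defaults (`hidden`, `lr`,
#'   `epochs`, `eval_every`, `patience`, `weights`); see
#'   `mlphotodyn:::default_hyperparams()`.
#' @param seed RNG seed for initialization and any stochastic choices.
#' @param verbose Print progress.
#' @return An object of class `c("nn_model", "es_provider")` carrying the
#'   weights, normalization statistics, descriptor specification and
#'   per-property training/validation RMSEs (raw units).
#' @export
train_nn <- function(ts, hyperparams = list(), seed = 1, verbose = FALSE) {
  hp <- merge_hyperparams(hyperparams)
  if (length(ts$split$train) == 0 || length(ts$split$val) == 0)
    stop("training and validation splits must be non-empty")
  nD <- length(ts$records[[1]]$x)
  spec <- if (!is.null(ts$header$descriptor) && ts$header$descriptor == "coordinate")
    descriptor_spec("coordinate", nD)
  else if (nD == 1) descriptor_spec("coordinate", 1L)
  else descriptor_spec("inverse_distance", nD)

  m_tr <- build_matrices(ts$records[ts$split$train], spec)
  m_va <- build_matrices(ts$records[ts$split$val], spec)
  norm <- compute_norm(m_tr)
  dat_tr <- standardize_data(m_tr, norm)
  dat_va <- standardize_data(m_va, norm)

  heads_dims <- list(energy = m_tr$nS, nac = m_tr$nP * nD)
  if (!is.null(m_tr$DIP)) heads_dims$dip <- ncol(m_tr$DIP)
  if (!is.null(m_tr$SOC)) heads_dims$soc <- ncol(m_tr$SOC)
  params <- init_params(spec$n_in, hp$hidden, heads_dims, seed)
  st <- adam_init(params)

  best <- list(loss = Inf, params = params, epoch = 0L)
  best_tr <- list(loss = Inf, params = params)
  bad_checks <- 0L
  history <- list()
  for (ep in seq_len(hp$epochs)) {
    lg <- nn_loss_grad(params, dat_tr, hp$weights, norm$g_scale, want_grad = TRUE)
    if (lg$total < best_tr$loss) best_tr <- list(loss = lg$total, params = params)
    lr_ep <- hp$lr * hp$lr_decay^((ep - 1) / max(hp$epochs - 1, 1))
    upd <- adam_step(params, lg$grad, st, lr_ep)
    params <- upd$params; st <- upd$state
    if (ep %% hp$eval_every == 0 || ep == hp$epochs) {
      vl <- nn_loss_grad(params, dat_va, hp$weights, norm$g_scale, want_grad = FALSE)
      history[[length(history) + 1L]] <- c(epoch = ep, train = lg$total, val = vl$total)
      if (vl$total < best$loss - 1e-14) {
        best <- list(loss = vl$total, params = params, epoch = ep)
        bad_checks <- 0L
      } else {
        bad_checks <- bad_checks + 1L
        if (isTRUE(hp$early_stopping) && bad_checks >= hp$patience) break
      }
      if (verbose)
        message(sprintf("epoch %d: train %.3e val %.3e", ep, lg$total, vl$total))
    }
  }
  # early stopping keeps the best-validation weights; without it the
  # best-training weights are kept (late-epoch Adam iterates oscillate)
  params <- if (isTRUE(hp$early_stopping)) best$params else best_tr$params

  model <- structure(list(
    params = params, norm = norm, spec = spec,
    n_states = m_tr$nS, n_dof = nD, n_pairs = m_tr$nP,
    n_comp = m_tr$n_comp, dip_pairs = m_tr$dip_pairs,
    has_dip = !is.null(m_tr$DIP), has_soc = !is.null(m_tr$SOC),
    masses = ts$header$masses_au,
    hyperparams = hp, seed = seed,
    history = do.call(rbind, history), best_epoch = best$epoch
  ), class = c("nn_model", "es_provider"))
  model$train_rmse <- property_rmse(model, ts$records[ts$split$train])
  model$val_rmse <- property_rmse(model, ts$records[ts$split$val])
  model
}

# Raw-unit per-property RMSE of a model over a list of records.
property_rmse <- function(model, records) {
  se <- list(energy = 0, force = 0, nac = 0, dipole = 0, soc = 0)
  ct <- list(energy = 0, force = 0, nac = 0, dipole = 0, soc = 0)
  for (rec in records) {
    p <- eval_properties(model, rec$x)
    se$energy <- se$energy + sum((p$energies - rec$props$energies)^2)
    ct$energy <- ct$energy + length(p$energies)
    se$force <- se$force + sum((p$gradients - rec$props$gradients)^2)
    ct$force <- ct$force + length(p$gradients)
    se$nac <- se$nac + sum((p$nacs - rec$props$nacs)^2)
    ct$nac <- ct$nac + length(p$nacs)
    if (model$has_dip && !is.null(rec$props$dipoles)) {
      se$dipole <- se$dipole + sum((p$dipoles - rec$props$dipoles)^2)
      ct$dipole <- ct$dipole + length(p$dipoles)
    }
    if (model$has_soc && !is.null(rec$props$socs)) {
      se$soc <- se$soc + sum((p$socs - rec$props$socs)^2)
      ct$soc <- ct$soc + length(p$socs)
    }
  }
  out <- c(energy = sqrt(se$energy / max(ct$energy, 1)),
           force = sqrt(se$force / max(ct$force, 1)),
           nac = sqrt(se$nac / max(ct$nac, 1)))
  if (ct$dipole > 0) out <- c(out, dipole = sqrt(se$dipole / ct$dipole))
  if (ct$soc > 0) out <- c(out, soc = sqrt(se$soc / ct$soc))
  out
}

#' @export
print.nn_model <- function(x, ...) {
  cat(sprintf("<nn_model> %d states, %d dof, trunk %s, best epoch %d\n",
              x$n_states, x$n_dof,
              paste(x$hyperparams$hidden, collapse = "x"), x$best_epoch))
  cat("  validation RMSE:",
      paste(sprintf("%s %.2e", names(x$val_rmse), x$val_rmse), collapse = ", "),
      "\n")
  invisible(x)
}

#' @rdname eval_properties
#' @export
eval_properties.nn_model <- function(provider, x, ...) {
  if (inherits(x, "geometry")) x <- flatten_coords(x)
  ds <- compute_descriptor(provider$spec, x)
  norm <- provider$norm
  Dh <- matrix((ds$values - norm$x_mu) / norm$x_sd, 1)
  fw <- nn_forward_trunk(provider$params, Dh)
  AL <- fw$A[[length(provider$params$W)]]
  E <- as.numeric(head_out(provider$params$heads$energy, AL)) * norm$e_sd + norm$e_mu
  nS <- provider$n_states; nD <- provider$n_dof
  # forces: chain through descriptor Jacobian (exact gradient of E_pred)
  Jt <- sweep(ds$jacobian, 1, norm$x_sd, "/") * norm$e_sd   # n_in x n_dof
  G <- matrix(0, nS, nD)
  for (i in seq_len(nS)) {
    Ghat <- grad_std_energy(provider$params, fw$Z, i)       # 1 x n_in
    G[i, ] <- as.numeric(Ghat %*% Jt)
  }
  nacs <- matrix(as.numeric(head_out(provider$params$heads$nac, AL)) * norm$nac_scale,
                 provider$n_pairs, nD, byrow = TRUE)
  dip <- NULL
  if (provider$has_dip) {
    yv <- as.numeric(head_out(provider$params$heads$dip, AL)) * norm$dip_scale + norm$dip_mu
    dip <- array(0, c(nS, nS, provider$n_comp))
    k <- 0L
    for (q in seq_len(nrow(provider$dip_pairs))) {
      i <- provider$dip_pairs[q, 1]; j <- provider$dip_pairs[q, 2]
      for (cc in seq_len(provider$n_comp)) {
        k <- k + 1L
        dip[i, j, cc] <- yv[k]
        dip[j, i, cc] <- yv[k]
      }
    }
  }
  soc <- NULL
  if (provider$has_soc) {
    sv <- as.numeric(head_out(provider$params$heads$soc, AL)) * norm$soc_scale
    soc <- matrix(0, nS, nS)
    pr <- state_pairs(nS)
    soc[pr] <- sv
    soc[pr[, c(2, 1), drop = FALSE]] <- sv
  }
  elecprops(E, G, nacs, dipoles = dip, socs = soc, eigvecs = NULL)
}

#' Analytic forces of an NN model
#'
#' Per-state energy gradients obtained by the chain rule through the
#' descriptor Jacobian, \eqn{G_i = (\partial E_i / \partial D)(\partial D /
#' \partial R)}: the exact gradient of the predicted energy, hence a
#' conservative force field.
#'
#' @param model A trained [train_nn()] model.
#' @param x Flat coordinates (Bohr) or a `geometry`.
#' @return n_states x n_dof matrix of gradients (Hartree/Bohr); forces are
#'   the negative of these.
#' @export
analytic_forces <- function(model, x) {
  eval_properties(model, x)$gradients
}

#' Random grid search over hyperparameters
#'
#' Samples hyperparameter combinations uniformly from a declared grid, trains
#' each candidate on the training split and ranks them by validation RMSE
#' (energy first, force as tie-breaker).
#'
#' @param ts A [training_set()].
#' @param search_space Named list; each element is a list (or vector) of
#'   candidate values for one hyperparameter (e.g. `hidden`, `lr`).
#' @param n_trials Number of random draws (>= 1).
#' @param seed Seed controlling both the draw sequence and per-trial training
#'   seeds.
#' @return List with `best_hyperparams`, `best_model` and a `trials`
#'   data frame logging every candidate and its validation RMSEs.
#' @export
random_grid_search <- function(ts, search_space, n_trials, seed = 1) {
  if (length(search_space) == 0 || any(lengths(search_space) == 0))
    stop("empty hyperparameter search space")
  if (n_trials < 1) stop("n_trials must be >= 1")
  picks <- local_seed(seed, {
    lapply(seq_len(n_trials), function(i)
      lapply(search_space, function(vals) {
        vals <- as.list(vals)
        vals[[sample.int(length(vals), 1)]]
      }))
  })
  rows <- list(); models <- list()
  for (tr in seq_len(n_trials)) {
    hp <- picks[[tr]]
    model <- train_nn(ts, hyperparams = hp, seed = seed + tr)
    models[[tr]] <- model
    rows[[tr]] <- data.frame(
      trial = tr,
      params = paste(vapply(names(hp), function(nm)
        paste0(nm, "=", paste(unlist(hp[[nm]]), collapse = "x")), character(1)),
        collapse = ", "),
      val_energy_rmse = model$val_rmse[["energy"]],
      val_force_rmse = model$val_rmse[["force"]],
      val_nac_rmse = model$val_rmse[["nac"]],
      stringsAsFactors = FALSE)
  }
  trials <- do.call(rbind, rows)
  ord <- order(trials$val_energy_rmse, trials$val_force_rmse)
  best <- ord[1]
  list(best_hyperparams = picks[[best]], best_model = models[[best]],
       trials = trials[ord, ])
}
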