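# Run configuration: YAML files with strict (unknown keys rejected)
# validation against the package defaults, and a resolved copy stored next
# to every output so any stage can be re-run bit-reproducibly.

#' Default run configuration
#'
#' Every tunable of the pipeline with its default value. User config files
#' override these; unknown keys are rejected.
#'
#' @return Nested named list with sections `provider`, `training`,
#'   `sampling`, `dynamics`, `optimization` and a global `seed`.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    provider = list(
      model = "three_state",        # avoided_crossing | three_state | conical_triatomic
      randomize_phase = FALSE,
      phase_seed = 1L
    ),
    training = list(
      hidden = c(50L, 50L),
      lr = 5e-3,
      epochs = 3000L,
      eval_every = 10L,
      patience = 40L,
      weights = list(energy = 1, force = 1, nac = 0.1, dipole = 0.1, soc = 0.1),
      validation_fraction = 0.1,
      n_members = 2L
    ),
    sampling = list(
      amplitudes = c(-3, -2, -1, 0, 1, 2, 3),
      safety_factor = 3,
      decay = 0.95,
      freeze_time_fs = 1e4,
      max_new_points = 50L,
      n_traj = 1L
    ),
    dynamics = list(
      dt_fs = 0.5,
      t_max_fs = 100,
      n_substeps = 20L,
      n_traj = 200L,
      initial_state = 3L,
      decoherence = NULL
    ),
    optimization = list(
      sigma0 = 3.5,
      alpha = 0.02,
      growth = 1.5,
      gap_tol = 1e-3,
      tol = 1e-4
    ),
    phase = list(
      decision_threshold = 0.5,
      max_bisections = 10L
    )
  )
}

merge_validate <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    here <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(defaults))
      stop("unknown configuration key: ", here)
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      if (!is.list(user[[nm]]))
        stop("configuration key ", here, " must be a section")
      defaults[[nm]] <- merge_validate(defaults[[nm]], user[[nm]], here)
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Load and validate a YAML run configuration
#'
#' @param path YAML file path; NULL returns the defaults.
#' @return Fully resolved configuration list (defaults overridden by the
#'   file). Unknown keys raise an error.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- merge_validate(cfg, user)
  }
  cfg
}

#' Write the resolved configuration next to an output
#'
#' @param cfg Configuration list.
#' @param dir Output directory (created if needed).
#' @return Path of the written YAML, invisibly.
#' @export
save_config <- function(cfg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- file.path(dir, "config.resolved.yaml")
  yaml::write_yaml(cfg, p)
  invisible(p)
}

# Instantiate the bundled model named in the config.
config_provider <- function(cfg) {
  pc <- cfg$provider
  switch(pc$model,
    avoided_crossing = model_avoided_crossing(randomize_phase = pc$randomize_phase,
                                              phase_seed = pc$phase_seed),
    three_state = model_three_state(randomize_phase = pc$randomize_phase,
                                    phase_seed = pc$phase_seed),
    conical_triatomic = model_conical_triatomic(randomize_phase = pc$randomize_phase,
                                                phase_seed = pc$phase_seed),
    stop("unknown model: ", pc$model))
}
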