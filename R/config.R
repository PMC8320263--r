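## Run configuration: a nested list with full defaults, YAML/JSON
## (de)serialization, and schema validation.  Every numeric choice that
## defines the exams lives here; nothing is hard-coded in the exam
## drivers.

#' Default run configuration
#'
#' Returns the complete configuration of the simulated examination: arm
#' geometry and dynamics, model precisions and smoothness, the discrete
#' task, lesion, exam protocol and numerics blocks.  All exported exam
#' functions consume this structure; [load_config()] merges a user
#' document over these defaults.
#'
#' @return a named nested list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    geometry = list(
      shoulder_pos = c(0, 0, 1.5),
      upper_len = 0.3,
      fore_len = 0.3),
    dynamics = list(
      kappa = 60,          # force-to-acceleration gain (1 / (kg m^2))
      damping = 0.12,      # beta (1/s), enters as kappa * beta
      action_gain = 1.5e-3,
      action_decay = 3),   # motor activation leak (1/s)
    precisions = list(
      sensory_logprec = list(proprio_pos = 3, proprio_vel = 2,
                             visual_pos = 2, visual_colour = 3),
      process_logprec = 4,
      cause_logprec = list(attractor = 5, colour = 2),
      lam_model = 0.1,     # assumed smoothness of fluctuations (s)
      lam_world = 0.1),    # true smoothness of the plant noise (s)
    noise = list(
      sensory_sd = 1e-3,
      process_sd = 1e-3),
    orders = list(states = 4, causes = 3),
    task = list(
      vertices = rbind(right = c(0.32, -0.18, 1.30),
                       apex = c(0.32, 0, 1.58),
                       lower_left = c(0.32, 0.18, 1.30)),
      preference = 0.6,    # nats on the "correct" outcome
      gamma = 2,
      a_conc = 0.9,
      a_temperature = 1,
      e_match = 0.8,
      e_static = 0.7,      # effort prior on not moving
      b2_stay = 0.7,
      t1 = 5, t2 = 4,
      epoch_duration = 1.25),
    lesion = list(name = "none", magnitude = NA_real_,
                  scope = "proprio_vel"),
    exam = list(
      tap = list(amplitude = 2, width = 0.025, onset = 1,
                 baseline = 1, post = 3),
      rest_angles = c(0, 0.5, 1.2),
      schedule = c("right", "apex", "lower_left", "apex"),
      reach_epsilon_frac = 0.05),  # "reached" = 5% of arm length
    numerics = list(dt = 1 / 128, divergence_bound = 1e3),
    seed = 1,
    output_dir = "."
  ), class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(sprintf("  lesion: %s\n", x$lesion$name))
  cat(sprintf("  dt = %g s, seed = %s\n", x$numerics$dt,
              format(x$seed)))
  cat(sprintf("  schedule: %s\n", paste(x$exam$schedule, collapse = " -> ")))
  invisible(x)
}

## recursively merge user values over defaults, rejecting unknown keys
merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(defaults) || !is.list(user) || is.null(names(defaults)))
    return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop_invalid("unknown config field(s): ",
                 paste0(path, unknown, collapse = ", "))
  for (nm in names(user))
    defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                   paste0(path, nm, "."))
  defaults
}

validate_config <- function(cfg) {
  check_scalar(cfg$dynamics$kappa, "dynamics.kappa", lower = 0,
               strict_lower = TRUE)
  check_scalar(cfg$dynamics$damping, "dynamics.damping", lower = 0)
  check_scalar(cfg$precisions$lam_model, "precisions.lam_model", lower = 0,
               strict_lower = TRUE)
  check_scalar(cfg$precisions$lam_world, "precisions.lam_world", lower = 0,
               strict_lower = TRUE)
  check_scalar(cfg$task$gamma, "task.gamma", lower = 0)
  check_scalar(cfg$task$a_temperature, "task.a_temperature", lower = 0,
               upper = 1, strict_lower = TRUE)
  check_scalar(cfg$numerics$dt, "numerics.dt", lower = 0,
               strict_lower = TRUE)
  check_count(cfg$orders$states, "orders.states")
  check_count(cfg$orders$causes, "orders.causes")
  if (!cfg$lesion$name %in% lesion_names)
    stop_invalid("lesion.name must be one of: ",
                 paste(lesion_names, collapse = ", "))
  if (!is.matrix(cfg$task$vertices))
    cfg$task$vertices <- matrix(unlist(cfg$task$vertices), 3, 3,
                                byrow = TRUE)
  bad <- setdiff(cfg$exam$schedule, c("right", "apex", "lower_left"))
  if (length(bad))
    stop_invalid("exam.schedule entries must name triangle vertices; got: ",
                 paste(bad, collapse = ", "))
  cfg
}

#' Load a configuration document
#'
#' Reads a YAML (or JSON) configuration, merges it over
#' [default_config()] and validates it.  Unknown keys are rejected with
#' an error naming the offending field; an empty document yields the
#' full defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` document.
#' @return a validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_invalid("config file not found: ", path)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- merge_config(unclass(default_config()), user)
  cfg <- validate_config(cfg)
  structure(cfg, class = "run_config")
}

#' Save a configuration document
#'
#' Writes the configuration as YAML; [load_config()] restores it
#' losslessly.
#'
#' @param config a `run_config`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$task$vertices <- lapply(seq_len(nrow(cfg$task$vertices)),
                              function(i) as.numeric(cfg$task$vertices[i, ]))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

## instantiate model objects from a config ----------------------------------

config_geometry <- function(cfg) {
  arm_geometry(cfg$geometry$shoulder_pos, cfg$geometry$upper_len,
               cfg$geometry$fore_len)
}

config_params <- function(cfg) {
  arm_dynamics_params(
    kappa = cfg$dynamics$kappa, damping = cfg$dynamics$damping,
    sensory_logprec = cfg$precisions$sensory_logprec,
    process_logprec = cfg$precisions$process_logprec,
    cause_logprec = cfg$precisions$cause_logprec,
    lam_model = cfg$precisions$lam_model,
    lam_world = cfg$precisions$lam_world,
    sensory_noise_sd = cfg$noise$sensory_sd,
    process_noise_sd = cfg$noise$process_sd)
}

config_cmodel <- function(cfg) {
  continuous_model(config_geometry(cfg), config_params(cfg),
                   n_x = cfg$orders$states, n_v = cfg$orders$causes,
                   action_gain = cfg$dynamics$action_gain,
                   action_decay = cfg$dynamics$action_decay,
                   divergence_bound = cfg$numerics$divergence_bound)
}

config_task <- function(cfg) {
  build_task_models(cfg$task$vertices, preference = cfg$task$preference,
                    gamma = cfg$task$gamma, a_conc = cfg$task$a_conc,
                    a_temperature = cfg$task$a_temperature,
                    e_match = cfg$task$e_match, e_static = cfg$task$e_static,
                    b2_stay = cfg$task$b2_stay,
                    T1 = cfg$task$t1, T2 = cfg$task$t2)
}
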