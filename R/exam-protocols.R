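## The two clinical exams as orchestrated experiments.

#' Simulated biceps tendon-tap examination
#'
#' Runs the continuous perception--action loop alone (no discrete
#' levels): one second of quiet posture with the descending prior held
#' at the resting hand position, a brief Gaussian pulse injected on the
#' elbow Ia (velocity) afferent as if the tendon had been stretched,
#' and three further seconds of observation.
#'
#' @param config a [default_config()]-style configuration.
#' @param lesion a [lesion_spec()] (default: none).
#' @return an object of class `exam_result` with the condition label,
#'   the trajectory table (one row per step: time, joint angles and
#'   velocities, hand position, the 12 sensory channels, 3 action
#'   channels, segment id), [compute_reflex_metrics()] output, and
#'   provenance (seed, config digest).
#' @export
tendon_tap_exam <- function(config = default_config(),
                            lesion = lesion_spec("none")) {
  lesioned <- apply_lesion(config, lesion)
  geom <- config_geometry(lesioned)
  p_model <- config_params(lesioned)
  p_world <- config_params(config)      # the plant is never lesioned
  m <- continuous_model(geom, p_model, n_x = lesioned$orders$states,
                        n_v = lesioned$orders$causes,
                        action_gain = lesioned$dynamics$action_gain,
                        action_decay = lesioned$dynamics$action_decay,
                        divergence_bound = lesioned$numerics$divergence_bound)
  dt <- lesioned$numerics$dt
  tap <- lesioned$exam$tap
  duration <- tap$baseline + tap$post
  n <- round(duration / dt)
  x0 <- c(lesioned$exam$rest_angles, 0, 0, 0)
  hand0 <- forward_kinematics(geom, x0[1:3])
  nv <- m$n_v
  ## tap onset is measured from the start of the baseline period
  onset <- tap$onset
  pulse <- function(t) {
    M <- matrix(0, 12, nv)
    M[6, ] <- embed_pulse(tap$amplitude, onset, tap$width, t, nv)
    M
  }
  plant <- make_arm_plant(geom, p_world, x0, n, dt, seed = config$seed,
                          perturb_fun = pulse, n_orders = nv)
  belief <- generalized_belief(m, x0 = x0, v0 = c(hand0, 0, 0, 0))
  prior <- cause_prior(m, c(hand0, 0, 0, 0))
  ep <- tryCatch(
    run_epoch(m, belief, prior, plant, duration, dt),
    error = function(e) stop_invalid(
      sprintf("tendon_tap_exam (lesion %s): %s", lesion$name,
              conditionMessage(e))))
  traj <- epoch_to_trajectory(ep, segment = 1L)
  metrics <- compute_reflex_metrics(traj, tap_onset = onset)
  exam_result("tendon_tap", lesion, traj, metrics, config)
}

#' Simulated three-target coordination examination
#'
#' Runs the full three-level model.  Each segment of the target
#' schedule is one level-2 step; within a segment the level-1 model
#' runs `t1` epochs, each driving the continuous loop for
#' `epoch_duration` seconds with a Bayesian-model-average prior over
#' the ring of attracting points.  Evidence accumulated by Bayesian
#' model reduction updates the level-1 beliefs after every epoch, and
#' the level-2 posterior is updated at every segment boundary.
#'
#' @inheritParams tendon_tap_exam
#' @param reference optional healthy `exam_result` at the same seed and
#'   schedule, used for the `post_switch_deviation` metric.
#' @return an `exam_result`; `metrics` is the per-segment data frame of
#'   [compute_reach_metrics()], and `extras` records the per-epoch
#'   attractor expectations and policy posteriors.
#' @export
coordination_exam <- function(config = default_config(),
                              lesion = lesion_spec("none"),
                              reference = NULL) {
  lesioned <- apply_lesion(config, lesion)
  geom <- config_geometry(lesioned)
  p_model <- config_params(lesioned)
  p_world <- config_params(config)
  m <- continuous_model(geom, p_model, n_x = lesioned$orders$states,
                        n_v = lesioned$orders$causes,
                        action_gain = lesioned$dynamics$action_gain,
                        action_decay = lesioned$dynamics$action_decay,
                        divergence_bound = lesioned$numerics$divergence_bound)
  task <- config_task(lesioned)
  dt <- lesioned$numerics$dt
  t1 <- task$level1$T
  epoch_dur <- lesioned$task$epoch_duration
  sched_names <- lesioned$exam$schedule
  vtx_index <- c(right = 1L, apex = 2L, lower_left = 3L)
  schedule <- vtx_index[sched_names]
  n_seg <- length(schedule)
  seg_dur <- t1 * epoch_dur
  n_total <- round(n_seg * seg_dur / dt)

  ## the world: arm starts at the right vertex; targets darken per the
  ## schedule
  start_vtx <- task$ring[task$vertex_ring[1L], ]
  q0 <- inverse_kinematics(geom, start_vtx,
                           init = lesioned$exam$rest_angles)
  x0 <- c(q0, 0, 0, 0)
  colours_fun <- function(t) {
    seg <- min(n_seg, 1L + floor(t / seg_dur))
    task$colours[schedule[seg], ]
  }
  plant <- make_arm_plant(geom, p_world, x0, n_total, dt,
                          seed = config$seed, colours_fun = colours_fun,
                          n_orders = m$n_v)
  belief <- generalized_belief(m, x0 = x0, v0 = c(start_vtx, 0, 0, 0))
  a <- NULL

  ## level-2 beliefs start from D^(2)
  traj2 <- task$level2$D$trajectory
  targ2 <- task$level2$D$target

  ring_eta <- function(l, col) c(task$ring[l, ], col)
  traj_parts <- vector("list", n_seg * t1)
  attractor_log <- matrix(0, n_seg * t1, 3)
  pi_log <- matrix(0, n_seg * t1, 3)
  seg_rows <- integer(0)

  for (seg in seq_len(n_seg)) {
    ctx <- descending_context(task, traj2, targ2)
    D1 <- ctx$D1
    obs_loc <- NULL; obs_col <- NULL
    ## initial policy posterior from the descending context alone
    sp0 <- lapply(1:3, function(p)
      state_posterior(task, p, D1, obs_loc, obs_col))
    Fv <- vapply(sp0, `[[`, numeric(1), "F")
    Gv <- vapply(1:3, function(p)
      expected_free_energy(task, p, D1$location, D1$target,
                           current_step = 0L), numeric(1))
    pi1 <- policy_posterior(ctx$E_eff, Fv, Gv, task$level1$gamma)

    for (tau in seq_len(t1)) {
      ## predicted location at this epoch: BMA over policies
      o_loc <- rep(0, 6)
      for (p in 1:3) o_loc <- o_loc + pi1[p] * sp0[[p]]$loc_post[tau, ]
      o_loc <- normalize(o_loc)
      targ_pred <- rep(0, 3)
      for (p in 1:3) targ_pred <- targ_pred + pi1[p] * sp0[[p]]$targ_post
      targ_pred <- normalize(targ_pred)
      col_bma <- as.numeric(crossprod(task$colours, targ_pred))
      att_bma <- as.numeric(crossprod(task$ring, o_loc))
      prior <- cause_prior(m, c(att_bma, col_bma))
      cand <- c(lapply(1:6, function(l) ring_eta(l, col_bma)),
                lapply(1:3, function(k) c(att_bma, task$colours[k, ])))
      ep <- tryCatch(
        run_epoch(m, belief, prior, plant, epoch_dur, dt,
                  candidates = cand, a0 = a),
        error = function(e) stop_invalid(
          sprintf("coordination_exam (lesion %s, segment %d, epoch %d): %s",
                  lesion$name, seg, tau, conditionMessage(e))))
      belief <- ep$belief
      a <- ep$a_final
      idx <- (seg - 1L) * t1 + tau
      traj_parts[[idx]] <- epoch_to_trajectory(ep, segment = seg)
      attractor_log[idx, ] <- att_bma
      pi_log[idx, ] <- pi1

      ## outcome posteriors from accumulated evidence
      r_loc <- outcome_posterior(o_loc, ep$L[1:6])
      r_col <- outcome_posterior(targ_pred, ep$L[7:9])
      obs_loc <- rbind(obs_loc, r_loc)
      obs_col <- rbind(obs_col, r_col)
      ## re-infer states and policies with the new evidence
      sp0 <- lapply(1:3, function(p)
        state_posterior(task, p, D1, obs_loc, obs_col))
      Fv <- vapply(sp0, `[[`, numeric(1), "F")
      loc_now <- rep(0, 6); targ_now <- rep(0, 3)
      for (p in 1:3) {
        loc_now <- loc_now + pi1[p] * sp0[[p]]$loc_post[tau, ]
        targ_now <- targ_now + pi1[p] * sp0[[p]]$targ_post
      }
      Gv <- vapply(1:3, function(p)
        expected_free_energy(task, p, normalize(loc_now),
                             normalize(targ_now),
                             current_step = tau), numeric(1))
      pi1 <- policy_posterior(ctx$E_eff, Fv, Gv, task$level1$gamma)
    }

    ## ascending message at the segment boundary
    s1_loc <- rep(0, 6); s_targ <- rep(0, 3)
    for (p in 1:3) {
      s1_loc <- s1_loc + pi1[p] * sp0[[p]]$init_post
      s_targ <- s_targ + pi1[p] * sp0[[p]]$targ_post
    }
    up <- ascending_update(task, traj2, pi1, normalize(s1_loc),
                           targ2, normalize(s_targ))
    ## predictive priors for the next segment
    traj2 <- as.numeric(task$level2$B$trajectory %*% up$traj)
    targ2 <- as.numeric(task$level2$B$target %*% up$target)
  }

  traj <- do.call(rbind, traj_parts)
  targets <- task$ring[task$vertex_ring[schedule], , drop = FALSE]
  eps <- lesioned$exam$reach_epsilon_frac *
    (lesioned$geometry$upper_len + lesioned$geometry$fore_len)
  ref_traj <- if (!is.null(reference)) reference$trajectory else NULL
  metrics <- compute_reach_metrics(traj, targets, epsilon = eps,
                                   reference = ref_traj)
  res <- exam_result("coordination", lesion, traj, metrics, config)
  res$extras <- list(attractors = attractor_log, pi = pi_log,
                     targets = targets, epsilon = eps)
  res
}

## convert an epoch_result into the tidy trajectory table
epoch_to_trajectory <- function(ep, segment) {
  n <- nrow(ep$states)
  df <- data.frame(
    time = ep$time,
    shoulder_rotation = ep$states[, 1], shoulder_flexion = ep$states[, 2],
    elbow_angle = ep$states[, 3],
    shoulder_rotation_velocity = ep$states[, 4],
    shoulder_flexion_velocity = ep$states[, 5],
    elbow_velocity = ep$states[, 6],
    hand_x = ep$hand[, 1], hand_y = ep$hand[, 2], hand_z = ep$hand[, 3])
  ycols <- paste0("y", sprintf("%02d", 1:12))
  for (j in 1:12) df[[ycols[j]]] <- ep$y[, j]
  for (j in 1:3) df[[paste0("a", j)]] <- ep$a[, j]
  df$free_energy <- ep$F
  df$segment <- segment
  df
}

## exam result container ------------------------------------------------------

exam_result <- function(exam, lesion, trajectory, metrics, config) {
  structure(list(exam = exam, condition = lesion$name, lesion = lesion,
                 trajectory = trajectory, metrics = metrics,
                 provenance = list(seed = config$seed,
                                   config_hash = config_digest(config),
                                   timestamp = format(Sys.time()))),
            class = "exam_result")
}

## cheap structural digest (no external dependencies)
config_digest <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "")
  sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 1e9
}

#' @export
print.exam_result <- function(x, ...) {
  cat(sprintf("<exam_result> %s exam, condition '%s', %d samples\n",
              x$exam, x$condition, nrow(x$trajectory)))
  if (inherits(x$metrics, "reflex_metrics")) print(x$metrics)
  else if (is.data.frame(x$metrics)) print(x$metrics, digits = 3)
  invisible(x)
}

#' Write an exam result to disk
#'
#' Writes the trajectory as CSV and the metrics plus provenance as a
#' JSON sidecar; the lesion name is embedded in both filenames.
#'
#' @param result an `exam_result`.
#' @param dir output directory (created if needed).
#' @return named character vector of the two paths, invisibly.
#' @export
write_exam_result <- function(result, dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- sprintf("%s_%s", result$exam, result$condition)
  traj_path <- file.path(dir, paste0(stem, "_trajectory.csv"))
  meta_path <- file.path(dir, paste0(stem, "_metrics.json"))
  utils::write.csv(result$trajectory, traj_path, row.names = FALSE)
  meta <- list(exam = result$exam, condition = result$condition,
               lesion = unclass(result$lesion),
               metrics = if (is.data.frame(result$metrics))
                 result$metrics else unclass(result$metrics),
               provenance = result$provenance)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(trajectory = traj_path, metrics = meta_path))
}
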