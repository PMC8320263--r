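## Stateful "real world" plant handle: wraps plant_step with smooth
## noise streams, the experimenter's colour schedule and any exogenous
## perturbation (the tendon tap), and serves generalized sensory frames
## to the filter.

#' Create a plant handle for closed-loop simulation
#'
#' The handle owns the true joint state and the noise realizations for a
#' whole run; [run_epoch()] draws one generalized sensory frame per step
#' and pushes actions back.  Noise is generated up front from `seed`
#' (smooth fluctuations at the world smoothness `p$lam_world`), so a
#' given seed yields a bit-identical trajectory.
#'
#' @param geom an [arm_geometry()].
#' @param p an [arm_dynamics_params()].
#' @param x0 initial 6-vector joint state.
#' @param n_steps total number of steps the handle will serve.
#' @param dt integration step (s).
#' @param seed integer seed for the noise streams.
#' @param colours_fun function(t) returning the 3-vector of true target
#'   colour intensities at time t.
#' @param perturb_fun optional function(t) returning a 12 x `n_orders`
#'   matrix added to the generalized sensory frame (e.g. the tendon
#'   tap).
#' @param n_orders number of derivative orders served per frame.
#' @param t0 time of the first step (s).
#' @return an environment with fields `state`, `last_y`, `time0` and
#'   methods `observe(a)` / `advance(a)`.
#' @export
make_arm_plant <- function(geom, p, x0, n_steps, dt, seed,
                           colours_fun = function(t) c(0, 0, 0),
                           perturb_fun = NULL, n_orders = 3, t0 = 0) {
  x0 <- check_numeric_vec(x0, "x0", 6)
  n_steps <- check_count(n_steps, "n_steps")
  pn <- smooth_noise(n_steps, dt, p$lam_world, 3L, p$process_noise_sd,
                     seed = seed)
  sn <- smooth_noise(n_steps, dt, p$lam_world, 12L, p$sensory_noise_sd,
                     seed = seed + 1L)
  env <- new.env(parent = emptyenv())
  env$state <- x0
  env$i <- 1L
  env$time0 <- t0
  env$dt <- dt
  env$last_y <- rep(NA_real_, 12)

  env$observe <- function(a) {
    i <- env$i
    if (i > n_steps) stop_invalid("plant handle exhausted its noise stream")
    t <- t0 + (i - 1L) * dt
    vw <- c(0, 0, 0, colours_fun(t))
    y0 <- sensory_map(env$state, vw, geom) + sn$value[, i]
    y1 <- plant_sensory_derivative(env$state, a, p, geom,
                                   w = pn$value[, i]) + sn$deriv[, i]
    y <- cbind(y0, y1)
    if (n_orders > 2L) {
      ## second derivative: acceleration is known analytically; jerk and
      ## the curvature of the visual map are unmodelled and served as 0
      acc <- p$kappa * (a - p$damping * env$state[4:6]) + pn$value[, i]
      y2 <- c(acc, rep(0, 3),
              as.numeric(kinematics_jacobian(geom, env$state[1:3]) %*% acc),
              rep(0, 3))
      y <- cbind(y, y2, matrix(0, 12, n_orders - 3L))
    }
    if (!is.null(perturb_fun)) y <- y + perturb_fun(t)
    env$last_y <- y[, 1]
    y
  }

  env$advance <- function(a) {
    i <- env$i
    t <- t0 + (i - 1L) * dt
    out <- plant_step(env$state, a, p, geom, dt,
                      v_world = c(0, 0, 0, colours_fun(t)),
                      noise = list(w = pn$value[, i], sy = sn$value[, i]))
    env$state <- out$state
    env$i <- i + 1L
    invisible(env)
  }
  env
}
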