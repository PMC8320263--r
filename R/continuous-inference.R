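## Generalized (variational) filtering and the reflex-arc action update.
##
## Beliefs follow a gradient flow on free energy in a frame of reference
## that moves with the generalized motion, mu' = D mu - dF/dmu, and are
## integrated by local linearization: the update over one step is
## (expm(J dt) - I) J^{-1} mu' with J = D - d2F/dmu2 (Gauss-Newton
## curvature), computed in an inversion-free augmented form.  Action
## descends the same free energy through the plant's sensory Jacobian,
## restricted to proprioceptive channels (the spinal reflex arc).

#' One step of generalized filtering
#'
#' @param belief a [generalized_belief()].
#' @param y_gen 12 x n_v matrix of generalized sensory data.
#' @param prior a [cause_prior()].
#' @param model a [continuous_model()].
#' @param dt integration step (s).
#' @return the updated belief, with the step's free energy appended to
#'   `free_energy_trace`.
#' @export
filtering_step <- function(belief, y_gen, prior, model, dt) {
  check_scalar(dt, "dt", lower = 0, strict_lower = TRUE)
  err <- prediction_errors(belief, y_gen, prior, model)
  belief_update(belief, err, model, dt)
}

## shared core: apply the local-linearization update given errors
belief_update <- function(belief, err, model, dt, curv = NULL) {
  g <- free_energy_gradient(err)
  Hs <- if (is.null(curv)) free_energy_curvature(err) else curv
  mu <- c(vec_cm(belief$mu_x), vec_cm(belief$mu_v))
  fdot <- as.numeric(model$D %*% mu) - g
  Jm <- model$D - Hs
  mu_new <- mu + ll_update(fdot, Jm, dt)
  if (!all(is.finite(mu_new)) ||
      max(abs(mu_new)) > model$divergence_bound)
    stop_invalid(
      "numerical instability in filtering_step: belief norm exceeded ",
      model$divergence_bound,
      " (consider smaller dt or weaker precisions)")
  nx6 <- 6L * model$n_x
  belief$mu_x <- unvec_cm(mu_new[1:nx6], 6L, model$n_x)
  belief$mu_v <- unvec_cm(mu_new[(nx6 + 1L):model$nmu], 6L, model$n_v)
  belief$free_energy_trace <- c(belief$free_energy_trace, free_energy(err))
  belief
}

#' Reflex-arc sensory Jacobian
#'
#' Default plant Jacobian \eqn{\partial\tilde y/\partial a}: torque at
#' joint i drives the order-0 Ia (velocity) and II (length) channels of
#' that joint with gain \eqn{\kappa}, reflecting the phasic and tonic
#' components of the stretch reflex over one loop delay.  Visual
#' channels carry no action gain, so only proprioceptive prediction
#' errors drive the reflex.
#'
#' @param model a [continuous_model()].
#' @return (12 n_v) x 3 matrix.
#' @export
reflex_jacobian <- function(model) {
  dyda <- matrix(0, 12L * model$n_v, 3L)
  for (i in 1:3) {
    dyda[model$iy(i, 0L), i] <- model$p$kappa        # II (tonic)
    dyda[model$iy(3L + i, 0L), i] <- model$p$kappa   # Ia (phasic)
  }
  dyda
}

#' One step of the action (reflex-arc) update
#'
#' \eqn{a \leftarrow a - \mathrm{d}t\, k_a (\partial\tilde y/\partial
#' a)^\top \tilde\Pi_y \varepsilon_y}: action descends free energy
#' through the precision-weighted proprioceptive prediction errors.
#'
#' @param a 3-vector of joint torques.
#' @param errors output of [prediction_errors()].
#' @param model a [continuous_model()].
#' @param dt integration step (s).
#' @param dyda optional plant sensory Jacobian; defaults to
#'   [reflex_jacobian()].
#' @return updated 3-vector action.
#' @export
action_step <- function(a, errors, model, dt, dyda = NULL) {
  a <- check_numeric_vec(a, "a", 3)
  if (is.null(dyda)) dyda <- reflex_jacobian(model)
  wy <- errors$L_y %*% errors$e_y
  as.numeric(a - dt * (model$action_gain * crossprod(dyda, wy) +
                       model$action_decay * a))
}

#' Run one closed-loop epoch of perception and action
#'
#' Integrates the full perception--action loop against a plant for
#' `duration` seconds: at each step the filter assimilates the plant's
#' generalized sensory frame under the descending cause prior, action is
#' updated by the reflex arc, and the plant advances.  For each
#' candidate cause prior, the Bayesian-model-reduction log evidence is
#' accumulated (rectangle rule at `dt`) relative to the full (Bayesian
#' model average) prior.
#'
#' @param model a [continuous_model()].
#' @param belief initial [generalized_belief()].
#' @param prior the full (BMA) [cause_prior()].
#' @param plant a plant handle from [make_arm_plant()].
#' @param duration epoch length (s); `duration / dt` must be integral.
#' @param dt integration step (s).
#' @param candidates optional list of 6-vector candidate cause
#'   expectations (order 0) sharing the prior's precision.
#' @param a0 initial action.
#' @return an object of class `epoch_result`: trajectory matrices
#'   (`time`, `states`, `hand`, `y`, `a`, `mu_x0`, `mu_v0`), the final
#'   `belief`, final action `a`, free-energy trace `F`, and accumulated
#'   log evidences `L` (one per candidate).
#' @export
run_epoch <- function(model, belief, prior, plant, duration, dt,
                      candidates = list(), a0 = NULL) {
  n <- round(duration / dt)
  if (abs(n * dt - duration) > 1e-9)
    stop_invalid("'duration' must be an integral multiple of 'dt'")
  a <- if (is.null(a0)) rep(0, 3) else check_numeric_vec(a0, "a0", 3)
  ncand <- length(candidates)
  L <- rep(0, ncand)
  iv0 <- vapply(1:6, function(ch) model$iv(ch, 0L), integer(1))
  P_v0 <- model$L_v[seq(1, by = model$n_v, length.out = 6),
                    seq(1, by = model$n_v, length.out = 6)]
  eta0 <- prior$eta_v[, 1]
  dyda <- reflex_jacobian(model)

  states <- matrix(0, n, 6); hand <- matrix(0, n, 3)
  yrec <- matrix(0, n, 12); arec <- matrix(0, n, 3)
  mux0 <- matrix(0, n, 6); muv0 <- matrix(0, n, 6)
  Ftr <- numeric(n)

  for (i in seq_len(n)) {
    y_gen <- plant$observe(a)
    err <- prediction_errors(belief, y_gen, prior, model)
    curv <- free_energy_curvature(err)
    if (ncand > 0L) {
      Q <- curv[iv0, iv0]
      m <- belief$mu_v[, 1]
      for (j in seq_len(ncand)) {
        L[j] <- L[j] + dt * reduced_log_evidence(
          posterior = list(mean = m, precision = Q),
          prior = list(mean = eta0, precision = P_v0),
          reduced_mean = candidates[[j]])
      }
    }
    belief <- belief_update(belief, err, model, dt, curv = curv)
    a <- action_step(a, err, model, dt, dyda = dyda)
    plant$advance(a)
    states[i, ] <- plant$state
    hand[i, ] <- forward_kinematics(model$geom, plant$state[1:3])
    yrec[i, ] <- plant$last_y
    arec[i, ] <- a
    mux0[i, ] <- belief$mu_x[, 1]
    muv0[i, ] <- belief$mu_v[, 1]
    Ftr[i] <- belief$free_energy_trace[length(belief$free_energy_trace)]
  }
  structure(list(time = plant$time0 + (seq_len(n) - 1L) * dt +
                   (plant$i - n - 1L) * dt, states = states,
                 hand = hand, y = yrec, a = arec, mu_x0 = mux0,
                 mu_v0 = muv0, F = Ftr, L = L, belief = belief, a_final = a),
            class = "epoch_result")
}
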