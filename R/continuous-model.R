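## Assembly of the continuous generative model in generalized
## coordinates: prediction errors, their exact derivative operators, the
## variational free energy, and its gradient/curvature.
##
## Channel-major ordering throughout: the vectorized belief stacks, for
## each channel, its derivative orders 0..n-1.  The combined belief
## vector is c(vec(mu_x), vec(mu_v)) with 6 state channels at order n_x
## and 6 cause channels at order n_v.
##
## The generative model (rows of the sensory map g and flow f) is
## nonlinear only through the forward kinematics Theta.  Orders >= 1 of g
## and f are propagated with the Jacobians evaluated at the order-0
## belief (local linearization).  The free-energy gradient is exact for
## this model definition: it includes the second-derivative tensor of
## Theta where the Jacobians depend on the believed angles.

## vectorization helpers (channel-major): matrix rows = channels,
## cols = orders
vec_cm <- function(M) as.numeric(t(M))
unvec_cm <- function(v, m, n) t(matrix(v, n, m))

#' Construct the continuous-inference model
#'
#' Precomputes the generalized precisions, shift operators and index maps
#' used by [prediction_errors()], [filtering_step()] and [run_epoch()].
#'
#' @param geom an [arm_geometry()].
#' @param p an [arm_dynamics_params()].
#' @param n_x embedding order for hidden states (default 4).
#' @param n_v embedding order for causes and data (default 2).
#' @param action_gain reflex-arc gain k_a.
#' @param action_decay leak rate of the action (motor activation decay,
#'   1/s); damps the integral action of the reflex arc.
#' @param divergence_bound belief norm beyond which the filter aborts
#'   with a numerical-instability error.
#' @return an object of class `continuous_model`.
#' @export
continuous_model <- function(geom, p, n_x = 4, n_v = 2, action_gain = 1,
                             action_decay = 0, divergence_bound = 1e3) {
  n_x <- check_count(n_x, "n_x")
  n_v <- check_count(n_v, "n_v")
  ## spatial precisions
  lp <- p$sensory_logprec
  pi_y <- diag(exp(c(rep(lp$proprio_pos, 3), rep(lp$proprio_vel, 3),
                     rep(lp$visual_pos, 3), rep(lp$visual_colour, 3))))
  pi_w <- diag(rep(exp(p$process_logprec), 6))
  pi_v <- diag(exp(c(rep(p$cause_logprec$attractor, 3),
                     rep(p$cause_logprec$colour, 3))))
  ky <- smoothness_kernel(p$lam_model, n_v)
  kx <- smoothness_kernel(p$lam_model, n_x)
  L_y <- generalized_precision(pi_y, ky)$full
  L_x <- generalized_precision(pi_w, kx)$full
  L_v <- generalized_precision(pi_v, ky)$full
  logdet <- determinant(L_y)$modulus + determinant(L_x)$modulus +
    determinant(L_v)$modulus
  nmu <- 6L * n_x + 6L * n_v
  D <- matrix(0, nmu, nmu)
  D[1:(6 * n_x), 1:(6 * n_x)] <- shift_operator(6L, n_x)
  D[(6 * n_x + 1):nmu, (6 * n_x + 1):nmu] <- shift_operator(6L, n_v)
  structure(list(
    geom = geom, p = p, n_x = n_x, n_v = n_v,
    L_y = L_y, L_x = L_x, L_v = L_v, logdet = as.numeric(logdet),
    D = D, nmu = nmu,
    ix = function(ch, k) (ch - 1L) * n_x + k + 1L,
    iv = function(ch, k) 6L * n_x + (ch - 1L) * n_v + k + 1L,
    iy = function(ch, k) (ch - 1L) * n_v + k + 1L,
    action_gain = action_gain, action_decay = action_decay,
    divergence_bound = divergence_bound
  ), class = "continuous_model")
}

#' Initialize a generalized belief
#'
#' @param model a [continuous_model()].
#' @param x0 6-vector initial state expectation (order 0).
#' @param v0 6-vector initial cause expectation (order 0).
#' @return an object of class `generalized_belief` with fields `mu_x`
#'   (6 x n_x), `mu_v` (6 x n_v) and `free_energy_trace`.
#' @export
generalized_belief <- function(model, x0 = rep(0, 6), v0 = rep(0, 6)) {
  mu_x <- matrix(0, 6, model$n_x)
  mu_v <- matrix(0, 6, model$n_v)
  mu_x[, 1] <- check_numeric_vec(x0, "x0", 6)
  mu_v[, 1] <- check_numeric_vec(v0, "v0", 6)
  structure(list(mu_x = mu_x, mu_v = mu_v, free_energy_trace = numeric(0)),
            class = "generalized_belief")
}

#' Descending prior over hidden causes
#'
#' @param model a [continuous_model()].
#' @param eta0 6-vector prior expectation of the causes at order 0.
#' @param eta1 6-vector prior expectation of the first derivative.
#' @return an object of class `cause_prior` with fields `eta_v`
#'   (6 x n_v) and `prec_v` (the generalized precision).
#' @export
cause_prior <- function(model, eta0, eta1 = rep(0, 6)) {
  eta <- matrix(0, 6, model$n_v)
  eta[, 1] <- check_numeric_vec(eta0, "eta0", 6)
  if (model$n_v > 1L) eta[, 2] <- check_numeric_vec(eta1, "eta1", 6)
  structure(list(eta_v = eta, prec_v = model$L_v), class = "cause_prior")
}

#' Generalized prediction errors and their derivative operators
#'
#' Computes the three error streams of the continuous model --
#' sensory \eqn{\varepsilon_y = \tilde y - \tilde g(\mu)}, dynamical
#' \eqn{\varepsilon_x = D\tilde\mu_x - \tilde f(\mu)} and prior
#' \eqn{\varepsilon_v = \tilde\mu_v - \tilde\eta_v} -- together with the
#' exact derivative operators \eqn{\partial\varepsilon/\partial\mu} used
#' for gradients and Gauss--Newton curvature.  Each stream carries its
#' generalized precision.
#'
#' @param belief a [generalized_belief()].
#' @param y_gen 12 x n_v matrix of sensory data in generalized
#'   coordinates (columns are derivative orders).
#' @param prior a [cause_prior()].
#' @param model a [continuous_model()].
#' @return list with error vectors `e_y`, `e_x`, `e_v` (channel-major),
#'   operators `A_y`, `A_x`, `A_v`, and the attached precisions.
#' @export
prediction_errors <- function(belief, y_gen, prior, model) {
  n_x <- model$n_x; n_v <- model$n_v
  if (!is.matrix(y_gen) || nrow(y_gen) != 12L || ncol(y_gen) != n_v)
    stop_invalid(sprintf("'y_gen' must be a 12 x %d matrix", n_v))
  X <- belief$mu_x; V <- belief$mu_v
  if (nrow(X) != 6L || ncol(X) != n_x || nrow(V) != 6L || ncol(V) != n_v)
    stop_invalid("belief dimensions do not match the model configuration")
  geom <- model$geom; p <- model$p
  q <- X[1:3, 1]; vel <- X[4:6, 1]; v0 <- V[, 1]
  Theta <- forward_kinematics(geom, q)
  J <- kinematics_jacobian(geom, q)
  H <- kinematics_hessian(geom, q)
  kap <- p$kappa; bet <- p$damping

  ix <- model$ix; iv <- model$iv; iy <- model$iy
  nmu <- model$nmu

  ## --- sensory errors -----------------------------------------------------
  e_y <- matrix(0, 12, n_v)
  e_y[, 1] <- y_gen[, 1] - c(q, vel, Theta, v0[4:6])
  if (n_v > 1L) {
    for (k in seq_len(n_v - 1L)) {
      gx <- c(X[1:3, k + 1L], X[4:6, k + 1L], as.numeric(J %*% X[1:3, k + 1L]),
              V[4:6, k + 1L])
      e_y[, k + 1L] <- y_gen[, k + 1L] - gx
    }
  }
  A_y <- matrix(0, 12L * n_v, nmu)
  for (k in 0:(n_v - 1L)) {
    for (c3 in 1:3) {
      A_y[iy(c3, k), ix(c3, k)] <- -1            # II rows
      A_y[iy(3L + c3, k), ix(3L + c3, k)] <- -1  # Ia rows
      A_y[iy(9L + c3, k), iv(3L + c3, k)] <- -1  # colour rows
    }
    for (i in 1:3) for (j in 1:3)
      A_y[iy(6L + i, k), ix(j, k)] <- -J[i, j]   # visual rows
  }
  ## tensor correction: order >= 1 visual rows depend on the believed
  ## angles through J
  if (n_v > 1L) {
    for (k in seq_len(n_v - 1L)) {
      for (l in 1:3) {
        hx <- H[[l]] %*% X[1:3, k + 1L]
        for (i in 1:3)
          A_y[iy(6L + i, k), ix(l, 0L)] <-
            A_y[iy(6L + i, k), ix(l, 0L)] - hx[i]
      }
    }
  }

  ## --- dynamical errors ---------------------------------------------------
  JtJ <- crossprod(J)
  d <- v0[1:3] - Theta
  e_x <- matrix(0, 6, n_x)
  f0 <- c(vel, kap * (as.numeric(crossprod(J, d)) - bet * vel))
  e_x[, 1] <- (if (n_x > 1L) X[, 2] else rep(0, 6)) - f0
  if (n_x > 1L) {
    for (k in seq_len(n_x - 1L)) {
      xk <- X[, k + 1L]
      vk <- if (k + 1L <= n_v) V[, k + 1L] else rep(0, 6)
      fk <- c(xk[4:6],
              kap * (as.numeric(-JtJ %*% xk[1:3]) - bet * xk[4:6] +
                       as.numeric(crossprod(J, vk[1:3]))))
      nxt <- if (k + 2L <= n_x) X[, k + 2L] else rep(0, 6)
      e_x[, k + 1L] <- nxt - fk
    }
  }
  A_x <- matrix(0, 6L * n_x, nmu)
  ## order 0
  for (i in 1:3) {
    if (n_x > 1L) A_x[ix(i, 0L), ix(i, 1L)] <- 1
    A_x[ix(i, 0L), ix(3L + i, 0L)] <- -1
    if (n_x > 1L) A_x[ix(3L + i, 0L), ix(3L + i, 1L)] <- 1
    A_x[ix(3L + i, 0L), ix(3L + i, 0L)] <- kap * bet
  }
  for (i in 1:3) for (j in 1:3)
    A_x[ix(3L + i, 0L), iv(j, 0L)] <- -kap * J[j, i]   # -kappa * t(J)
  for (l in 1:3) {
    corr <- -kap * (as.numeric(crossprod(H[[l]], d)) - as.numeric(crossprod(J, J[, l])))
    for (i in 1:3)
      A_x[ix(3L + i, 0L), ix(l, 0L)] <-
        A_x[ix(3L + i, 0L), ix(l, 0L)] + corr[i]
  }
  ## orders >= 1
  if (n_x > 1L) {
    for (k in seq_len(n_x - 1L)) {
      for (i in 1:3) {
        if (k + 2L <= n_x) A_x[ix(i, k), ix(i, k + 1L)] <- 1
        A_x[ix(i, k), ix(3L + i, k)] <- -1
        if (k + 2L <= n_x) A_x[ix(3L + i, k), ix(3L + i, k + 1L)] <- 1
        A_x[ix(3L + i, k), ix(3L + i, k)] <- kap * bet
      }
      for (i in 1:3) for (j in 1:3) {
        A_x[ix(3L + i, k), ix(j, k)] <- kap * JtJ[i, j]
        if (k + 1L <= n_v) A_x[ix(3L + i, k), iv(j, k)] <- -kap * J[j, i]
      }
      ## tensor corrections wrt the order-0 angles
      xk <- X[1:3, k + 1L]
      vk <- if (k + 1L <= n_v) V[1:3, k + 1L] else rep(0, 3)
      for (l in 1:3) {
        dJtJ <- crossprod(H[[l]], J) + crossprod(J, H[[l]])
        corr <- kap * (as.numeric(dJtJ %*% xk) -
                         as.numeric(crossprod(H[[l]], vk)))
        for (i in 1:3)
          A_x[ix(3L + i, k), ix(l, 0L)] <-
            A_x[ix(3L + i, k), ix(l, 0L)] + corr[i]
      }
    }
  }

  ## --- prior errors -------------------------------------------------------
  e_v <- V - prior$eta_v
  A_v <- matrix(0, 6L * n_v, nmu)
  for (ch in 1:6) for (k in 0:(n_v - 1L))
    A_v[(ch - 1L) * n_v + k + 1L, iv(ch, k)] <- 1

  list(e_y = vec_cm(e_y), e_x = vec_cm(e_x), e_v = vec_cm(e_v),
       A_y = A_y, A_x = A_x, A_v = A_v,
       L_y = model$L_y, L_x = model$L_x, L_v = model$L_v,
       logdet = model$logdet)
}

#' Variational free energy of a set of prediction errors
#'
#' \eqn{F = \frac12 \sum_s \varepsilon_s^\top \tilde\Pi_s \varepsilon_s
#' - \frac12 \ln|\tilde\Pi_s| + \mathrm{const}}; the log-determinant and
#' \eqn{2\pi} terms are constant for a fixed configuration and are
#' included so traces are on the scale of a negative log joint.
#'
#' @param errors output of [prediction_errors()].
#' @return scalar free energy.
#' @export
free_energy <- function(errors) {
  quad <- as.numeric(
    crossprod(errors$e_y, errors$L_y %*% errors$e_y) +
      crossprod(errors$e_x, errors$L_x %*% errors$e_x) +
      crossprod(errors$e_v, errors$L_v %*% errors$e_v))
  d <- length(errors$e_y) + length(errors$e_x) + length(errors$e_v)
  0.5 * quad - 0.5 * errors$logdet + 0.5 * d * log(2 * pi)
}

## gradient and Gauss-Newton curvature of F wrt the combined belief
free_energy_gradient <- function(errors) {
  as.numeric(
    crossprod(errors$A_y, errors$L_y %*% errors$e_y) +
      crossprod(errors$A_x, errors$L_x %*% errors$e_x) +
      crossprod(errors$A_v, errors$L_v %*% errors$e_v))
}

free_energy_curvature <- function(errors) {
  crossprod(errors$A_y, errors$L_y %*% errors$A_y) +
    crossprod(errors$A_x, errors$L_x %*% errors$A_x) +
    crossprod(errors$A_v, errors$L_v %*% errors$A_v)
}
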