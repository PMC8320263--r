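## Continuous generative model of a three-joint arm, and the "real world"
## plant that integrates the true dynamics driven by action.
##
## State x = (x1..3, x4..6): angular positions (shoulder rotation,
## shoulder flexion, elbow flexion) and the corresponding velocities.
## Hidden causes v = (v1..3, v4..6): the Euclidean attracting point of a
## fictitious equilibrium-point force, and the intensities of the three
## target colours.  Sensory data y (12 channels, fixed order): type-II
## afferents (joint angles), Ia afferents (joint velocities), visual hand
## position, visual target colours.
##
## Kinematic convention: zero angles mean the arm hangs vertically;
## shoulder rotation is about the vertical axis and flexions are measured
## from the downward vertical, the forearm using the summed angle
## x2 + x3.  Segment direction: u(r, phi) = (sin phi cos r,
## sin phi sin r, -cos phi).

#' Arm geometry
#'
#' @param shoulder_pos 3-vector, shoulder position (m).
#' @param upper_len upper-arm length L1 (m), > 0.
#' @param fore_len forearm length L2 (m), > 0.
#' @return an object of class `arm_geometry`.
#' @export
arm_geometry <- function(shoulder_pos = c(0, 0, 1.5),
                         upper_len = 0.3, fore_len = 0.3) {
  shoulder_pos <- check_numeric_vec(shoulder_pos, "shoulder_pos", 3)
  check_scalar(upper_len, "upper_len", lower = 0, strict_lower = TRUE)
  check_scalar(fore_len, "fore_len", lower = 0, strict_lower = TRUE)
  structure(list(shoulder_pos = shoulder_pos, upper_len = upper_len,
                 fore_len = fore_len),
            class = "arm_geometry")
}

## unit direction of a segment at shoulder rotation r, flexion phi
seg_dir <- function(r, phi) {
  c(sin(phi) * cos(r), sin(phi) * sin(r), -cos(phi))
}

#' Forward kinematics
#'
#' Euclidean hand position
#' \eqn{\Theta(x) = \theta + L_1 u(x_1, x_2) + L_2 u(x_1, x_2 + x_3)}
#' with \eqn{u(r, \phi) = (\sin\phi\cos r, \sin\phi\sin r, -\cos\phi)}:
#' the arm hangs straight down at zero angles.
#'
#' @param geom an [arm_geometry()].
#' @param angles 3-vector of joint angles (rad): shoulder rotation,
#'   shoulder flexion, elbow flexion.
#' @return 3-vector hand position (m).
#' @export
forward_kinematics <- function(geom, angles) {
  angles <- check_numeric_vec(angles, "angles", 3)
  geom$shoulder_pos +
    geom$upper_len * seg_dir(angles[1], angles[2]) +
    geom$fore_len * seg_dir(angles[1], angles[2] + angles[3])
}

#' Jacobian of the forward kinematics
#'
#' Analytic gradient \eqn{\partial\Theta/\partial x} of the hand position
#' with respect to the three joint angles.
#'
#' @inheritParams forward_kinematics
#' @return 3 x 3 matrix; column j is the hand velocity per unit angular
#'   velocity of joint j.
#' @export
kinematics_jacobian <- function(geom, angles) {
  angles <- check_numeric_vec(angles, "angles", 3)
  r <- angles[1]; phi <- angles[2]; psi <- angles[2] + angles[3]
  L1 <- geom$upper_len; L2 <- geom$fore_len
  du_dr <- function(rr, pp) c(-sin(pp) * sin(rr), sin(pp) * cos(rr), 0)
  du_dphi <- function(rr, pp) c(cos(pp) * cos(rr), cos(pp) * sin(rr), sin(pp))
  J <- matrix(0, 3, 3)
  J[, 1] <- L1 * du_dr(r, phi) + L2 * du_dr(r, psi)
  J[, 2] <- L1 * du_dphi(r, phi) + L2 * du_dphi(r, psi)
  J[, 3] <- L2 * du_dphi(r, psi)
  J
}

## Second-derivative tensor of Theta wrt angles: a list of three 3x3
## matrices, H[[l]] = d J / d q_l.  Needed for exact free-energy
## gradients in the continuous filter.
kinematics_hessian <- function(geom, angles) {
  r <- angles[1]; phi <- angles[2]; psi <- angles[2] + angles[3]
  L1 <- geom$upper_len; L2 <- geom$fore_len
  u_rr <- function(rr, pp) c(-sin(pp) * cos(rr), -sin(pp) * sin(rr), 0)
  u_rp <- function(rr, pp) c(-cos(pp) * sin(rr), cos(pp) * cos(rr), 0)
  u_pp <- function(rr, pp) c(-sin(pp) * cos(rr), -sin(pp) * sin(rr), cos(pp))
  H <- vector("list", 3)
  ## dJ/dr
  M <- matrix(0, 3, 3)
  M[, 1] <- L1 * u_rr(r, phi) + L2 * u_rr(r, psi)
  M[, 2] <- L1 * u_rp(r, phi) + L2 * u_rp(r, psi)
  M[, 3] <- L2 * u_rp(r, psi)
  H[[1]] <- M
  ## dJ/dphi (shoulder flexion affects both phi and psi)
  M <- matrix(0, 3, 3)
  M[, 1] <- L1 * u_rp(r, phi) + L2 * u_rp(r, psi)
  M[, 2] <- L1 * u_pp(r, phi) + L2 * u_pp(r, psi)
  M[, 3] <- L2 * u_pp(r, psi)
  H[[2]] <- M
  ## dJ/d(elbow): only terms in psi
  M <- matrix(0, 3, 3)
  M[, 1] <- L2 * u_rp(r, psi)
  M[, 2] <- L2 * u_pp(r, psi)
  M[, 3] <- L2 * u_pp(r, psi)
  H[[3]] <- M
  H
}

#' Parameters of the continuous dynamics and plant
#'
#' @param kappa gain coupling the fictitious force to angular
#'   acceleration (inverse-inertia-like, > 0).
#' @param damping velocity damping coefficient beta (>= 0); enters the
#'   flow as \eqn{\kappa(\dots - \beta x_{4..6})}.
#' @param sensory_logprec named list of log precisions for the four
#'   sensory modalities: `proprio_pos` (II), `proprio_vel` (Ia),
#'   `visual_pos`, `visual_colour`.
#' @param process_logprec scalar log precision of the state-noise terms.
#' @param cause_logprec named list with `attractor` and `colour` log
#'   precisions of the descending cause prior.
#' @param lam_model smoothness assumed by the generative model (s).
#' @param lam_world smoothness of the plant's actual fluctuations (s).
#' @param sensory_noise_sd,process_noise_sd plant noise amplitudes.
#' @return an object of class `arm_dynamics_params`.
#' @export
arm_dynamics_params <- function(kappa = 60, damping = 0.12,
                                sensory_logprec = list(
                                  proprio_pos = 4, proprio_vel = 4,
                                  visual_pos = 4, visual_colour = 4),
                                process_logprec = 3,
                                cause_logprec = list(attractor = 2,
                                                     colour = 2),
                                lam_model = 1 / 32, lam_world = 1 / 32,
                                sensory_noise_sd = 1e-3,
                                process_noise_sd = 1e-3) {
  check_scalar(kappa, "kappa", lower = 0, strict_lower = TRUE)
  check_scalar(damping, "damping", lower = 0)
  check_scalar(lam_model, "lam_model", lower = 0, strict_lower = TRUE)
  check_scalar(lam_world, "lam_world", lower = 0, strict_lower = TRUE)
  structure(list(kappa = kappa, damping = damping,
                 sensory_logprec = sensory_logprec,
                 process_logprec = process_logprec,
                 cause_logprec = cause_logprec,
                 lam_model = lam_model, lam_world = lam_world,
                 sensory_noise_sd = sensory_noise_sd,
                 process_noise_sd = process_noise_sd),
            class = "arm_dynamics_params")
}

#' Equilibrium-point model flow
#'
#' Flow of the generative model: positions follow velocities, and
#' velocities accelerate toward a fictitious attracting point,
#' \eqn{\dot x_{4..6} = \kappa (J^\top (v_{1..3} - \Theta(x)) - \beta
#' x_{4..6})}, where `J` is the kinematics Jacobian.
#'
#' @param x 6-vector joint state (angles then velocities).
#' @param v 6-vector hidden causes (attractor xyz then colours).
#' @param p an [arm_dynamics_params()].
#' @param geom an [arm_geometry()].
#' @return 6-vector \eqn{\dot x}.
#' @export
model_flow <- function(x, v, p, geom) {
  x <- check_numeric_vec(x, "x", 6)
  v <- check_numeric_vec(v, "v", 6)
  J <- kinematics_jacobian(geom, x[1:3])
  acc <- p$kappa * (as.numeric(crossprod(J, v[1:3] - forward_kinematics(geom, x[1:3]))) -
                      p$damping * x[4:6])
  c(x[4:6], acc)
}

#' Sensory mapping
#'
#' The map g from hidden states and causes to the 12 sensory channels, in
#' fixed order: II afferents (angles), Ia afferents (velocities), visual
#' hand position, visual target colours.
#'
#' @inheritParams model_flow
#' @return 12-vector sensory prediction.
#' @export
sensory_map <- function(x, v, geom) {
  x <- check_numeric_vec(x, "x", 6)
  v <- check_numeric_vec(v, "v", 6)
  c(x[1:3], x[4:6], forward_kinematics(geom, x[1:3]), v[4:6])
}

#' One Euler--Maruyama step of the true plant
#'
#' Integrates the real-world dynamics \eqn{\dot x_{1..3} = x_{4..6}},
#' \eqn{\dot x_{4..6} = \kappa (a - \beta x_{4..6}) + w} and emits the new
#' sensory frame.  Noise values (smooth fluctuations generated at the
#' world smoothness) are supplied explicitly so that the caller controls
#' the noise process; `NULL` means noise-free.
#'
#' @param state 6-vector joint state.
#' @param a 3-vector action (torque-like, one per joint).
#' @param p an [arm_dynamics_params()].
#' @param geom an [arm_geometry()].
#' @param dt integration step (s), > 0.
#' @param v_world 6-vector of true causes entering the sensory frame
#'   (colour channels); attractor channels are not sensed.
#' @param noise optional list with `w` (3-vector process noise on the
#'   accelerations) and `sy` (12-vector additive sensory noise).
#' @return list with `state` (new 6-vector, angles wrapped to
#'   \eqn{(-\pi, \pi]}) and `y` (12-vector sensory frame including
#'   noise).
#' @export
plant_step <- function(state, a, p, geom, dt, v_world = rep(0, 6),
                       noise = NULL) {
  check_scalar(dt, "dt", lower = 0, strict_lower = TRUE)
  state <- check_numeric_vec(state, "state", 6)
  a <- check_numeric_vec(a, "a", 3)
  w <- if (is.null(noise)) rep(0, 3) else noise$w
  sy <- if (is.null(noise)) rep(0, 12) else noise$sy
  acc <- p$kappa * (a - p$damping * state[4:6]) + w
  new <- c(wrap_angle(state[1:3] + dt * state[4:6]),
           state[4:6] + dt * acc)
  y <- sensory_map(new, v_world, geom) + sy
  list(state = new, y = y)
}

## Time derivative of the noise-free plant sensory frame; used to embed
## the data in generalized coordinates (order 1).
plant_sensory_derivative <- function(state, a, p, geom, w = rep(0, 3)) {
  acc <- p$kappa * (a - p$damping * state[4:6]) + w
  J <- kinematics_jacobian(geom, state[1:3])
  c(state[4:6], acc, as.numeric(J %*% state[4:6]), rep(0, 3))
}

#' Smooth (temporally correlated) Gaussian noise
#'
#' Generates channels of unit-variance Gaussian noise with Gaussian
#' autocorrelation of width `lam` on a regular time grid, together with
#' its analytic time derivative, by convolving white noise with a
#' Gaussian kernel (and the kernel's derivative).  Scaled by `sd`.
#'
#' @param n_steps number of time points.
#' @param dt grid spacing (s).
#' @param lam autocorrelation width (s).
#' @param n_channels number of independent channels.
#' @param sd marginal standard deviation of each channel.
#' @param seed integer seed; the draw is fully determined by it.
#' @return list with `value` and `deriv`, both `n_channels` x `n_steps`.
#' @export
smooth_noise <- function(n_steps, dt, lam, n_channels, sd, seed) {
  n_steps <- check_count(n_steps, "n_steps")
  check_scalar(dt, "dt", lower = 0, strict_lower = TRUE)
  check_scalar(lam, "lam", lower = 0, strict_lower = TRUE)
  if (sd == 0) {
    z <- matrix(0, n_channels, n_steps)
    return(list(value = z, deriv = z))
  }
  ## white noise convolved with a Gaussian of width sig = lam / sqrt(2)
  ## has autocorrelation exp(-h^2 / (2 lam^2))
  sig <- lam / sqrt(2)
  half <- max(1L, ceiling(4 * sig / dt))
  tk <- (-half:half) * dt
  kern <- exp(-tk^2 / (2 * sig^2))
  dkern <- -tk / sig^2 * kern
  ## normalization so that the filtered white noise has unit variance
  nrm <- sqrt(sum(kern^2))
  kern <- kern / nrm
  dkern <- dkern / nrm
  set.seed(seed)
  npad <- n_steps + 2L * half
  z <- matrix(rnorm(n_channels * npad), n_channels, npad)
  val <- matrix(0, n_channels, n_steps)
  der <- matrix(0, n_channels, n_steps)
  for (ch in seq_len(n_channels)) {
    v <- stats::convolve(z[ch, ], rev(kern), type = "filter")
    d <- stats::convolve(z[ch, ], rev(dkern), type = "filter")
    val[ch, ] <- sd * v[seq_len(n_steps)]
    der[ch, ] <- sd * d[seq_len(n_steps)]
  }
  list(value = val, deriv = der)
}

#' Numeric inverse kinematics
#'
#' Finds joint angles placing the hand at `target` by damped least
#' squares iteration from `init`.  Used to pose the arm at exam start.
#'
#' @param geom an [arm_geometry()].
#' @param target 3-vector Euclidean target (m); must be reachable.
#' @param init starting angles for the iteration.
#' @return 3-vector of joint angles.
#' @export
inverse_kinematics <- function(geom, target, init = c(0, 0.5, 1)) {
  target <- check_numeric_vec(target, "target", 3)
  q <- init
  for (i in seq_len(200)) {
    err <- target - forward_kinematics(geom, q)
    if (sqrt(sum(err^2)) < 1e-10) break
    J <- kinematics_jacobian(geom, q)
    dq <- solve(crossprod(J) + 1e-6 * diag(3), crossprod(J, err))
    q <- q + as.numeric(dq)
  }
  if (sqrt(sum((target - forward_kinematics(geom, q))^2)) > 1e-6)
    stop_invalid("inverse_kinematics did not converge; is the target reachable?")
  wrap_angle(q)
}
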