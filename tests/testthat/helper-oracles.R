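# Independent oracles used across test files.  These deliberately avoid
# the code paths they check.

# k-th symbolic derivative of the Gaussian autocorrelation
# rho(h) = exp(-h^2 / (2 lam^2)) evaluated at h = 0, via repeated
# symbolic differentiation with stats::D().
rho_deriv_symbolic <- function(lam, k) {
  ex <- quote(exp(-h^2 / (2 * lam^2)))
  for (i in seq_len(k)) ex <- stats::D(ex, "h")
  eval(ex, list(h = 0, lam = lam))
}

# Smoothness covariance/precision built directly from the symbolic oracle.
kernel_symbolic <- function(lam, n) {
  V <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- (i - 1) + (j - 1)
    if (s %% 2 == 0) V[i, j] <- (-1)^(i - 1) * rho_deriv_symbolic(lam, s)
  }
  list(V = V, S = solve(V))
}

# Hand position by composing numeric rotations, independent of the
# closed-form spherical expressions used in the package.  The arm hangs
# along -z at zero angles; shoulder rotation is about the vertical (z)
# axis, flexions rotate about the (rotated) y axis.
fk_rotation_oracle <- function(shoulder, L1, L2, q) {
  Rz <- function(a) rbind(c(cos(a), -sin(a), 0),
                          c(sin(a), cos(a), 0),
                          c(0, 0, 1))
  Ry <- function(a) rbind(c(cos(a), 0, sin(a)),
                          c(0, 1, 0),
                          c(-sin(a), 0, cos(a)))
  down <- c(0, 0, -1)
  # flexion phi from the downward vertical within the plane selected by
  # the shoulder rotation r: direction = Rz(r) %*% Ry(-phi) %*% down
  # with Ry(-phi) tipping -z toward +x.
  dir1 <- Rz(q[1]) %*% Ry(-q[2]) %*% down
  dir2 <- Rz(q[1]) %*% Ry(-(q[2] + q[3])) %*% down
  as.numeric(shoulder + L1 * dir1 + L2 * dir2)
}

# Central finite-difference Jacobian of a vector-valued function.
fd_jacobian <- function(f, x, h = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    e <- rep(0, length(x)); e[j] <- h
    J[, j] <- (f(x + e) - f(x - e)) / (2 * h)
  }
  J
}
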