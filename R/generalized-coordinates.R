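## Generalized coordinates of motion: smoothness kernels S(lambda),
## factorized generalized precisions Pi (x) S(lambda), Taylor-shift
## (derivative) operators, and analytic embedding of exogenous pulses.
##
## A variable in generalized coordinates is represented by its value and
## its first n-1 temporal derivatives.  Random fluctuations with Gaussian
## autocorrelation rho(h) = exp(-h^2 / (2 lambda^2)) induce correlations
## between those derivative orders; S(lambda) is the resulting temporal
## precision, so that the full precision over a generalized variable
## factorizes into a spatial part Pi and a temporal part S(lambda).

#' Even derivatives of the Gaussian autocorrelation at zero lag
#'
#' Returns \eqn{\rho(0), \rho''(0), \rho''''(0), \dots} for the Gaussian
#' autocorrelation \eqn{\rho(h) = \exp(-h^2/(2\lambda^2))}, up to the
#' order needed to build an `n` x `n` smoothness kernel.  Odd derivatives
#' vanish by symmetry and are not returned.  The closed form is
#' \eqn{\rho^{(2k)}(0) = (-1)^k (2k-1)!! / \lambda^{2k}}.
#'
#' @param lam smoothness parameter \eqn{\lambda > 0} (time units).
#' @param n embedding order (number of derivative orders represented).
#' @return numeric vector of length `n`: the even derivatives
#'   \eqn{\rho^{(2k)}(0)} for \eqn{k = 0, \dots, n-1}.
#' @examples
#' autocorrelation_derivatives(1, 3)   # 1, -1, 3
#' @export
autocorrelation_derivatives <- function(lam, n) {
  check_scalar(lam, "lam", lower = 0, strict_lower = TRUE)
  n <- check_count(n, "n")
  k <- seq_len(n) - 1L
  ## double factorial (2k - 1)!! with (-1)!! = 1
  dfact <- vapply(k, function(kk) {
    if (kk == 0L) 1 else prod(seq(2 * kk - 1, 1, by = -2))
  }, numeric(1))
  (-1)^k * dfact / lam^(2 * k)
}

#' Temporal smoothness kernel S(lambda)
#'
#' Covariance `V` and precision `S = solve(V)` among the first `n`
#' derivative orders of a fluctuation with Gaussian autocorrelation of
#' width `lam`.  `V[i, j] = (-1)^i rho^(i+j)(0)` for even `i + j`
#' (zero-based indices) and zero otherwise, so entries with odd index sum
#' are exactly zero and both matrices are symmetric positive definite.
#'
#' @inheritParams autocorrelation_derivatives
#' @return an object of class `smoothness_kernel` with fields `lam`,
#'   `order`, `S` (precision) and `V` (covariance).
#' @examples
#' smoothness_kernel(1, 3)$V   # rbind(c(1,0,-1), c(0,1,0), c(-1,0,3))
#' @export
smoothness_kernel <- function(lam, n) {
  n <- check_count(n, "n")
  rho <- autocorrelation_derivatives(lam, n)  # even derivatives 0, 2, ...
  V <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      s <- (i - 1L) + (j - 1L)
      if (s %% 2L == 0L) V[i, j] <- (-1)^(i - 1L) * rho[s / 2L + 1L]
    }
  }
  S <- tryCatch(solve(V), error = function(e) {
    stop_invalid(sprintf(
      "smoothness kernel covariance is numerically singular (lam = %g, n = %d): %s",
      lam, n, conditionMessage(e)))
  })
  S <- (S + t(S)) / 2
  structure(list(lam = lam, order = n, S = S, V = V),
            class = "smoothness_kernel")
}

#' @export
print.smoothness_kernel <- function(x, ...) {
  cat(sprintf("<smoothness_kernel> lambda = %g, order = %d\n", x$lam, x$order))
  cat("S (temporal precision):\n")
  print(signif(x$S, 4))
  invisible(x)
}

#' Factorized generalized precision Pi (x) S(lambda)
#'
#' Kronecker product of a spatial precision `spatial` (over channels)
#' with the temporal precision of a smoothness kernel, under channel-major
#' ordering: all derivative orders of channel 1 first, then channel 2, and
#' so on.  This ordering convention is used for every generalized vector
#' in the package.
#'
#' @param spatial symmetric positive-definite m x m precision matrix.
#' @param kernel a [smoothness_kernel()].
#' @return an object of class `generalized_precision` with fields
#'   `spatial`, `kernel` and `full` (the (m n) x (m n) precision).
#' @export
generalized_precision <- function(spatial, kernel) {
  if (!inherits(kernel, "smoothness_kernel"))
    stop_invalid("'kernel' must be a smoothness_kernel object")
  if (!is.matrix(spatial) || nrow(spatial) != ncol(spatial) ||
      any(!is.finite(spatial)))
    stop_invalid("'spatial' must be a finite square matrix")
  if (max(abs(spatial - t(spatial))) > 1e-8 * max(1, max(abs(spatial))))
    stop_invalid("'spatial' precision must be symmetric")
  ev <- eigen(spatial, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop_invalid("'spatial' precision must be positive definite")
  full <- kronecker(spatial, kernel$S)
  structure(list(spatial = spatial, kernel = kernel, full = full),
            class = "generalized_precision")
}

#' Generalized derivative (Taylor-shift) operator
#'
#' Block-diagonal operator that maps each channel's derivative stack
#' \eqn{(x, x', \dots, x^{(n-1)})} to \eqn{(x', \dots, x^{(n-1)}, 0)},
#' i.e. differentiation truncated at the embedding order.  Applied to a
#' channel-major generalized vector of `m` channels it is nilpotent of
#' order `n`.
#'
#' @param m number of channels.
#' @param n embedding order per channel.
#' @return an (m n) x (m n) matrix.
#' @export
shift_operator <- function(m, n) {
  m <- check_count(m, "m")
  n <- check_count(n, "n")
  block <- matrix(0, n, n)
  if (n > 1L) block[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- 1
  kronecker(diag(m), block)
}

#' Generalized coordinates of a Gaussian pulse
#'
#' Value and first `n - 1` analytic time derivatives of the pulse
#' \eqn{a \exp(-(t - t_0)^2 / (2 w^2))} at time `t`.  Used to embed the
#' exogenous tendon-tap perturbation in the same generalized coordinates
#' as the sensory data.  Derivatives use the probabilists' Hermite
#' recursion: \eqn{d^k/dt^k e^{-s^2/2} = (-1/w)^k He_k(s) e^{-s^2/2}}
#' with \eqn{s = (t - t_0)/w}.
#'
#' @param amplitude pulse height.
#' @param onset pulse centre \eqn{t_0} (s).
#' @param width pulse width \eqn{w > 0} (s).
#' @param t evaluation time (s); may be a vector.
#' @param n number of derivative orders to return (>= 1).
#' @return if `t` is scalar, a numeric vector of length `n` (orders
#'   0..n-1); otherwise an `n` x `length(t)` matrix.
#' @export
embed_pulse <- function(amplitude, onset, width, t, n) {
  check_scalar(amplitude, "amplitude")
  check_scalar(onset, "onset")
  check_scalar(width, "width", lower = 0, strict_lower = TRUE)
  n <- check_count(n, "n")
  s <- (t - onset) / width
  base <- amplitude * exp(-s^2 / 2)
  out <- matrix(0, n, length(s))
  He_prev <- rep(0, length(s))
  He <- rep(1, length(s))          # He_0
  for (k in seq_len(n) - 1L) {
    out[k + 1L, ] <- (-1 / width)^k * He * base
    He_next <- s * He - k * He_prev
    He_prev <- He
    He <- He_next
  }
  if (length(s) == 1L) drop(out) else out
}
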