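## Internal numeric helpers shared across modules.

#' Softmax with a log floor
#'
#' Normalized exponential of a numeric vector.  Probabilities entering
#' logs elsewhere in the package are floored at `exp(-16)`, the same
#' floor used by the discrete belief updates.
#'
#' @param x numeric vector of log weights.
#' @return numeric vector summing to one.
#' @keywords internal
#' @noRd
softmax <- function(x) {
  x <- x - max(x)
  e <- exp(x)
  e / sum(e)
}

## log with probability floor exp(-16): keeps degenerate outcome
## distributions from producing -Inf inside discrete updates.
log_floor <- function(p) log(pmax(p, exp(-16)))

## normalize a nonnegative vector to sum 1 (uniform fallback on zero mass)
normalize <- function(p) {
  s <- sum(p)
  if (s <= 0 || !is.finite(s)) rep(1 / length(p), length(p)) else p / s
}

#' Matrix exponential (scaling-and-squaring Pade)
#'
#' Dense matrix exponential used by the local-linearization update of the
#' generalized filter.  Pade approximant of order 6 with scaling and
#' squaring; adequate for the small (< 50 x 50) Jacobians handled here.
#'
#' @param A square numeric matrix.
#' @return `exp(A)` as a dense matrix.
#' @keywords internal
#' @noRd
expm_pade <- function(A) {
  n <- nrow(A)
  nrmA <- max(rowSums(abs(A)))
  s <- if (nrmA > 0.5) max(0L, ceiling(log2(nrmA / 0.5))) else 0L
  A <- A / 2^s
  ## order-6 diagonal Pade coefficients
  cc <- c(1, 1 / 2, 5 / 44, 1 / 66, 1 / 792, 1 / 15840, 1 / 665280)
  I <- diag(n)
  P <- I
  U <- cc[1] * I
  V <- cc[1] * I
  sgn <- -1
  for (k in seq_len(6)) {
    P <- P %*% A
    U <- U + cc[k + 1] * P
    V <- V + sgn * cc[k + 1] * P
    sgn <- -sgn
  }
  E <- solve(V, U)
  for (k in seq_len(s)) E <- E %*% E
  E
}

## local-linearization step: returns the finite update
##   dx = (expm(J dt) - I) J^-1 f
## computed without inverting J via the augmented-matrix form.
ll_update <- function(f, J, dt) {
  n <- length(f)
  M <- matrix(0, n + 1L, n + 1L)
  M[2:(n + 1L), 1L] <- f * dt
  M[2:(n + 1L), 2:(n + 1L)] <- J * dt
  E <- expm_pade(M)
  E[2:(n + 1L), 1L]
}

## argument validation helpers ------------------------------------------------

stop_invalid <- function(...) stop(..., call. = FALSE)

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(sprintf("'%s' must be a finite numeric scalar", name))
  if ((strict_lower && x <= lower) || (!strict_lower && x < lower) || x > upper)
    stop_invalid(sprintf("'%s' = %g is outside its allowed range", name, x))
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < lower)
    stop_invalid(sprintf("'%s' must be an integer >= %d", name, lower))
  as.integer(x)
}

check_numeric_vec <- function(x, name, len) {
  if (!is.numeric(x) || length(x) != len || any(!is.finite(x)))
    stop_invalid(sprintf("'%s' must be a finite numeric vector of length %d",
                         name, len))
  as.numeric(x)
}

## wrap angles into (-pi, pi]
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}
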