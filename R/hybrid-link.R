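## The discrete <-> continuous interface: discrete outcomes are assigned
## points in the continuous cause space; descending predictions are the
## Bayesian model average of those points under the predicted outcome
## distribution; ascending evidence is accumulated by Bayesian model
## reduction (re-scoring the continuous posterior under each candidate
## prior mean) and combined with the outcome prior by a softmax.

#' Map from discrete outcomes to continuous cause expectations
#'
#' @param points matrix with one row per discrete outcome and 6 columns
#'   (attractor xyz then colour triple), or a list of 6-vectors.
#' @return an object of class `outcome_cause_map`.
#' @export
outcome_cause_map <- function(points) {
  if (is.list(points)) points <- do.call(rbind, points)
  if (!is.matrix(points) || ncol(points) != 6L || any(!is.finite(points)))
    stop_invalid("'points' must be a finite matrix with 6 columns")
  structure(list(points = points, n = nrow(points)),
            class = "outcome_cause_map")
}

#' Bayesian-model-average cause prior
#'
#' Descending prediction for the continuous level: the expectation of
#' the mapped cause points under the predicted outcome distribution,
#' \eqn{\eta_v = \sum_i o_i \eta_i}.
#'
#' @param map an [outcome_cause_map()].
#' @param o_prior predicted outcome probabilities (one per mapped
#'   point); must be normalized.
#' @param model a [continuous_model()] supplying the shared cause
#'   precision.
#' @return a [cause_prior()] at the averaged expectation.
#' @export
bma_cause_prior <- function(map, o_prior, model) {
  o_prior <- check_numeric_vec(o_prior, "o_prior", map$n)
  if (abs(sum(o_prior) - 1) > 1e-8)
    stop_invalid("'o_prior' must sum to one")
  eta <- as.numeric(crossprod(map$points, o_prior))
  cause_prior(model, eta)
}

#' Bayesian model reduction for a swapped Gaussian prior mean
#'
#' Closed-form difference in log evidence when the full prior mean
#' \eqn{\eta} is replaced by a reduced mean \eqn{\eta_r} at the same
#' prior precision \eqn{P}, given the full posterior \eqn{N(m, Q^{-1})}:
#' \deqn{\Delta L = \tfrac12\,(\eta^\top P \eta - \eta_r^\top P \eta_r
#'   + m_r^\top Q m_r - m^\top Q m), \quad
#'   m_r = m + Q^{-1} P (\eta_r - \eta).}
#'
#' @param posterior list with `mean` and `precision` of the posterior
#'   over the causes (from the continuous filter).
#' @param prior list with `mean` and `precision` of the full prior.
#' @param reduced_mean the candidate prior mean.
#' @return scalar log-evidence difference (reduced minus full).
#' @export
reduced_log_evidence <- function(posterior, prior, reduced_mean) {
  m <- posterior$mean; Q <- posterior$precision
  eta <- prior$mean; P <- prior$precision
  reduced_mean <- check_numeric_vec(reduced_mean, "reduced_mean", length(eta))
  if (length(m) != length(eta))
    stop_invalid("posterior and prior dimensions do not match")
  if (!is.matrix(Q) || !is.matrix(P) || any(dim(Q) != dim(P)))
    stop_invalid("posterior and prior precisions do not match: ",
                 "Bayesian model reduction requires a shared precision family")
  mr <- m + solve(Q, P %*% (reduced_mean - eta))
  0.5 * as.numeric(
    crossprod(eta, P %*% eta) - crossprod(reduced_mean, P %*% reduced_mean) +
      crossprod(mr, Q %*% mr) - crossprod(m, Q %*% m))
}

#' Posterior over discrete outcomes from accumulated evidence
#'
#' \eqn{r = \sigma(\ln o + L)}: the outcome prior combined with the log
#' evidence accumulated over a categorical epoch, log-floored at
#' `exp(-16)`.
#'
#' @param o_prior normalized predicted outcome distribution.
#' @param L numeric vector of accumulated log evidences.
#' @return normalized posterior outcome distribution.
#' @export
outcome_posterior <- function(o_prior, L) {
  if (abs(sum(o_prior) - 1) > 1e-8)
    stop_invalid("'o_prior' must sum to one")
  if (length(L) != length(o_prior))
    stop_invalid("'L' and 'o_prior' must have the same length")
  softmax(log_floor(o_prior) + L)
}
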