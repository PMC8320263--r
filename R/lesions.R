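## Named, reproducible computational lesions.  Each lesion perturbs the
## generative model only -- the plant ("the world") is never changed, so
## every lesion is a model-world mismatch.

lesion_names <- c("none", "pi_overestimate", "lambda_overestimate",
                  "gamma_attenuate", "A_attenuate")

#' Construct a lesion specification
#'
#' The four computational lesions and their knobs:
#' * `pi_overestimate`: adds `magnitude` (log-precision units, in
#'   \[-4, 4\]) to the proprioceptive sensory log precision of the
#'   model; the corticospinal failure of sensory attenuation.
#' * `lambda_overestimate`: multiplies the model's smoothness
#'   \eqn{\lambda} by `magnitude` (in \[1, 4\]); the cerebellar
#'   mis-estimation of temporal precision.
#' * `gamma_attenuate`: multiplies the level-1 policy precision
#'   \eqn{\gamma} by `magnitude` (in (0, 1\]); the parkinsonian loss of
#'   confidence in policy selection.
#' * `A_attenuate`: applies temperature `magnitude` (in (0, 1\]) to the
#'   columns of the hierarchical likelihood \eqn{A^{(2)}} (elementwise
#'   power, renormalized); the executive disconnection between levels.
#'
#' @param name one of `"none"`, `"pi_overestimate"`,
#'   `"lambda_overestimate"`, `"gamma_attenuate"`, `"A_attenuate"`.
#' @param magnitude scalar lesion knob (see above; ignored for
#'   `"none"`). Defaults: +2 log units, x2, x0.25, 0.25.
#' @param scope for `pi_overestimate`, which proprioceptive modalities
#'   receive the precision shift; default the Ia (velocity) afferents
#'   that mediate the tendon jerk.
#' @return an object of class `lesion_spec`.
#' @export
lesion_spec <- function(name = "none", magnitude = NULL,
                        scope = "proprio_vel") {
  name <- match.arg(name, lesion_names)
  if (is.null(magnitude))
    magnitude <- switch(name, none = NA_real_, pi_overestimate = 2,
                        lambda_overestimate = 2, gamma_attenuate = 0.25,
                        A_attenuate = 0.5)
  if (name != "none") {
    lims <- switch(name,
                   pi_overestimate = c(-4, 4),
                   lambda_overestimate = c(1, 4),
                   gamma_attenuate = c(1e-6, 1),
                   A_attenuate = c(1e-6, 1))
    if (!is.numeric(magnitude) || length(magnitude) != 1L ||
        !is.finite(magnitude) || magnitude < lims[1] || magnitude > lims[2])
      stop_invalid(sprintf(
        "lesion '%s' magnitude %s is outside its bounds [%g, %g]",
        name, format(magnitude), lims[1], lims[2]))
    bad <- setdiff(scope, c("proprio_pos", "proprio_vel"))
    if (length(bad))
      stop_invalid("unknown lesion scope: ", paste(bad, collapse = ", "))
  }
  structure(list(name = name, magnitude = magnitude, scope = scope),
            class = "lesion_spec")
}

#' @export
print.lesion_spec <- function(x, ...) {
  cat(sprintf("<lesion_spec> %s%s\n", x$name,
              if (x$name == "none") "" else
                sprintf(" (magnitude %g)", x$magnitude)))
  invisible(x)
}

#' Apply a lesion to a run configuration
#'
#' Returns a new configuration with the perturbation applied to the
#' generative-model parameters; the input configuration and all
#' plant-side ("world") parameters are untouched.
#'
#' @param config a [default_config()]-style configuration list.
#' @param lesion a [lesion_spec()].
#' @return the perturbed configuration (the input is not modified).
#' @export
apply_lesion <- function(config, lesion) {
  if (!inherits(lesion, "lesion_spec"))
    lesion <- do.call(lesion_spec, as.list(lesion))
  out <- config
  out$lesion <- list(name = lesion$name, magnitude = lesion$magnitude,
                     scope = lesion$scope)
  switch(lesion$name,
         none = NULL,
         pi_overestimate = {
           for (ch in lesion$scope)
             out$precisions$sensory_logprec[[ch]] <-
               out$precisions$sensory_logprec[[ch]] + lesion$magnitude
         },
         lambda_overestimate = {
           out$precisions$lam_model <-
             out$precisions$lam_model * lesion$magnitude
         },
         gamma_attenuate = {
           out$task$gamma <- out$task$gamma * lesion$magnitude
         },
         A_attenuate = {
           out$task$a_temperature <-
             out$task$a_temperature * lesion$magnitude
         })
  out
}
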