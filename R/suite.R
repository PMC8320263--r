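## Orchestration: run both exams across a set of lesion conditions,
## write per-condition outputs and a cross-condition summary table.

#' Run the full examination suite
#'
#' Runs the tendon-tap and coordination exams for each condition at a
#' shared seed.  The healthy (`none`) condition is always run first and
#' serves as the reference path for `post_switch_deviation`.  Failures
#' in one condition are recorded and the remaining conditions still
#' run.
#'
#' @param config a [default_config()]-style configuration.
#' @param conditions list of [lesion_spec()]s; defaults to the healthy
#'   model plus the four canonical lesions at their default magnitudes.
#' @param exams character vector: which exams to run.
#' @param out_dir optional output directory; when given, per-condition
#'   trajectories/metrics and a `summary.csv` are written there.
#' @param quiet suppress per-stage progress messages.
#' @return (invisibly for written runs) a list with `summary` (one row
#'   per condition x exam x metric), `results` (the `exam_result`
#'   objects, keyed `<exam>.<condition>`), and `failures`.
#' @export
run_exam_suite <- function(config = default_config(),
                           conditions = default_conditions(),
                           exams = c("tendon_tap", "coordination"),
                           out_dir = NULL, quiet = FALSE) {
  exams <- match.arg(exams, c("tendon_tap", "coordination"),
                     several.ok = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  ## healthy reference first
  names(conditions) <- vapply(conditions, function(l) l$name, character(1))
  ord <- order(names(conditions) != "none")
  conditions <- conditions[ord]
  results <- list()
  failures <- character(0)
  rows <- list()
  reference <- NULL
  for (les in conditions) {
    for (exam in exams) {
      key <- paste(exam, les$name, sep = ".")
      t0 <- Sys.time()
      res <- tryCatch({
        if (exam == "tendon_tap") tendon_tap_exam(config, les)
        else coordination_exam(config, les, reference = reference)
      }, error = function(e) conditionMessage(e))
      if (is.character(res)) {
        failures <- c(failures, stats::setNames(res, key))
        say("%-28s FAILED: %s", key, res)
        next
      }
      say("%-28s done in %.1f s (final F = %.1f)", key,
          as.numeric(difftime(Sys.time(), t0, units = "secs")),
          utils::tail(res$trajectory$free_energy, 1))
      results[[key]] <- res
      if (exam == "coordination" && les$name == "none") reference <- res
      rows[[key]] <- summarize_metrics(res)
      if (!is.null(out_dir)) write_exam_result(res, out_dir)
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  if (!is.null(out_dir)) {
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
  }
  out <- list(summary = summary, results = results, failures = failures)
  class(out) <- "exam_suite"
  if (is.null(out_dir)) out else invisible(out)
}

#' @export
print.exam_suite <- function(x, ...) {
  cat(sprintf("<exam_suite> %d results, %d failures\n",
              length(x$results), length(x$failures)))
  print(utils::head(x$summary, 20), digits = 3)
  invisible(x)
}

#' Default suite conditions: healthy plus the four canonical lesions
#' @return list of [lesion_spec()]s.
#' @export
default_conditions <- function() {
  list(lesion_spec("none"),
       lesion_spec("pi_overestimate"),
       lesion_spec("lambda_overestimate"),
       lesion_spec("gamma_attenuate"),
       lesion_spec("A_attenuate"))
}

## long-format metric rows for the summary table
summarize_metrics <- function(res) {
  if (inherits(res$metrics, "reflex_metrics")) {
    m <- res$metrics
    data.frame(exam = res$exam, condition = res$condition,
               segment = NA_integer_,
               metric = c("peak_amplitude", "time_to_peak",
                          "zero_crossings", "settle_time"),
               value = c(m$peak_amplitude, m$time_to_peak,
                         m$zero_crossings, m$settle_time))
  } else {
    m <- res$metrics
    metric_cols <- setdiff(names(m), "segment")
    do.call(rbind, lapply(metric_cols, function(nm)
      data.frame(exam = res$exam, condition = res$condition,
                 segment = m$segment, metric = nm, value = m[[nm]])))
  }
}

#' Plot an exam result
#'
#' Base-graphics summary: joint angles against time (with segment
#' boundaries for the coordination exam) and, for coordination, the
#' hand path in the y-z plane with the ring of attracting points.
#' Optional output only; not part of any tested contract.
#'
#' @param x an `exam_result`.
#' @param ... unused.
#' @return `x`, invisibly.
#' @export
plot.exam_result <- function(x, ...) {
  tr <- x$trajectory
  op <- graphics::par(mfrow = if (x$exam == "coordination") c(2, 1)
                      else c(1, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(tr$time,
                    cbind(tr$shoulder_rotation, tr$shoulder_flexion,
                          tr$elbow_angle),
                    type = "l", lty = 1, xlab = "time (s)",
                    ylab = "joint angle (rad)",
                    main = sprintf("%s exam (%s)", x$exam, x$condition))
  graphics::legend("topright", c("shoulder rot", "shoulder flex", "elbow"),
                   col = 1:3, lty = 1, cex = 0.7, bty = "n")
  if (x$exam == "coordination") {
    bounds <- tr$time[c(which(diff(tr$segment) != 0), nrow(tr))]
    graphics::abline(v = bounds, col = "grey70", lty = 3)
    graphics::plot(tr$hand_y, tr$hand_z, type = "l", asp = 1,
                   xlab = "y (m)", ylab = "z (m)", main = "hand path")
    if (!is.null(x$extras))
      graphics::points(x$extras$targets[, 2], x$extras$targets[, 3],
                       pch = 19, col = "red")
  }
  invisible(x)
}
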