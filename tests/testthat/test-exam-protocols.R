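test_that("reflex metrics recover the analytic features of a damped sinusoid", {
  # synthetic elbow angle: baseline 1 rad, then e^{-t} sin(2 pi t)
  dt <- 1 / 128
  t <- seq(0, 4 - dt, by = dt)
  onset <- 1
  sig <- ifelse(t < onset, 0, exp(-(t - onset)) * sin(2 * pi * (t - onset)))
  traj <- data.frame(time = t, elbow_angle = 1 + sig,
                     elbow_velocity = c(0, diff(sig) / dt))
  m <- compute_reflex_metrics(traj, tap_onset = onset)

  # independent oracle for the peak: maximize |e^{-u} sin(2 pi u)|
  peak_t <- stats::optimize(function(u) exp(-u) * sin(2 * pi * u),
                            c(0, 0.5), maximum = TRUE)
  expect_equal(m$time_to_peak, peak_t$maximum, tolerance = 2 * dt)
  expect_equal(m$peak_amplitude, peak_t$objective, tolerance = 1e-2)

  # extrema of the signal in (0, 2]: derivative changes sign at
  # tan(2 pi u) = 2 pi, i.e. 4 times in 2 s
  expect_equal(m$zero_crossings, 4L)
  expect_equal(m$baseline, 1, tolerance = 1e-12)

  # constant trajectory: everything zero
  flat <- data.frame(time = t, elbow_angle = rep(0.7, length(t)),
                     elbow_velocity = rep(0, length(t)))
  mf <- compute_reflex_metrics(flat, tap_onset = onset)
  expect_equal(mf$peak_amplitude, 0)
  expect_equal(mf$zero_crossings, 0L)
  expect_equal(mf$settle_time, 0)

  # invariance to a constant offset of the angle channel
  traj2 <- traj; traj2$elbow_angle <- traj2$elbow_angle + 0.5
  m2 <- compute_reflex_metrics(traj2, tap_onset = onset)
  expect_equal(m2$peak_amplitude, m$peak_amplitude)
  expect_equal(m2$zero_crossings, m$zero_crossings)

  # insufficient coverage is a contract error
  expect_error(compute_reflex_metrics(traj[t < 2, ], tap_onset = onset),
               "must cover")
})

test_that("reach metrics recover constructed path features", {
  dt <- 1 / 128
  t <- seq(0, 2 - dt, by = dt)
  target <- c(0.1, 0, 0)

  # straight-line constant-speed approach: monotone, no overshoot
  lam <- pmin(1, t / 1.5)
  path <- cbind(lam * target[1], 0, 0)
  traj <- data.frame(time = t, hand_x = path[, 1], hand_y = path[, 2],
                     hand_z = path[, 3], segment = 1L)
  m <- compute_reach_metrics(traj, rbind(target), epsilon = 0.005)
  expect_equal(m$monotone_fraction, 1)
  expect_equal(m$overshoot, 0)
  expect_equal(m$endpoint_error, 0, tolerance = 1e-12)
  expect_equal(m$segment_amplitude, 0.1, tolerance = 1e-12)
  # 10% of the commanded displacement is covered at t = 0.15
  expect_lt(abs(m$onset_latency - 0.15), 2 * dt)

  # path passing 0.1 beyond the target and returning: overshoot = 0.1
  x <- 0.1 + 0.1 * sin(pmin(pi, t * pi))  # rises to 0.2, returns to 0.1
  traj2 <- data.frame(time = t, hand_x = x, hand_y = 0, hand_z = 0,
                      segment = 1L)
  traj2$hand_x[1] <- 0   # start at the origin so approach direction is +x
  m2 <- compute_reach_metrics(traj2, rbind(target), epsilon = 0.005)
  expect_equal(m2$overshoot, 0.1, tolerance = 1e-6)

  # oscillating approach: d(t) = 0.3 e^{-t} (1 + 0.5 cos 10 t); the
  # number of sign changes of d'(t) from a symbolic-derivative oracle
  d <- 0.3 * exp(-t) * (1 + 0.5 * cos(10 * t))
  traj3 <- data.frame(time = t, hand_x = target[1] + d, hand_y = 0,
                      hand_z = 0, segment = 1L)
  m3 <- compute_reach_metrics(traj3, rbind(target), epsilon = 1e-4)
  dexpr <- stats::D(quote(0.3 * exp(-t) * (1 + 0.5 * cos(10 * t))), "t")
  dprime <- eval(dexpr, list(t = t))
  oracle_zc <- sum(diff(sign(dprime[abs(dprime) > 1e-5])) != 0)
  expect_equal(m3$path_zero_crossings, oracle_zc)

  # reference comparison and its contract
  ref <- traj
  traj4 <- traj; traj4$hand_y <- traj4$hand_y + 0.02
  m4 <- compute_reach_metrics(traj4, rbind(target), epsilon = 0.005,
                              reference = ref)
  expect_equal(m4$post_switch_deviation, 0.02, tolerance = 1e-9)
  expect_error(compute_reach_metrics(traj4, rbind(target), 0.005,
                                     reference = ref[1:10, ]),
               "does not match")
  expect_error(compute_reach_metrics(traj, rbind(target, target), 0.005),
               "do not tile")
})

test_that("the tendon-tap exam is deterministic and self-consistent", {
  cfg <- default_config()
  r1 <- tendon_tap_exam(cfg)
  r2 <- tendon_tap_exam(cfg)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(unclass(r1$metrics), unclass(r2$metrics))

  # metrics are recomputable from the stored trajectory
  m <- compute_reflex_metrics(r1$trajectory, tap_onset = cfg$exam$tap$onset)
  expect_equal(unclass(m), unclass(r1$metrics))

  # zero-amplitude tap produces no response above the noise floor
  cfg0 <- cfg
  cfg0$exam$tap$amplitude <- 0
  r0 <- tendon_tap_exam(cfg0)
  expect_lt(r0$metrics$peak_amplitude, 3 * r0$metrics$baseline_jitter + 1e-4)
})

test_that("exam results serialize to CSV + JSON and survive a round trip", {
  cfg <- default_config()
  res <- tendon_tap_exam(cfg)
  dir <- withr::local_tempdir()
  paths <- write_exam_result(res, dir)
  expect_true(all(file.exists(paths)))
  expect_match(basename(paths["trajectory"]), "none")
  back <- utils::read.csv(paths[["trajectory"]])
  m <- compute_reflex_metrics(back, tap_onset = cfg$exam$tap$onset)
  expect_equal(m$peak_amplitude, res$metrics$peak_amplitude,
               tolerance = 1e-9)
  meta <- jsonlite::read_json(paths[["metrics"]])
  expect_equal(meta$condition, "none")
  expect_equal(meta$metrics$peak_amplitude, res$metrics$peak_amplitude,
               tolerance = 1e-9)
})

test_that("the suite runs conditions, labels outputs and summarizes", {
  cfg <- default_config()
  dir <- withr::local_tempdir()
  suite <- run_exam_suite(
    cfg, conditions = list(lesion_spec("none"),
                           lesion_spec("pi_overestimate")),
    exams = "tendon_tap", out_dir = dir, quiet = TRUE)
  expect_length(suite$results, 2)
  expect_length(suite$failures, 0)
  expect_true(file.exists(file.path(dir, "summary.csv")))
  expect_true(file.exists(file.path(dir,
                                    "tendon_tap_pi_overestimate_metrics.json")))
  expect_setequal(unique(suite$summary$condition),
                  c("none", "pi_overestimate"))
  expect_true("peak_amplitude" %in% suite$summary$metric)
})
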