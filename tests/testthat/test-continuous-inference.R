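ts <- test_setup()

consistent_state <- function(ts) {
  # belief, data and prior all exactly consistent at a fixed point:
  # hand at the attractor, zero velocities, colours zero
  v0 <- c(ts$hand0, 0, 0, 0)
  bel <- generalized_belief(ts$m, x0 = ts$x0, v0 = v0)
  y <- cbind(sensory_map(ts$x0, v0, ts$geom),
             matrix(0, 12, ts$m$n_v - 1))
  prior <- cause_prior(ts$m, v0)
  list(belief = bel, y = y, prior = prior)
}

test_that("prediction errors vanish at a consistent fixed point", {
  cs <- consistent_state(ts)
  err <- prediction_errors(cs$belief, cs$y, cs$prior, ts$m)
  expect_lt(max(abs(err$e_y)), 1e-12)
  expect_lt(max(abs(err$e_x)), 1e-12)
  expect_lt(max(abs(err$e_v)), 1e-12)

  # a perturbation on one Ia channel appears only in that channel block
  y2 <- cs$y
  y2[5, 1] <- y2[5, 1] + 0.3
  err2 <- prediction_errors(cs$belief, y2, cs$prior, ts$m)
  nz <- which(abs(err2$e_y) > 1e-12)
  expect_equal(nz, ts$m$iy(5L, 0L))
  expect_lt(max(abs(err2$e_x)), 1e-12)
})

test_that("free energy is the precision-weighted quadratic form", {
  cs <- consistent_state(ts)
  err0 <- prediction_errors(cs$belief, cs$y, cs$prior, ts$m)
  f0 <- free_energy(err0)   # log-determinant constant only

  # single scalar sensory error contributes 1/2 * weighted square
  y2 <- cs$y
  delta <- 0.25
  y2[2, 1] <- y2[2, 1] + delta
  err <- prediction_errors(cs$belief, y2, cs$prior, ts$m)
  w <- err$L_y[ts$m$iy(2L, 0L), ts$m$iy(2L, 0L)]
  expect_equal(free_energy(err) - f0, 0.5 * w * delta^2, tolerance = 1e-10)

  # composite random instance matches the dense quadratic form
  inst <- random_instance(ts, seed = 3)
  err3 <- prediction_errors(inst$belief, inst$y, inst$prior, ts$m)
  brute <- 0.5 * (as.numeric(t(err3$e_y) %*% err3$L_y %*% err3$e_y) +
                    as.numeric(t(err3$e_x) %*% err3$L_x %*% err3$e_x) +
                    as.numeric(t(err3$e_v) %*% err3$L_v %*% err3$e_v))
  expect_equal(free_energy(err3) - f0, brute, tolerance = 1e-8)
})

test_that("free-energy gradient matches finite differences", {
  for (seed in 1:3) {
    inst <- random_instance(ts, seed = seed)
    err <- prediction_errors(inst$belief, inst$y, inst$prior, ts$m)
    g <- kinesia:::free_energy_gradient(err)
    mu <- c(kinesia:::vec_cm(inst$belief$mu_x),
            kinesia:::vec_cm(inst$belief$mu_v))
    nx6 <- 6L * ts$m$n_x
    fmu <- function(v) {
      b <- inst$belief
      b$mu_x <- kinesia:::unvec_cm(v[1:nx6], 6L, ts$m$n_x)
      b$mu_v <- kinesia:::unvec_cm(v[(nx6 + 1):length(v)], 6L, ts$m$n_v)
      free_energy(prediction_errors(b, inst$y, inst$prior, ts$m))
    }
    gfd <- vapply(seq_along(mu), function(j) {
      e <- rep(0, length(mu)); e[j] <- 1e-6
      (fmu(mu + e) - fmu(mu - e)) / 2e-6
    }, numeric(1))
    expect_equal(g, gfd, tolerance = 1e-5)
  }
})

test_that("filtering leaves a consistent fixed point unchanged", {
  cs <- consistent_state(ts)
  bel <- cs$belief
  for (i in 1:16) bel <- filtering_step(bel, cs$y, cs$prior, ts$m, ts$dt)
  expect_lt(max(abs(bel$mu_x - cs$belief$mu_x)), 16 * 1e-8)
  expect_lt(max(abs(bel$mu_v - cs$belief$mu_v)), 16 * 1e-8)
})

test_that("free energy decreases on static data after a transient", {
  cs <- consistent_state(ts)
  bel <- cs$belief
  bel$mu_x[, 1] <- bel$mu_x[, 1] + c(0.05, -0.04, 0.06, 0, 0, 0)
  for (i in 1:80) bel <- filtering_step(bel, cs$y, cs$prior, ts$m, ts$dt)
  tr <- bel$free_energy_trace
  expect_true(all(diff(tr[10:80]) <= 1e-6))
  expect_lt(tr[80], tr[1])
})

test_that("filtering reaches the fixed point after a prior step", {
  # displace the attractor prior; the belief's predicted hand position
  # should converge toward the new attractor
  cs <- consistent_state(ts)
  target <- ts$hand0 + c(0, 0.05, 0.04)
  prior2 <- cause_prior(ts$m, c(target, 0, 0, 0))
  bel <- cs$belief
  for (i in 1:(3 * 128)) bel <- filtering_step(bel, cs$y, prior2, ts$m, ts$dt)
  pred_hand <- forward_kinematics(ts$geom, bel$mu_x[1:3, 1])
  d0 <- sqrt(sum((ts$hand0 - target)^2))
  d1 <- sqrt(sum((pred_hand - target)^2))
  # with static (conflicting) data the asymptote is a precision-weighted
  # compromise between the attractor and the sensed posture; the belief
  # must move substantially toward the attractor
  expect_lt(d1, 0.8 * d0)
})

test_that("filtering reports divergence with a diagnostic", {
  m2 <- continuous_model(ts$geom, ts$p, n_v = ts$m$n_v,
                         divergence_bound = 1e-3)
  inst <- random_instance(ts, seed = 2)
  expect_error(filtering_step(inst$belief, inst$y, inst$prior, m2, ts$dt),
               "numerical instability in filtering_step")
})

test_that("action update has reflex-arc structure", {
  cs <- consistent_state(ts)
  err0 <- prediction_errors(cs$belief, cs$y, cs$prior, ts$m)
  a <- c(0.1, -0.2, 0.05)
  m_noleak <- continuous_model(ts$geom, ts$p, n_v = ts$m$n_v,
                               action_gain = ts$m$action_gain,
                               action_decay = 0)
  # zero errors leave the action unchanged (without the leak)
  expect_equal(action_step(a, err0, m_noleak, ts$dt), a)

  # positive Ia error at the elbow only: elbow torque moves opposite to
  # the error, other joints unchanged
  y2 <- cs$y
  y2[6, 1] <- y2[6, 1] + 0.5
  err <- prediction_errors(cs$belief, y2, cs$prior, ts$m)
  a2 <- action_step(c(0, 0, 0), err, m_noleak, ts$dt)
  expect_lt(a2[3], 0)
  expect_equal(a2[1:2], c(0, 0))

  # visual errors never drive action
  y3 <- cs$y
  y3[8, 1] <- y3[8, 1] + 0.5
  err3 <- prediction_errors(cs$belief, y3, cs$prior, ts$m)
  expect_equal(action_step(c(0, 0, 0), err3, m_noleak, ts$dt), c(0, 0, 0))
})

test_that("healthy closed loop holds posture within 1e-3 rad for 5 s", {
  n <- 5 * 128
  plant <- make_arm_plant(ts$geom, ts$p, ts$x0, n, ts$dt, seed = 11,
                          n_orders = ts$m$n_v)
  bel <- generalized_belief(ts$m, x0 = ts$x0, v0 = c(ts$hand0, 0, 0, 0))
  prior <- cause_prior(ts$m, c(ts$hand0, 0, 0, 0))
  ep <- run_epoch(ts$m, bel, prior, plant, 5, ts$dt)
  hand_drift <- max(sqrt(rowSums(sweep(ep$hand, 2, ts$hand0)^2)))
  joint_drift <- max(abs(sweep(ep$states[, 1:3], 2, ts$q0)))
  expect_lt(hand_drift, 1e-3)
  expect_lt(joint_drift, 2e-3)
})

test_that("epoch evidence favours the generating hypothesis", {
  # candidate equal to the full prior accumulates exactly zero evidence
  prior <- cause_prior(ts$m, c(ts$hand0, 0, 0, 0))
  plant <- make_arm_plant(ts$geom, ts$p, ts$x0, 64, ts$dt, seed = 4,
                          n_orders = ts$m$n_v)
  bel <- generalized_belief(ts$m, x0 = ts$x0, v0 = c(ts$hand0, 0, 0, 0))
  ep <- run_epoch(ts$m, bel, prior, plant, 0.5, ts$dt,
                  candidates = list(c(ts$hand0, 0, 0, 0)))
  expect_equal(ep$L, 0, tolerance = 1e-10)

  # two candidates: drive the loop toward candidate 1; its evidence wins
  p1 <- ts$hand0 + c(0, 0.06, 0.05)
  p2 <- ts$hand0 - c(0, 0.06, 0.05)
  prior1 <- cause_prior(ts$m, c(p1, 0, 0, 0))
  plant2 <- make_arm_plant(ts$geom, ts$p, ts$x0, 256, ts$dt, seed = 4,
                           n_orders = ts$m$n_v)
  bel2 <- generalized_belief(ts$m, x0 = ts$x0, v0 = c(ts$hand0, 0, 0, 0))
  ep2 <- run_epoch(ts$m, bel2, prior1, plant2, 2, ts$dt,
                   candidates = list(c(p1, 0, 0, 0), c(p2, 0, 0, 0)))
  expect_gt(ep2$L[1], ep2$L[2])
})

test_that("proprioceptive precision scales the tap response monotonically", {
  # sensory-attenuation property: +2 log units increases the peak
  # response, -2 decreases it, monotonically across the three levels
  peaks <- vapply(c(-2, 0, 2), function(shift) {
    cfg <- ts$cfg
    les <- if (shift == 0) lesion_spec("none") else
      lesion_spec("pi_overestimate", shift)
    tendon_tap_exam(cfg, les)$metrics$peak_amplitude
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
})
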