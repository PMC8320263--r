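# Shared fixtures: a small continuous model at the package defaults and
# a resting posture used across the continuous-inference tests.

test_setup <- function(...) {
  cfg <- default_config()
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- utils::modifyList(cfg[[nm]], dots[[nm]])
  geom <- kinesia:::config_geometry(cfg)
  p <- kinesia:::config_params(cfg)
  m <- kinesia:::config_cmodel(cfg)
  q0 <- cfg$exam$rest_angles
  x0 <- c(q0, 0, 0, 0)
  hand0 <- forward_kinematics(geom, q0)
  list(cfg = cfg, geom = geom, p = p, m = m, q0 = q0, x0 = x0,
       hand0 = hand0, dt = cfg$numerics$dt)
}

# random but consistent belief/data instance for gradient-style checks
random_instance <- function(ts, seed = 1) {
  set.seed(seed)
  bel <- generalized_belief(ts$m, x0 = ts$x0, v0 = c(ts$hand0, 0, 0, 0))
  bel$mu_x <- bel$mu_x + matrix(rnorm(length(bel$mu_x), 0, 0.1),
                                nrow(bel$mu_x))
  bel$mu_v <- bel$mu_v + matrix(rnorm(length(bel$mu_v), 0, 0.1),
                                nrow(bel$mu_v))
  y <- cbind(sensory_map(ts$x0, c(ts$hand0, 0, 0, 0), ts$geom) +
               rnorm(12, 0, 0.05),
             matrix(rnorm(12 * (ts$m$n_v - 1), 0, 0.1), 12))
  prior <- cause_prior(ts$m, c(ts$hand0, 0, 0, 0) + rnorm(6, 0, 0.02))
  list(belief = bel, y = y, prior = prior)
}
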