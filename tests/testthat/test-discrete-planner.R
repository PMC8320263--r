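verts <- rbind(c(0.32, -0.18, 1.30), c(0.32, 0, 1.58), c(0.32, 0.18, 1.30))
task <- build_task_models(verts)

test_that("task models have the printed state-space structure", {
  # level 2: 9 trajectory states (3 start x 3 end vertices, including
  # the 3 static ones) and 3 target states
  expect_length(task$level2$D$trajectory, 9)
  expect_equal(dim(task$level2$B$trajectory), c(9L, 9L))
  expect_length(task$level2$D$target, 3)
  expect_equal(sum(task$traj_start == task$traj_end), 3)

  # level 1: 6 attracting points x 3 targets, 3 policies
  expect_length(task$level1$D$location, 6)
  expect_length(task$level1$D$target, 3)
  expect_equal(nrow(task$level1$policies), 3L)

  # every generated probability column is normalized
  for (M in c(task$level1$A, task$level1$B, task$level2$B, task$link))
    expect_equal(colSums(M), rep(1, ncol(M)), tolerance = 1e-12)
  expect_equal(sum(task$level2$D$trajectory), 1)

  # D^(2): uniform over targets, trajectories start at the right vertex
  expect_equal(task$level2$D$target, rep(1 / 3, 3))
  expect_equal(task$level2$D$trajectory[task$traj_start == 1L], rep(1 / 3, 3))

  # level-1 target transitions are the identity under every action
  # (the target is static at this timescale; only location moves)
  loc <- c(1, rep(0, 5))
  expect_equal(as.numeric(task$level1$B$static %*% loc), loc)

  # cyclic structure: six clockwise steps return to the start
  P <- diag(6)
  for (i in 1:6) P <- task$level1$B$cw %*% P
  expect_equal(P, diag(6))

  # ring geometry: vertices interleaved with edge midpoints
  expect_equal(task$ring[task$vertex_ring, ], verts)
  expect_equal(task$ring[2, ], (verts[1, ] + verts[2, ]) / 2)
})

test_that("expected free energy reduces to entropy arithmetic on edge cases", {
  # predicted outcome equal to a deterministic preference: G = 0
  toy <- task
  toy$level1 <- task$level1
  # put the attracting point at the target vertex with certainty and a
  # huge preference: risk at every remaining step is then ~0 for static
  toy2 <- build_task_models(verts, preference = 50)
  loc <- rep(0, 6); loc[toy2$vertex_ring[2]] <- 1
  targ <- c(0, 1, 0)
  g_static <- expected_free_energy(toy2, 3, loc, targ, current_step = 1L)
  # the only residual is the uniform-preference location/colour terms
  per_step <- log(6) + log(3)
  expect_equal(g_static, (toy2$level1$T - 1) * per_step, tolerance = 1e-4)

  # uniform predictions with flat preferences: per-step G = ln K for
  # the location modality exactly cancels ... i.e. KL(uniform||uniform)=0
  loc_u <- rep(1 / 6, 6); targ_u <- rep(1 / 3, 3)
  g_u <- expected_free_energy(toy2, 3, loc_u, targ_u,
                              current_step = toy2$level1$T - 1L)
  # location and colour risks vanish; only the correct/incorrect risk
  # remains: KL((1/6, 5/6) || softmax(C))
  pc <- 1 / 6
  pref <- kinesia:::softmax(c(50, 0))
  kl <- pc * (log(pc) - log(pref[1])) +
    (1 - pc) * (log(1 - pc) - log(max(pref[2], exp(-16))))
  expect_equal(g_u, kl, tolerance = 1e-6)

  # brute-force oracle: exhaustive evaluation of the risk sum for a
  # generic posterior and every policy
  set.seed(5)
  loc_r <- kinesia:::normalize(runif(6))
  targ_r <- kinesia:::normalize(runif(3))
  for (p in 1:3) {
    got <- expected_free_energy(task, p, loc_r, targ_r, current_step = 2L)
    # independent re-computation with explicit loops
    lev <- task$level1
    pref <- lapply(lev$C, kinesia:::softmax)
    loc <- loc_r
    G <- 0
    for (tau in 3:lev$T) {
      loc <- as.numeric(lev$B[[lev$policies[p, tau - 1]]] %*% loc)
      o_cor <- 0
      for (k in 1:3) o_cor <- o_cor + targ_r[k] * loc[task$vertex_ring[k]]
      kl2 <- function(pp, qq) sum(pp * (log(pmax(pp, exp(-16))) -
                                          log(pmax(qq, exp(-16)))))
      G <- G + kl2(loc, pref$location) + kl2(targ_r, pref$colour) +
        kl2(c(o_cor, 1 - o_cor), pref$correct)
    }
    expect_equal(got, G, tolerance = 1e-12)
  }
})

test_that("policy posterior follows the softmax of prior, evidence and risk", {
  # uniform everything gives a uniform posterior
  expect_equal(policy_posterior(rep(1, 3), rep(0.5, 3), rep(2, 3), 1),
               rep(1 / 3, 3))

  # worked arithmetic case
  pi <- policy_posterior(c(0.5, 0.25, 0.25), rep(0, 3), c(1, 2, 3), 1)
  expect_equal(pi, c(0.7992, 0.1470, 0.0541), tolerance = 1e-3)

  # gamma = 0 removes any dependence on G exactly
  set.seed(2)
  for (i in 1:10) {
    E <- kinesia:::normalize(runif(3)); F <- rnorm(3)
    expect_equal(policy_posterior(E, F, runif(3, 0, 10), 0),
                 policy_posterior(E, F, runif(3, 0, 10), 0))
  }

  # gamma-monotonicity: weight on the argmin-G policy strictly grows
  G <- c(1, 2.5, 3)
  w <- vapply(c(0.25, 0.5, 1, 2, 4), function(g)
    policy_posterior(rep(1, 3), rep(0, 3), G, g)[1], numeric(1))
  expect_true(all(diff(w) > 0))
})

test_that("state posterior matches exhaustive enumeration", {
  D1 <- list(location = kinesia:::normalize(c(4, 1, 1, 1, 2, 1)),
             target = c(0.5, 0.3, 0.2))
  set.seed(9)
  obs_loc <- t(apply(matrix(runif(12), 2), 1, kinesia:::normalize))
  obs_col <- t(apply(matrix(runif(6), 2), 1, kinesia:::normalize))
  for (p in 1:3) {
    sp <- state_posterior(task, p, D1, obs_loc, obs_col)
    # brute force over all 18 joint initial states
    shift <- c(1, -1, 0)
    w <- matrix(0, 6, 3)
    for (l in 1:6) for (k in 1:3) {
      prob <- D1$location[l] * D1$target[k]
      pos <- l
      for (tau in 1:2) {
        if (tau > 1) pos <- ((pos - 1 + shift[task$level1$policies[p, tau - 1]]) %% 6) + 1
        prob <- prob * obs_loc[tau, pos] * obs_col[tau, k]
      }
      w[l, k] <- prob
    }
    expect_equal(sp$F, -log(sum(w)), tolerance = 1e-12)
    expect_equal(sp$init_post, rowSums(w) / sum(w), tolerance = 1e-12)
    expect_equal(sp$targ_post, colSums(w) / sum(w), tolerance = 1e-12)
    expect_equal(sum(sp$init_post), 1, tolerance = 1e-10)
    for (tau in seq_len(task$level1$T))
      expect_equal(sum(sp$loc_post[tau, ]), 1, tolerance = 1e-10)
  }

  # uninformative outcomes leave the prior chain untouched
  flat_loc <- matrix(1 / 6, 1, 6); flat_col <- matrix(1 / 3, 1, 3)
  sp0 <- state_posterior(task, 3, D1, flat_loc, flat_col)
  expect_equal(sp0$init_post, D1$location, tolerance = 1e-12)
  expect_equal(sp0$targ_post, D1$target, tolerance = 1e-12)

  # impossible outcomes fall back to uniform with a warning
  zero_loc <- matrix(c(0, 0, 0, 0, 0, 1), 1)
  D_delta <- list(location = c(1, 0, 0, 0, 0, 0), target = c(1, 0, 0))
  expect_warning(state_posterior(task, 3, D_delta, zero_loc, flat_col),
                 "degenerate evidence")
})

test_that("descending context parameterizes level 1 correctly", {
  # delta posterior on trajectory right -> apex
  j <- which(task$traj_start == 1 & task$traj_end == 2)
  traj <- rep(0, 9); traj[j] <- 1
  ctx <- descending_context(task, traj, c(0, 1, 0))
  # initial location concentrates on the right vertex's ring position
  expect_equal(which.max(ctx$D1$location), task$vertex_ring[1])
  # E favours the shorter (clockwise) ring direction to the apex
  expect_equal(which.max(ctx$o_dir), 1L)
  expect_gt(ctx$E_eff[1], ctx$E_eff[2])

  # static trajectory: direction context peaks on the static policy
  j0 <- which(task$traj_start == 2 & task$traj_end == 2)
  traj0 <- rep(0, 9); traj0[j0] <- 1
  ctx0 <- descending_context(task, traj0, c(1, 0, 0))
  expect_equal(which.max(ctx0$o_dir), 3L)
  expect_equal(which.max(ctx0$E_eff), 3L)

  # uniform level-2 posterior gives the row-average of A^(2)
  ctxu <- descending_context(task, rep(1 / 9, 9), rep(1 / 3, 3))
  expect_equal(ctxu$o_start, as.numeric(task$link$start %*% rep(1 / 9, 9)))
  expect_equal(ctxu$o_start, rowMeans(task$link$start), tolerance = 1e-12)
})

test_that("ascending update is Bayes rule over trajectory states", {
  o_traj <- kinesia:::normalize(1:9)
  o_targ <- c(0.2, 0.5, 0.3)
  # uninformative likelihood terms leave the prior unchanged
  pi_u <- rep(1 / 3, 3); s_u <- rep(1 / 6, 6); st_u <- rep(1 / 3, 3)
  up <- ascending_update(task, o_traj, pi_u, s_u, o_targ, st_u)
  expect_equal(up$traj, o_traj, tolerance = 1e-10)
  expect_equal(up$target, o_targ, tolerance = 1e-10)

  # numeric case equals direct Bayes arithmetic
  pi1 <- c(0.7, 0.2, 0.1); s1 <- kinesia:::normalize(c(5, 1, 1, 1, 1, 1))
  st1 <- c(0.6, 0.3, 0.1)
  up2 <- ascending_update(task, o_traj, pi1, s1, o_targ, st1)
  E_lik <- as.numeric(crossprod(task$link$direction, pi1))
  D_lik <- as.numeric(crossprod(task$link$start, s1))
  want <- kinesia:::normalize(o_traj * E_lik * D_lik)
  expect_equal(up2$traj, want, tolerance = 1e-10)
  t_lik <- as.numeric(crossprod(task$link$target, st1))
  expect_equal(up2$target, kinesia:::normalize(o_targ * t_lik),
               tolerance = 1e-10)

  # delta-consistent likelihoods concentrate the posterior
  j <- which(task$traj_start == 1 & task$traj_end == 2)
  pi_d <- c(1, 0, 0)
  s_d <- rep(0, 6); s_d[task$vertex_ring[1]] <- 1
  up3 <- ascending_update(task, rep(1 / 9, 9), pi_d, s_d, o_targ, st1)
  expect_equal(which.max(up3$traj), j)
})

test_that("A-temperature softening flattens the hierarchical likelihood", {
  t_half <- build_task_models(verts, a_temperature = 0.5)
  t_tiny <- build_task_models(verts, a_temperature = 1e-6)
  # softened columns are flatter but keep the same argmax
  for (j in 1:9) {
    expect_equal(which.max(t_half$link$start[, j]),
                 which.max(task$link$start[, j]))
    expect_lt(max(t_half$link$start[, j]), max(task$link$start[, j]))
  }
  # temperature -> 0 limit: uniform columns
  expect_equal(t_tiny$link$start,
               matrix(1 / 6, 6, 9), tolerance = 1e-4)
})

test_that("healthy planning moves the attractor to the darkened target", {
  # with an intact model and the target known, the best policy carries
  # the attracting point from the current vertex to the target vertex
  # along the shorter ring direction
  for (case in list(c(1, 2, 1), c(1, 3, 2), c(2, 3, 1), c(3, 2, 2),
                    c(2, 2, 3))) {
    start_v <- case[1]; targ_v <- case[2]; best <- case[3]
    D1 <- list(location = replace(rep(0.01, 6), task$vertex_ring[start_v],
                                  0.95),
               target = replace(rep(0.025, 3), targ_v, 0.95))
    D1$location <- kinesia:::normalize(D1$location)
    D1$target <- kinesia:::normalize(D1$target)
    G <- vapply(1:3, function(p)
      expected_free_energy(task, p, D1$location, D1$target,
                           current_step = 0L), numeric(1))
    expect_equal(which.min(G), best)
  }
})

test_that("task arrays serialize to a structured text document", {
  path <- withr::local_tempfile(fileext = ".yaml")
  save_task_models(task, path)
  doc <- yaml::read_yaml(path)
  expect_equal(do.call(rbind, doc$link$start), unname(task$link$start),
               tolerance = 1e-12)
  expect_equal(do.call(rbind, doc$level1$B$cw), unname(task$level1$B$cw))
  expect_equal(doc$level1$T, task$level1$T)
  expect_equal(do.call(rbind, doc$ring), unname(task$ring),
               tolerance = 1e-12)
})
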