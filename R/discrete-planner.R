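## Two-level discrete active inference for the coordination task.
##
## Level 1 ("where is the attracting point"): a ring of 6 locations --
## the 3 triangle vertices interleaved with the 3 edge midpoints -- and a
## static target factor (3 states).  Three policies move the attracting
## point clockwise, anticlockwise, or not at all; each policy is a fixed
## action sequence that carries the point to an adjacent vertex (two
## ring steps) and then holds it there.
##
## Level 2 ("which trajectory am I performing"): 9 trajectory states,
## the ordered pairs (start vertex, end vertex) including the 3 static
## ones, plus a replica of the target factor that may change between
## level-2 steps.  A^(2) maps the trajectory state to context outcomes
## (initial ring location, ring direction, target identity) that set the
## level-1 initial-state prior D^(1) and policy prior E^(1).

ring_size <- 6L
vertex_ring <- c(1L, 3L, 5L)   # ring positions of the triangle vertices

#' Discrete level specification
#'
#' Light container for one level's arrays; columns of every probability
#' array must sum to one.
#'
#' @param A list of likelihood matrices (outcome x state) per modality.
#' @param B list of transition matrices per action.
#' @param C list of log-preference vectors per modality.
#' @param D list of initial-state priors per factor.
#' @param E prior over policies.
#' @param policies matrix (one row per policy) of action indices.
#' @param T planning horizon (number of outcome epochs).
#' @param gamma expected-free-energy precision (>= 0).
#' @return an object of class `mdp_level`.
#' @export
mdp_level <- function(A, B, C, D, E, policies, T, gamma) {
  chk <- function(M, what) {
    s <- colSums(M)
    if (any(abs(s - 1) > 1e-12))
      stop_invalid(sprintf("columns of %s must sum to 1", what))
  }
  for (i in seq_along(A)) chk(A[[i]], paste0("A[[", i, "]]"))
  for (i in seq_along(B)) chk(B[[i]], paste0("B[[", i, "]]"))
  for (i in seq_along(D)) {
    if (abs(sum(D[[i]]) - 1) > 1e-12)
      stop_invalid(sprintf("D[[%d]] must sum to 1", i))
  }
  if (abs(sum(E) - 1) > 1e-8) stop_invalid("E must sum to 1")
  check_count(T, "T")
  check_scalar(gamma, "gamma", lower = 0)
  structure(list(A = A, B = B, C = C, D = D, E = E, policies = policies,
                 T = as.integer(T), gamma = gamma),
            class = "mdp_level")
}

#' Build the two discrete levels of the coordination task
#'
#' @param vertices 3 x 3 matrix of triangle vertex coordinates (rows:
#'   right, apex, lower-left; columns x, y, z in metres).
#' @param preference log-preference (nats) on the "correct" outcome.
#' @param gamma level-1 policy precision.
#' @param a_conc concentration of the level-2 likelihood `A^(2)`: the
#'   probability assigned to the veridical context outcome (the rest is
#'   spread uniformly).  Must exceed 1/K for every modality.
#' @param a_temperature temperature applied to the columns of `A^(2)`
#'   (elementwise power then renormalization); 1 is intact, smaller
#'   values attenuate the hierarchical likelihood precision.
#' @param e_match prior policy weight consistent with the descending
#'   direction context (remaining mass spread over the other policies).
#' @param e_static prior mass on the static policy (the effort prior:
#'   movement is a priori implausible and must be licensed by expected
#'   free energy); the remainder is split over the two movement
#'   policies.
#' @param b2_stay stickiness of the level-2 target transitions.
#' @param T1,T2 level-1 and level-2 horizons.
#' @return an object of class `task_models`: fields `level1`, `level2`,
#'   `link` (the `A^(2)` matrices), `ring` (6 x 3 ring coordinates),
#'   `vertex_ring`, and `colours` (one-hot target colour patterns).
#' @export
build_task_models <- function(vertices, preference = 3, gamma = 1,
                              a_conc = 0.9, a_temperature = 1,
                              e_match = 0.8, e_static = 0.7,
                              b2_stay = 0.7, T1 = 4, T2 = 4) {
  if (!is.matrix(vertices) || any(dim(vertices) != c(3, 3)) ||
      any(!is.finite(vertices)))
    stop_invalid("'vertices' must be a finite 3 x 3 matrix (one vertex per row)")
  check_scalar(preference, "preference")
  check_scalar(gamma, "gamma", lower = 0)
  check_scalar(a_conc, "a_conc", lower = 0.5, upper = 1)
  check_scalar(a_temperature, "a_temperature", lower = 0, upper = 1,
               strict_lower = TRUE)
  check_scalar(e_match, "e_match", lower = 1 / 3, upper = 1)
  check_scalar(e_static, "e_static", lower = 0, upper = 1, strict_lower = TRUE)
  check_scalar(b2_stay, "b2_stay", lower = 0, upper = 1)
  T1 <- check_count(T1, "T1"); T2 <- check_count(T2, "T2")

  ## ring coordinates: vertices at positions 1, 3, 5; midpoints between
  ring <- matrix(0, ring_size, 3)
  ring[vertex_ring, ] <- vertices
  for (v in 1:3) {
    nxt <- vertices[if (v == 3) 1 else v + 1, ]
    ring[vertex_ring[v] + 1L, ] <- (vertices[v, ] + nxt) / 2
  }

  ## ---- level 1 -----------------------------------------------------------
  rot <- function(shift) {
    P <- matrix(0, ring_size, ring_size)
    for (j in seq_len(ring_size))
      P[((j - 1L + shift) %% ring_size) + 1L, j] <- 1
    P
  }
  B1 <- list(cw = rot(1L), acw = rot(-1L), static = diag(ring_size))
  ## policies: fixed action sequences (T1 - 1 transitions); one ring
  ## step per epoch for two epochs, then hold
  policies <- rbind(cw = c(1L, 1L, rep(3L, T1 - 3L)),
                    acw = c(2L, 2L, rep(3L, T1 - 3L)),
                    static = rep(3L, T1 - 1L))
  A_loc <- diag(ring_size)
  A_col <- diag(3)
  ## correct outcome: location factor x target factor scored jointly;
  ## represented as a function below (never observed by the model)
  C1 <- list(location = rep(0, ring_size), colour = rep(0, 3),
             correct = c(preference, 0))  # (correct, incorrect)
  D1 <- list(location = rep(1 / ring_size, ring_size),
             target = rep(1 / 3, 3))
  E1 <- rep(1 / 3, 3)
  level1 <- mdp_level(A = list(location = A_loc, colour = A_col),
                      B = B1, C = C1, D = D1, E = E1,
                      policies = policies, T = T1, gamma = gamma)

  ## ---- level 2 -----------------------------------------------------------
  ## trajectory states: ordered (start, end) vertex pairs, start-major
  traj_start <- rep(1:3, each = 3)
  traj_end <- rep(1:3, times = 3)
  n_traj <- 9L
  ## trajectory transitions: new start = old end, new end uniform
  B2_traj <- matrix(0, n_traj, n_traj)
  for (j in seq_len(n_traj)) {
    nxt <- which(traj_start == traj_end[j])
    B2_traj[nxt, j] <- 1 / length(nxt)
  }
  B2_targ <- matrix((1 - b2_stay) / 2, 3, 3)
  diag(B2_targ) <- b2_stay
  D2 <- list(trajectory = as.numeric(traj_start == 1L) / 3,
             target = rep(1 / 3, 3))

  ## A^(2): context outcomes generated from level-2 states
  spread <- function(K, idx) {
    p <- rep((1 - a_conc) / (K - 1), K); p[idx] <- a_conc; p
  }
  A2_start <- vapply(seq_len(n_traj),
                     function(j) spread(ring_size, vertex_ring[traj_start[j]]),
                     numeric(ring_size))
  ring_dir <- function(s, e) {
    if (s == e) return(3L)                       # static
    d_cw <- (vertex_ring[e] - vertex_ring[s]) %% ring_size
    if (d_cw <= ring_size / 2) 1L else 2L        # cw else acw
  }
  A2_dir <- vapply(seq_len(n_traj),
                   function(j) spread(3L, ring_dir(traj_start[j], traj_end[j])),
                   numeric(3))
  A2_targ <- vapply(1:3, function(k) spread(3L, k), numeric(3))

  temper <- function(M) apply(M, 2, function(col) normalize(col^a_temperature))
  link <- list(start = temper(A2_start), direction = temper(A2_dir),
               target = temper(A2_targ))

  level2 <- mdp_level(A = link, B = list(trajectory = B2_traj,
                                         target = B2_targ),
                      C = list(), D = D2, E = 1,
                      policies = matrix(1L, 1, 1), T = T2, gamma = gamma)

  colours <- diag(3)   # one-hot colour pattern per darkened target
  structure(list(level1 = level1, level2 = level2, link = link,
                 ring = ring, vertex_ring = vertex_ring,
                 traj_start = traj_start, traj_end = traj_end,
                 e_match = e_match, e_static = e_static, colours = colours,
                 preference = preference),
            class = "task_models")
}

## probability that location l is "correct" given target k
correct_prob <- function(task, l_dist, k_dist) {
  p <- 0
  for (k in 1:3) p <- p + k_dist[k] * l_dist[task$vertex_ring[k]]
  p
}

#' Expected free energy of a policy
#'
#' \eqn{G = \sum_\tau \sum_m [\mathrm{KL}(o_{pred}\Vert\sigma(C_m)) +
#' E_{states}[H(A_m)]]} over the policy's remaining steps: risk
#' (divergence of predicted from preferred outcomes) plus ambiguity
#' (expected conditional entropy of the likelihood).  The supplied
#' posteriors describe the state at step `current_step` (0 before the
#' first outcome); the policy's own actions roll the location forward
#' through steps `current_step + 1 .. T`.
#'
#' @param task a [build_task_models()] object.
#' @param policy policy index (1 cw, 2 acw, 3 static).
#' @param loc_post posterior over the 6 ring locations at `current_step`.
#' @param targ_post posterior over the 3 targets.
#' @param current_step step index of the supplied posterior (>= 0).
#' @return scalar expected free energy (nats).
#' @export
expected_free_energy <- function(task, policy, loc_post, targ_post,
                                 current_step = 0L) {
  lev <- task$level1
  loc <- normalize(loc_post)
  targ <- normalize(targ_post)
  if (current_step >= lev$T) return(0)
  pref <- list(location = softmax(lev$C$location),
               colour = softmax(lev$C$colour),
               correct = softmax(lev$C$correct))
  kl <- function(p, q) sum(p * (log_floor(p) - log_floor(q)))
  G <- 0
  for (tau in seq.int(current_step + 1L, lev$T)) {
    if (tau > 1L) {
      act <- lev$policies[policy, tau - 1L]
      loc <- as.numeric(lev$B[[act]] %*% loc)
    }
    o_loc <- as.numeric(lev$A$location %*% loc)
    o_col <- as.numeric(lev$A$colour %*% targ)
    pc <- correct_prob(task, loc, targ)
    o_cor <- c(pc, 1 - pc)
    G <- G + kl(o_loc, pref$location) + kl(o_col, pref$colour) +
      kl(o_cor, pref$correct)
    ## ambiguity: all level-1 likelihoods are deterministic, H(A) = 0
  }
  G
}

#' Posterior over policies
#'
#' \eqn{\pi = \sigma(\ln(E \cdot o^{(2)}) - F - \gamma G)} with the
#' log floor `exp(-16)`.
#'
#' @param E_eff context-weighted prior policy weights (need not be
#'   normalized).
#' @param F vector of variational free energies per policy.
#' @param G vector of expected free energies per policy.
#' @param gamma policy precision.
#' @return normalized policy posterior.
#' @export
policy_posterior <- function(E_eff, F, G, gamma) {
  if (length(F) != length(E_eff) || length(G) != length(E_eff))
    stop_invalid("'E_eff', 'F' and 'G' must have equal length")
  check_scalar(gamma, "gamma", lower = 0)
  softmax(log_floor(normalize(E_eff)) - F - gamma * G)
}

#' Policy-conditioned state posterior by exact enumeration
#'
#' Enumerates the joint initial location x target space (18 states; the
#' location path is deterministic given the policy) and scores the soft
#' outcomes observed so far, returning per-step location posteriors,
#' the target posterior, and the policy's variational free energy
#' \eqn{F = -\ln} (marginal likelihood of its outcomes under the
#' priors).
#'
#' @param task a [build_task_models()] object.
#' @param policy policy index.
#' @param D1 list with `location` and `target` initial priors.
#' @param obs_loc matrix (epochs so far x 6) of soft location outcomes.
#' @param obs_col matrix (epochs so far x 3) of soft colour outcomes.
#' @return list with `loc_post` (T1 x 6 predicted/updated location
#'   distributions), `targ_post`, `init_post` (posterior over the
#'   initial location), and `F`.
#' @export
state_posterior <- function(task, policy, D1, obs_loc, obs_col) {
  lev <- task$level1
  n_obs <- if (is.null(obs_loc)) 0L else nrow(obs_loc)
  ## deterministic ring path per initial location
  path <- matrix(0L, ring_size, lev$T)
  shift <- c(1L, -1L, 0L)
  for (l in seq_len(ring_size)) {
    pos <- l
    path[l, 1L] <- pos
    for (tau in 2:lev$T) {
      pos <- ((pos - 1L + shift[lev$policies[policy, tau - 1L]]) %%
                ring_size) + 1L
      path[l, tau] <- pos
    }
  }
  ## joint weights over (initial location, target)
  w <- outer(D1$location, D1$target)
  if (n_obs > 0L) {
    for (tau in seq_len(n_obs)) {
      lik_loc <- obs_loc[tau, path[, tau]]
      lik_col <- as.numeric(obs_col[tau, ] %*% task$level1$A$colour)
      w <- w * outer(lik_loc, lik_col)
    }
  }
  evidence <- sum(w)
  if (evidence <= 0) {
    warning("degenerate evidence for policy ", policy,
            ": all outcomes have zero probability; using uniform posterior")
    w <- matrix(1, ring_size, 3)
    evidence <- exp(-16)
  }
  wj <- w / sum(w)
  init_post <- rowSums(wj)
  targ_post <- colSums(wj)
  loc_post <- matrix(0, lev$T, ring_size)
  for (tau in seq_len(lev$T)) {
    for (l in seq_len(ring_size))
      loc_post[tau, path[l, tau]] <- loc_post[tau, path[l, tau]] + init_post[l]
  }
  list(loc_post = loc_post, targ_post = targ_post, init_post = init_post,
       F = -log(max(evidence, exp(-16))))
}

#' Descending context from level 2
#'
#' Maps the level-2 posterior through `A^(2)` into the context outcomes
#' that parameterize level 1: an initial-location prior `D1_loc`, a
#' target prior `D1_targ`, and policy prior weights `E_eff` that favour
#' the policy whose ring direction matches the predicted trajectory.
#'
#' @param task a [build_task_models()] object.
#' @param traj_post posterior over the 9 trajectory states.
#' @param targ_post posterior over the 3 level-2 target states.
#' @return list with `o_start`, `o_dir`, `o_targ` (outcome
#'   distributions), `D1` (level-1 priors) and `E_eff`.
#' @export
descending_context <- function(task, traj_post, targ_post) {
  traj_post <- normalize(traj_post)
  targ_post <- normalize(targ_post)
  o_start <- as.numeric(task$link$start %*% traj_post)
  o_dir <- as.numeric(task$link$direction %*% traj_post)
  o_targ <- as.numeric(task$link$target %*% targ_post)
  E_base <- matrix((1 - task$e_match) / 2, 3, 3)
  diag(E_base) <- task$e_match      # rows: direction context, cols: policy
  effort <- c(rep((1 - task$e_static) / 2, 2), task$e_static)
  E_eff <- normalize(effort * as.numeric(crossprod(E_base, o_dir)))
  list(o_start = o_start, o_dir = o_dir, o_targ = o_targ,
       D1 = list(location = o_start, target = o_targ),
       E_eff = E_eff)
}

#' Ascending update of the level-2 posterior
#'
#' \eqn{r^{(2)} = \sigma(\ln o^{(2)} + \ln(E^{(1)}\cdot\pi^{(1)}) +
#' \ln(D^{(1)}\cdot s_1^{(1)}))}: the level-2 prior is combined with the
#' likelihood of the policy and initial state inferred at level 1.
#'
#' @param task a [build_task_models()] object.
#' @param o_traj prior (predictive) distribution over trajectory states.
#' @param pi1 level-1 policy posterior.
#' @param s1_loc level-1 posterior over the initial ring location.
#' @param o_targ2 prior over level-2 target states.
#' @param s_targ level-1 target posterior.
#' @return list with `traj` and `target` posteriors.
#' @export
ascending_update <- function(task, o_traj, pi1, s1_loc, o_targ2, s_targ) {
  E_lik <- as.numeric(crossprod(task$link$direction, pi1))
  D_lik <- as.numeric(crossprod(task$link$start, s1_loc))
  traj <- softmax(log_floor(normalize(o_traj)) + log_floor(E_lik) +
                    log_floor(D_lik))
  t_lik <- as.numeric(crossprod(task$link$target, s_targ))
  target <- softmax(log_floor(normalize(o_targ2)) + log_floor(t_lik))
  list(traj = traj, target = target)
}

#' Serialize task-model arrays to a structured text document
#'
#' Writes all discrete arrays (A, B, C, D, E, policies, horizons, the
#' hierarchical link and ring geometry) as nested lists in YAML, for
#' fixture reuse and cross-implementation comparison.
#'
#' @param task a [build_task_models()] object.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
save_task_models <- function(task, path) {
  tolists <- function(M) lapply(seq_len(nrow(M)), function(i) as.numeric(M[i, ]))
  doc <- list(
    level1 = list(A = lapply(task$level1$A, tolists),
                  B = lapply(task$level1$B, tolists),
                  C = task$level1$C,
                  D = task$level1$D,
                  E = task$level1$E,
                  policies = tolists(task$level1$policies),
                  T = task$level1$T, gamma = task$level1$gamma),
    level2 = list(B = lapply(task$level2$B, tolists),
                  D = task$level2$D,
                  T = task$level2$T),
    link = lapply(task$link, tolists),
    ring = tolists(task$ring),
    vertex_ring = task$vertex_ring)
  yaml::write_yaml(doc, path)
  invisible(path)
}
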