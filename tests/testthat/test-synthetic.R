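test_that("chain systems expose analytic stationary, committor and Kemeny oracles", {
  P <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  sys <- chain_system(P, bound = 1, unbound = 2)
  expect_equal(sys$pi, c(2, 1) / 3, tolerance = 1e-12)
  expect_equal(chain_kemeny(P), 1 / 0.3, tolerance = 1e-10)

  Q <- gambler_chain(11)
  expect_equal(chain_committor(Q, 1, 11), (0:10) / 10, tolerance = 1e-10)

  # mean first-passage identity on a random chain: K = sum_j pi_j m_ij, any i
  R <- rand_chain(8, seed = 4)
  m <- chain_mfpt(R)
  pi <- chain_stationary(R)
  K <- chain_kemeny(R)
  for (i in c(1, 5, 8)) expect_equal(sum(pi * m[i, ]), K, tolerance = 1e-8)
})

test_that("chain construction validates its preconditions", {
  expect_error(build_chain_system(1), "at least 2")
  expect_error(build_chain_system(2, p_intra = 0.1, p_escape = 0.2),
               "p_escape < p_intra")
  expect_error(chain_system(matrix(c(0.5, 0.6, 0.2, 0.8), 2, byrow = TRUE),
                            1, 2), "sum to 1")
  # disconnected construction is rejected
  P <- diag(2)
  expect_error(chain_system(P, 1, 2), "not irreducible")
})

test_that("markov sampling is seed-reproducible with per-replica streams", {
  sys <- build_chain_system(2, seed = 3)
  e1 <- sample_markov_trajectories(sys, 4, 200, seed = 11)
  e2 <- sample_markov_trajectories(sys, 4, 200, seed = 11)
  expect_identical(e1$frames, e2$frames)
  # replica streams independent of the replica count
  e3 <- sample_markov_trajectories(sys, 8, 200, seed = 11)
  expect_identical(e1$frames, e3$frames[1:4])
  # degenerate length: single frame per replica
  e4 <- sample_markov_trajectories(sys, 3, 1, seed = 11)
  expect_true(all(vapply(e4$frames, length, integer(1)) == 1L))
})

test_that("long-run occupancy matches the analytic stationary distribution", {
  P <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  sys <- chain_system(P, bound = 1, unbound = 2)
  n <- 1e6
  traj <- sample_markov_trajectories(sys, 1, n, seed = 17, start = 1)$frames[[1]]
  occ <- mean(traj == 1)
  # binomial SE inflated by the chain's integrated autocorrelation time
  tau_int <- (1 + 0.7) / (1 - 0.7)
  se <- sqrt(2 / 3 * 1 / 3 / n * tau_int)
  expect_lt(abs(occ - 2 / 3), 3 * se)
})

test_that("analytic committor matches a Monte-Carlo walker committor", {
  P <- rand_chain(12, seed = 21)
  B <- 1:2; U <- 11:12
  q <- chain_committor(P, B, U)
  cumP <- t(apply(P, 1, cumsum))
  set.seed(5)
  mc <- msmpath:::cpp_mc_committor(cumP, seq_len(12) %in% B,
                                   seq_len(12) %in% U, 1e5L, 1e5L)
  expect_lt(max(abs(mc[, 1] - q)), 0.01)
  expect_equal(max(mc[, 2]), 0)
})

test_that("zero-noise funnel dynamics stay in the bound basin", {
  fp <- funnel_params()
  ens <- langevin_funnel(fp, 3, 1001, dt = 0.01, kT = 1e-9, seed = 2)
  expect_lt(max(unlist(ens$observables$cage_distance)), fp$barrier_radius / 4)
})

test_that("free diffusion obeys the Einstein relation", {
  fp <- funnel_params(barrier_height = 0, wall_radius = 1e6)
  ens <- langevin_funnel(fp, 300, 501, dt = 0.01, kT = 1, seed = 5)
  # MSD fit over the trace, pooled across 300 replicas
  t_grid <- c(100, 300, 500)
  for (tg in t_grid) {
    X <- t(vapply(ens$frames, function(f) f[tg + 1, ], numeric(2)))
    msd <- mean(rowSums(X^2))
    expect_equal(msd, 4 * fp$diffusion * tg * 0.01, tolerance = 0.2)
  }
})

test_that("deep-well escape rate agrees with a Kramers estimate", {
  fp <- funnel_params(barrier_height = 8, channel_contrast = 0)
  # numeric Kramers MFPT for 2-D radial diffusion to an absorbing ring:
  # tau = (1/D) int_0^R dy e^{U(y)}/y int_0^y x e^{-U(x)} dx
  U <- function(r) funnel_potential(fp, r)
  inner <- Vectorize(function(y)
    stats::integrate(function(x) x * exp(-U(x)), 0, y)$value)
  tau <- stats::integrate(function(y) exp(U(y)) / y * inner(y),
                          1e-6, fp$barrier_radius)$value / fp$diffusion
  n_rep <- 32; n_steps <- 150000; dt <- 0.01
  ens <- langevin_funnel(fp, n_rep, n_steps + 1, dt = dt, kT = 1, seed = 3)
  crossings <- sum(vapply(ens$observables$cage_distance, function(r)
    any(r > fp$barrier_radius), logical(1)))
  expected <- n_rep * (1 - exp(-n_steps * dt / tau))
  expect_gt(crossings, expected / 10)
  expect_lt(crossings, expected * 10)
})

test_that("funnel metastability: bound dwells dominate approach times", {
  fp <- funnel_params(barrier_height = 6)
  ens <- langevin_funnel(fp, 16, 50001, dt = 0.01, kT = 1, seed = 9)
  # core-shell first-passage accounting avoids ridge recrossing noise
  stats_by_rep <- lapply(ens$observables$cage_distance, function(r) {
    st <- ifelse(r < 4, 1L, ifelse(r > 10, 2L, 3L))
    tryCatch(empirical_rates(st, 1, 2, time_per_step = 0.01),
             error = function(e) NULL)
  })
  ev <- sum(vapply(stats_by_rep, function(s) s$events_bu, numeric(1)))
  tb <- sum(vapply(stats_by_rep, function(s) s$time_bound, numeric(1)))
  dwell <- tb / max(ev, 1)
  # diffusive approach time from the ridge to the well centre
  approach <- fp$barrier_radius^2 / (4 * fp$diffusion)
  expect_gte(dwell, 10 * approach)
})

test_that("reseeding-tree emulation preserves frames and transition statistics", {
  sys <- build_chain_system(2, seed = 3)
  ens <- sample_markov_trajectories(sys, 6, 400, seed = 8)
  expect_identical(emulate_reseeding_tree(ens, 50, 0), ens)
  tree <- emulate_reseeding_tree(ens, 50, 0.5, seed = 4)
  expect_equal(total_frames(tree), total_frames(ens))
  expect_gt(nrow(tree$parents), 0)
  # every branch frame exists in its parent replica
  nfr <- vapply(tree$frames, length, integer(1))
  expect_true(all(tree$parents$branch_frame <= nfr[tree$parents$parent]))
  # path-through-tree counting reproduces the unsplit counts exactly
  for (lag in c(1L, 3L)) {
    c0 <- count_transitions(ens, lag = lag)
    c1 <- count_transitions(tree, lag = lag)
    expect_equal(as.matrix(c1$C), as.matrix(c0$C))
  }
  # forced case: one interior boundary, fraction 1 -> every replica splits once
  forced <- emulate_reseeding_tree(ens, 200, 1, seed = 1)
  expect_equal(length(forced$frames), 2L * length(ens$frames))
  expect_equal(nrow(forced$parents), length(ens$frames))
  expect_error(emulate_reseeding_tree(ens, 50, 1.5), "fraction")
})

test_that("empirical core-set rates recover two-state chain rates", {
  a <- 0.004; b <- 0.02
  P <- matrix(c(1 - a, a, b, 1 - b), 2, 2, byrow = TRUE)
  sys <- chain_system(P, 1, 2)
  traj <- sample_markov_trajectories(sys, 1, 5e5, seed = 31, start = 1)$frames[[1]]
  er <- empirical_rates(traj, 1, 2)
  expect_equal(er$k_off, a, tolerance = 0.15)
  expect_equal(er$k_on_rate, b, tolerance = 0.15)
})
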