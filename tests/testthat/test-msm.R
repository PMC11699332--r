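test_that("sliding-window counts match hand enumeration", {
  cm <- count_transitions(list(c(1L, 1L, 2L, 2L)), lag = 1)
  expect_equal(as.matrix(cm$C),
               matrix(c(1, 0, 1, 1), 2, 2), ignore_attr = TRUE)
  # length 4 at lag 2: exactly 2 sliding pairs
  cm2 <- count_transitions(list(c(1L, 2L, 1L, 2L)), lag = 2)
  expect_equal(sum(cm2$C), 2)
  expect_equal(as.numeric(cm2$C[1, 1]), 1)
  expect_equal(as.numeric(cm2$C[2, 2]), 1)
  expect_warning(count_transitions(list(c(1L, 2L)), lag = 5), "empty counts")
})

test_that("tree-aware counting follows root-to-leaf paths only", {
  # parent 1: frames a b c d; child 2 branches after frame 2: frames e f
  labs <- list(c(1L, 2L, 3L, 4L), c(5L, 6L))
  par <- data.frame(replica = 2L, parent = 1L, branch_frame = 2L)
  cm <- count_transitions(labs, lag = 1, parents = par)
  got <- Matrix::summary(cm$C)
  pairs <- paste(got$i, got$j, sep = "->")
  # lineage of child: 1 2 | 5 6; pairs 2->5 and 5->6 belong to the child
  expect_setequal(pairs, c("1->2", "2->3", "3->4", "2->5", "5->6"))
  # no pair joins 4 (leaf of replica 1) with 5/6 (different lineage tip)
  expect_false(any(pairs %in% c("4->5", "4->6")))
  # lag 2 reaches across the branch through the inherited context
  cm2 <- count_transitions(labs, lag = 2, parents = par)
  got2 <- Matrix::summary(cm2$C)
  expect_setequal(paste(got2$i, got2$j, sep = "->"),
                  c("1->3", "2->4", "1->5", "2->6"))
})

test_that("count totals satisfy the segment-length identity", {
  sys <- build_chain_system(2, seed = 5)
  ens <- sample_markov_trajectories(sys, 5, 120, seed = 6)
  tree <- emulate_reseeding_tree(ens, 30, 0.7, seed = 2)
  for (lag in c(1L, 4L)) {
    cm <- count_transitions(tree, lag = lag)
    nfr <- vapply(tree$frames, length, integer(1))
    has_parent <- seq_along(tree$frames) %in% tree$parents$replica
    ctx <- ifelse(has_parent, lag, 0) # all parents here are long enough
    expect_equal(sum(cm$C), sum(pmax(nfr + ctx - lag, 0)))
  }
})

test_that("estimation is invariant to replica ordering", {
  sys <- build_chain_system(2, seed = 5)
  ens <- sample_markov_trajectories(sys, 6, 300, seed = 9)
  cm1 <- count_transitions(ens$frames, lag = 1)
  cm2 <- count_transitions(rev(ens$frames), lag = 1)
  expect_equal(as.matrix(cm1$C), as.matrix(cm2$C))
})

test_that("geometric pseudocounts add a symmetric, distance-decaying prior", {
  cm <- as_counts(matrix(c(5, 1, 0, 0, 7, 2, 1, 0, 9), 3, 3, byrow = TRUE))
  d <- matrix(c(0, 1, 4, 1, 0, 3, 4, 3, 0), 3, 3)
  expect_identical(geometric_pseudocounts(cm, d, mass = 0), cm)
  out <- geometric_pseudocounts(cm, d, bin_width = 0.002, mass = 0.5,
                                neighbor_quantile = 0.5)
  added <- as.matrix(out$C - cm$C)
  expect_equal(added, t(added), tolerance = 1e-12)
  expect_equal(sum(added), 0.5 * 3, tolerance = 1e-10)
  # zero distance receives the maximal prior weight
  d2 <- matrix(c(0, 0, 4, 0, 0, 4, 4, 4, 0), 3, 3)
  out2 <- geometric_pseudocounts(cm, d2, mass = 0.5)
  add2 <- as.matrix(out2$C - cm$C)
  expect_equal(add2[1, 2], max(add2[upper.tri(add2)]))
  expect_gt(add2[1, 2], add2[1, 3])
  expect_error(geometric_pseudocounts(cm, d, bin_width = 0), "positive")
})

test_that("model estimation normalizes rows and solves the stationary vector", {
  cm <- as_counts(matrix(c(9, 1, 2, 8), 2, 2, byrow = TRUE))
  m <- estimate_model(cm)
  expect_equal(m$T, matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE),
               ignore_attr = TRUE)
  expect_equal(m$pi, c(2, 1) / 3, tolerance = 1e-12)
  expect_equal(rowSums(m$T), c(1, 1), tolerance = 1e-12)
  expect_lt(max(abs(as.numeric(m$pi %*% m$T) - m$pi)), 1e-10)
  # symmetric counts imply detailed balance
  S <- matrix(c(8, 2, 1, 2, 6, 2, 1, 2, 9), 3, 3)
  S <- S + t(S)
  ms <- estimate_model(as_counts(S))
  F1 <- ms$pi * ms$T
  expect_equal(F1, t(F1), tolerance = 1e-10)
  # disconnected blocks: only the heavier block is kept, the rest reported
  blocks <- matrix(0, 5, 5)
  blocks[1:3, 1:3] <- 10; blocks[4:5, 4:5] <- 1
  mb <- estimate_model(as_counts(blocks))
  expect_equal(mb$states, 1:3)
  expect_setequal(mb$dropped, 4:5)
})

test_that("strongly connected components agree with a matrix-power oracle", {
  set.seed(20)
  for (rep in 1:5) {
    n <- 12
    A <- matrix(stats::rbinom(n * n, 1, 0.12), n, n)
    diag(A) <- 1
    cm <- as_counts(A)
    comps <- connected_components(cm)
    # independent oracle: boolean transitive closure by repeated squaring
    R <- A > 0
    for (k in 1:5) R <- (R %*% R + R) > 0
    member <- integer(n); cid <- 0L
    for (i in seq_len(n)) {
      if (member[i] > 0) next
      cid <- cid + 1L
      member[R[i, ] & R[, i]] <- cid
    }
    oracle <- unname(split(seq_len(n), member[seq_len(n)]))
    expect_setequal(lapply(comps, sort), lapply(oracle, sort))
  }
})

test_that("implied timescales follow the eigenvalue definition", {
  m <- model_from_P(matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE))
  ts <- implied_timescales(m)
  expect_equal(ts$timescale, -1 / log(0.7), tolerance = 1e-12)
  expect_equal(round(ts$timescale, 3), 2.804)
  expect_false(ts$complex)
  # a lambda = exp(-1) eigenvalue at lag 1 gives timescale 1
  m2 <- model_from_P(matrix(c(1 + exp(-1), 1 - exp(-1),
                              1 - exp(-1), 1 + exp(-1)) / 2, 2, 2))
  expect_equal(implied_timescales(m2)$timescale[1], 1, tolerance = 1e-10)
  # scan flags non-monotone sequences (diagnostic contract)
  sys <- build_chain_system(2, p_intra = 0.2, p_escape = 0.02,
                            p_return = 0.04, seed = 5)
  ens <- sample_markov_trajectories(sys, 8, 500, seed = 3)
  sc <- timescale_scan(ens$frames, lags = c(1L, 2L, 4L))
  expect_true(is.logical(attr(sc, "non_monotone")))
  expect_equal(nrow(sc), 9L)
})

test_that("stationary distribution recovered from sampling matches the generator", {
  sys <- build_chain_system(2, seed = 5)
  ens <- sample_markov_trajectories(sys, 32, 2500, seed = 13)
  m <- estimate_model(count_transitions(ens, lag = 1))
  n_eff <- 32 * 2500 / 50 # conservative autocorrelation discount
  se <- sqrt(sys$pi * (1 - sys$pi) / n_eff)
  expect_true(all(abs(m$pi - sys$pi) < 3 * se + 0.01))
})
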