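test_that("boundary definition applies the strict 25 A medoid rule", {
  m <- model_from_P(gambler_chain(3))
  obs <- c(3, 12, 30)
  b <- define_boundaries(m, obs, start_clusters = 1, u_cutoff = 25)
  expect_equal(b$B, 1L); expect_equal(b$U, 3L)
  # medoid exactly at the cutoff is not unbound
  b2 <- define_boundaries(m, c(3, 25, 30), start_clusters = 1)
  expect_equal(b2$U, 3L)
  # start frame inside an unbound cluster violates disjointness
  expect_error(define_boundaries(m, obs, start_clusters = 3), "overlap")
  expect_error(define_boundaries(m, c(1, 2, 3), start_clusters = 1),
               "boundary state empty")
})

test_that("forward committor solves the gambler's-ruin profile exactly", {
  m <- model_from_P(gambler_chain(11))
  b <- boundary_states(1, 11)
  q <- forward_committor(m, b)
  expect_equal(unname(q), (0:10) / 10, tolerance = 1e-10)
  expect_identical(unname(q[c(1, 11)]), c(0, 1)) # boundary values exact
  expect_true(all(q[2:10] > 0 & q[2:10] < 1))
})

test_that("committors match Monte-Carlo walkers on a random chain", {
  P <- rand_chain(20, seed = 31)
  m <- model_from_P(P)
  b <- boundary_states(1:2, 19:20)
  q <- forward_committor(m, b)
  cumP <- t(apply(P, 1, cumsum))
  set.seed(77)
  mc <- msmpath:::cpp_mc_committor(cumP, seq_len(20) %in% b$B,
                                   seq_len(20) %in% b$U, 1e5L, 1e6L)
  expect_lt(max(abs(mc[, 1] - q)), 0.01)
  # backward committor vs walkers on the explicitly reversed chain
  qm <- backward_committor(m, b)
  Trev <- t(m$T * m$pi) / m$pi
  cumR <- t(apply(Trev, 1, cumsum))
  set.seed(78)
  mcr <- msmpath:::cpp_mc_committor(cumR, seq_len(20) %in% b$U,
                                    seq_len(20) %in% b$B, 1e5L, 1e6L)
  expect_lt(max(abs(mcr[, 1] - qm)), 0.01)
})

test_that("reversible chains satisfy q- = 1 - q+ and the flux factorization", {
  # symmetric counts give detailed balance
  S <- matrix(c(0, 5, 1, 5, 0, 4, 1, 4, 0), 3, 3) + diag(c(10, 8, 12))
  m <- estimate_model(as_counts(S))
  b <- boundary_states(1, 3)
  qp <- forward_committor(m, b); qm <- backward_committor(m, b)
  expect_equal(unname(qm), 1 - unname(qp), tolerance = 1e-10)
  fl <- reactive_flux(m, b, qp, qm)
  f_expected <- m$pi * m$T * outer(1 - qp, qp)
  expect_equal(fl$f, f_expected, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("reactive flux reproduces hand evaluation on a 3-state chain", {
  # B - I - U linear chain with hand-printed T
  P <- matrix(c(0.8, 0.2, 0.0,
                0.3, 0.4, 0.3,
                0.0, 0.1, 0.9), 3, 3, byrow = TRUE)
  m <- model_from_P(P)
  b <- boundary_states(1, 3)
  qp <- forward_committor(m, b)
  qm <- backward_committor(m, b)
  fl <- reactive_flux(m, b, qp, qm)
  # net outgoing reactive current from B: pi_1 T_12 q+_2 (q-_1 = 1)
  expect_equal(fl$F_BU, m$pi[1] * 0.2 * qp[2], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(fl$F_BU, fl$F_UB, tolerance = 1e-10)
  # committor of the middle state: q = 0.3/(0.3+0.3) toward U
  expect_equal(unname(qp[2]), 0.5)
})

test_that("flux conservation holds on random connected chains", {
  for (s in 1:6) {
    P <- rand_chain(15, seed = 100 + s)
    m <- model_from_P(P)
    b <- boundary_states(1:2, 14:15)
    qp <- forward_committor(m, b); qm <- backward_committor(m, b)
    fl <- reactive_flux(m, b, qp, qm)
    expect_lt(abs(fl$F_BU - fl$F_UB) / fl$F_BU, 1e-10)
  }
})

test_that("TPT rates follow the flux-over-population definition", {
  P <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  m <- model_from_P(P)
  b <- boundary_states(1, 2)
  qp <- forward_committor(m, b); qm <- backward_committor(m, b)
  fl <- reactive_flux(m, b, qp, qm)
  expect_equal(fl$F_BU, 2 / 3 * 0.1, tolerance = 1e-12) # pi_B * a
  r1 <- tpt_rates(fl$F_BU, fl$F_UB, m$pi, qm, lag = 1)
  # nu_BU = F_BU / (tau * sum pi q-) = (pi_B a)/(pi_B) = a
  expect_equal(r1$nu_BU, 0.1, tolerance = 1e-12)
  expect_equal(r1$nu_UB, 0.2, tolerance = 1e-12)
  # doubling the lag halves both rates
  r2 <- tpt_rates(fl$F_BU, fl$F_UB, m$pi, qm, lag = 2)
  expect_equal(r2$nu_BU, r1$nu_BU / 2)
  expect_equal(r2$nu_UB, r1$nu_UB / 2)
  # algebraic identity when F_BU = F_UB
  expect_equal(r1$nu_BU / r1$nu_UB,
               sum(m$pi * (1 - qm)) / sum(m$pi * qm), tolerance = 1e-12)
  expect_error(tpt_rates(1, 1, m$pi, qm, lag = 0), "positive")
})

test_that("box concentration converts side length to molarity", {
  expect_equal(ligand_box_concentration(70.7) * 1000, 4.70, tolerance = 0.01)
  c1 <- ligand_box_concentration(50)
  expect_equal(ligand_box_concentration(100), c1 / 8, tolerance = 1e-12)
  # side such that V = 1 L / N_A gives exactly 1 M
  side <- (1 / 6.02214076e23)^(1 / 3) * 1e9 # dm^ -> A
  expect_equal(ligand_box_concentration(side), 1, tolerance = 1e-9)
})

test_that("rate-constant worked examples reproduce the printed arithmetic", {
  # K_D = k_off / k_on: 0.26 us^-1 over 300 M^-1 us^-1 is 0.87 mM
  expect_equal(round(0.26 / 300 * 1000, 2), 0.87)
  # unit change only: 300 M^-1 us^-1 = 0.3 mM^-1 us^-1
  expect_equal(300 * 1e-3, 0.3)
  # toy chain: constants computed end to end from the definition
  P <- matrix(c(0.98, 0.02, 0, 0.05, 0.9, 0.05, 0, 0.01, 0.99), 3, 3,
              byrow = TRUE)
  m <- model_from_P(P)
  b <- boundary_states(1, 3)
  qp <- forward_committor(m, b); qm <- backward_committor(m, b)
  fl <- reactive_flux(m, b, qp, qm)
  rt <- tpt_rates(fl$F_BU, fl$F_UB, m$pi, qm, 1)
  ctb <- committor_to_bound(m, b)
  C <- 2
  kc <- rate_constants(rt$nu_BU, rt$nu_UB, m$pi, ctb, C = C)
  pi_b <- sum(m$pi[ctb > 0.5])
  expect_equal(kc$LR, C * pi_b, tolerance = 1e-12)
  expect_equal(kc$L, C - kc$LR)
  expect_equal(kc$k_off, rt$nu_BU / (C * pi_b), tolerance = 1e-12)
  expect_equal(kc$k_on, rt$nu_UB / (C - C * pi_b)^2, tolerance = 1e-12)
  expect_equal(kc$K_D, kc$k_off / kc$k_on, tolerance = 1e-14)
  # K_D scales linearly with the box concentration (the volume factor)
  kc2 <- rate_constants(rt$nu_BU, rt$nu_UB, m$pi, ctb, C = 2 * C)
  expect_equal(kc2$K_D / kc$K_D, 2, tolerance = 1e-12)
  expect_equal(kc2$k_off, kc$k_off / 2, tolerance = 1e-12)
})

test_that("Kemeny constant: eigen formula, row invariance and lumping", {
  P <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  m <- model_from_P(P)
  expect_equal(kemeny_constant(m), 1 / 0.3, tolerance = 1e-10)
  # row invariance of sum_j pi_j m_ij across every starting row
  R <- rand_chain(10, seed = 55)
  mr <- model_from_P(R)
  mf <- mean_first_passage(mr)
  rows <- as.numeric(mf %*% mr$pi)
  expect_lt(max(rows) - min(rows), 1e-8)
  expect_equal(kemeny_constant(mr), rows[1], tolerance = 1e-8)
  # lumping two states cannot lengthen global travel times
  counts <- as_counts(round(1000 * R * chain_stationary(R)) + 1)
  part <- c(1, 1, 2:9)
  diag_res <- lumping_diagnostics(counts, part)
  expect_lte(diag_res$K_lumped, diag_res$K_full)
  expect_equal(diag_res$percent, 100 * diag_res$K_lumped / diag_res$K_full)
  # percentage equals an independent recomputation from scratch
  K2 <- kemeny_constant(estimate_model(lump_states(counts, part)),
                        check = FALSE)
  expect_equal(diag_res$K_lumped, K2, tolerance = 1e-12)
})

test_that("state lumping aggregates counts and rejects degenerate partitions", {
  cm <- as_counts(matrix(1:16, 4, 4))
  same <- lump_states(cm, 1:4)
  expect_equal(as.matrix(same$C), as.matrix(cm$C), ignore_attr = TRUE)
  two <- lump_states(cm, c(1, 1, 2, 2))
  expect_equal(sum(two$C), sum(cm$C))
  expect_equal(as.numeric(two$C[1, 1]), 1 + 2 + 5 + 6)
  expect_error(lump_states(cm, rep(1, 4)), "single state")
  expect_error(lump_states(cm, 1:3), "cover")
})

test_that("bootstrap confidence intervals behave under count removal", {
  sys <- build_chain_system(2, seed = 5)
  ens <- sample_markov_trajectories(sys, 24, 1500, seed = 19)
  cm <- count_transitions(ens, lag = 1)
  b <- boundary_states(sys$bound, sys$unbound)
  # zero removal: all repeats identical, zero-width intervals
  bs0 <- bootstrap_rates(cm, b, removal_fraction = 0, repeats = 5, seed = 1)
  expect_equal(bs0$ci$lower, bs0$ci$upper, tolerance = 1e-12)
  expect_equal(bs0$ci$lower[bs0$ci$constant == "K_D"],
               bs0$estimate$K_D, tolerance = 1e-12)
  # CI width grows with the removal fraction (paired seeds, in expectation)
  widths <- sapply(c(0.005, 0.02, 0.08), function(f) {
    w <- sapply(1:8, function(s) {
      ci <- bootstrap_rates(cm, b, removal_fraction = f, repeats = 10,
                            seed = s)$ci
      ci$upper[3] - ci$lower[3]
    })
    mean(w)
  })
  expect_true(widths[1] < widths[3])
  expect_error(bootstrap_rates(as_counts(matrix(c(5, 5, 5, 5), 2)), b),
               "at least 100")
})
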