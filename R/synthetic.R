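#' Discrete synthetic system with analytic kinetic ground truth
#'
#' Wraps an arbitrary row-stochastic transition matrix together with declared
#' bound/unbound state sets. All analytic quantities (stationary distribution,
#' committors, mean first-passage times, Kemeny constant) are obtained by
#' direct linear solves and serve as oracles for the estimation pipeline.
#'
#' @param transition_matrix square row-stochastic matrix (rows sum to 1
#'   within 1e-12).
#' @param bound,unbound disjoint, non-empty integer state sets.
#' @param seed integer seed stored for downstream sampling.
#' @return object of class `chain_system` with elements `P`, `bound`,
#'   `unbound`, `pi` (analytic stationary distribution) and `seed`.
#' @export
chain_system <- function(transition_matrix, bound, unbound, seed = 1L) {
  P <- as.matrix(transition_matrix)
  if (nrow(P) != ncol(P)) stop("transition matrix must be square")
  if (any(abs(rowSums(P) - 1) > 1e-12)) stop("rows must sum to 1 within 1e-12")
  if (any(P < 0)) stop("negative transition probabilities")
  bound <- as.integer(bound); unbound <- as.integer(unbound)
  if (length(bound) == 0L || length(unbound) == 0L)
    stop("bound and unbound sets must be non-empty")
  if (length(intersect(bound, unbound)) > 0L)
    stop("bound and unbound sets must be disjoint")
  g <- igraph::graph_from_adjacency_matrix(P > 0, mode = "directed")
  if (igraph::components(g, mode = "strong")$no != 1L)
    stop("chain is not irreducible (disconnected construction)")
  structure(list(P = P, bound = bound, unbound = unbound,
                 pi = chain_stationary(P), seed = as.integer(seed)),
            class = "chain_system")
}

#' Build a metastable chain with designated bound/unbound macrostates
#'
#' Constructs a birth-death chain of `n_metastable` blocks of `block_size`
#' microstates each. Nearest-neighbour hops within a block occur with
#' probability `p_intra` per direction; hops across a block boundary occur
#' with the much smaller probability `p_escape` (away from the bound block)
#' and `p_return` (back toward it), making each block a metastable
#' macrostate. With `p_return > p_escape` the bound block is thermo-
#' dynamically favoured (stationary weight ratio `p_return / p_escape` per
#' boundary), emulating a predominantly bound complex with rare barrier
#' crossings. The first block is the bound macrostate, the last the unbound
#' one.
#'
#' @param n_metastable number of metastable blocks (>= 2).
#' @param p_intra within-block hop probability, `0 < p_escape < p_intra < 1`
#'   and `2 * p_intra <= 1`.
#' @param p_escape cross-block hop probability away from the bound block.
#' @param p_return cross-block hop probability toward the bound block
#'   (default `20 * p_escape`: a deeply bound complex).
#' @param block_size microstates per block (default 3).
#' @param seed integer seed for downstream sampling.
#' @return a [chain_system()].
#' @export
build_chain_system <- function(n_metastable, p_intra = 0.15,
                               p_escape = 0.002,
                               p_return = 20 * p_escape,
                               block_size = 3L, seed = 1L) {
  if (!(p_escape > 0 && p_escape < p_intra && p_intra < 1))
    stop("require 0 < p_escape < p_intra < 1")
  if (p_return <= 0 || p_return >= 1) stop("p_return must be in (0, 1)")
  if (2 * max(p_intra, p_return) > 1) stop("hop probabilities exceed a stochastic row")
  if (n_metastable < 2L) stop("need at least 2 metastable blocks")
  n <- n_metastable * block_size
  P <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    cross <- (i %% block_size) == 0L # edge between consecutive blocks
    P[i, i + 1L] <- if (cross) p_escape else p_intra
    P[i + 1L, i] <- if (cross) p_return else p_intra
  }
  diag(P) <- 1 - rowSums(P)
  chain_system(P, bound = seq_len(block_size),
               unbound = n - block_size + seq_len(block_size), seed = seed)
}

#' Analytic stationary distribution of a transition matrix
#'
#' Solves `pi = pi P`, `sum(pi) = 1` by a direct least-squares linear solve
#' (no eigeniteration), for use as an oracle.
#'
#' @param P row-stochastic matrix.
#' @return stationary probability vector.
#' @export
chain_stationary <- function(P) {
  n <- nrow(P)
  A <- rbind(t(diag(n) - P), rep(1, n))
  pi <- qr.solve(A, c(rep(0, n), 1))
  pi / sum(pi)
}

#' Analytic forward committor by direct linear solve
#'
#' Probability, per state, of reaching the target set before the source set.
#'
#' @param P row-stochastic matrix.
#' @param source states where the committor is 0.
#' @param target states where the committor is 1.
#' @return committor vector over all states.
#' @export
chain_committor <- function(P, source, target) {
  n <- nrow(P)
  q <- numeric(n)
  q[target] <- 1
  inter <- setdiff(seq_len(n), c(source, target))
  if (length(inter) > 0L) {
    A <- diag(length(inter)) - P[inter, inter, drop = FALSE]
    b <- P[inter, target, drop = FALSE] %*% rep(1, length(target))
    q[inter] <- solve(A, b)
  }
  q
}

#' Analytic mean first-passage time matrix
#'
#' Uses the fundamental matrix `Z = (I - P + 1 pi')^{-1}`; `m[i, j]` is the
#' expected number of steps to first reach `j` from `i`, with `m[i, i] = 0`.
#'
#' @param P row-stochastic, irreducible matrix.
#' @return matrix of mean first-passage times.
#' @export
chain_mfpt <- function(P) {
  n <- nrow(P)
  pi <- chain_stationary(P)
  Z <- solve(diag(n) - P + matrix(1, n, 1) %*% t(pi))
  m <- (matrix(diag(Z), n, n, byrow = TRUE) - Z) /
    matrix(pi, n, n, byrow = TRUE)
  diag(m) <- 0
  m
}

#' Analytic Kemeny constant from the eigenvalue formula
#'
#' `K = sum_{i >= 2} 1 / (1 - lambda_i)` over the non-unit eigenvalues;
#' complex pairs cancel in the sum for non-reversible matrices.
#'
#' @param P row-stochastic, irreducible matrix.
#' @return Kemeny constant in lag units.
#' @export
chain_kemeny <- function(P) {
  ev <- eigen(P, only.values = TRUE)$values
  ev <- ev[order(-Mod(ev), Mod(Im(ev)))][-1L] # drop the unit eigenvalue
  K <- sum(1 / (1 - ev))
  if (abs(Im(K)) > 1e-8 * max(1, abs(Re(K))))
    stop("imaginary residue in Kemeny sum")
  Re(K)
}

#' Sample independent replicas of a discrete Markov chain
#'
#' Replica `r` uses its own RNG stream derived from `(seed, r)`, so adding
#' replicas never perturbs existing ones; ensembles are bitwise reproducible
#' given `(seed, parameters)`.
#'
#' @param system a [chain_system()].
#' @param n_replicas number of replicas.
#' @param n_steps frames per replica (>= 1); the first frame is the start
#'   state.
#' @param seed master seed (defaults to the system's).
#' @param start starting state; `NULL` draws it from the stationary
#'   distribution within each replica's stream.
#' @return a [replica_ensemble()] with integer state frames.
#' @export
sample_markov_trajectories <- function(system, n_replicas, n_steps,
                                       seed = system$seed, start = NULL) {
  stopifnot(inherits(system, "chain_system"), n_steps >= 1L)
  cumP <- t(apply(system$P, 1, cumsum))
  frames <- vector("list", n_replicas)
  for (r in seq_len(n_replicas)) {
    set.seed(replica_seed(seed, r))
    s0 <- if (is.null(start)) {
      sample.int(nrow(system$P), 1L, prob = system$pi)
    } else as.integer(start)
    frames[[r]] <- if (n_steps == 1L) s0 else
      c(s0, cpp_sample_chain(cumP, s0, n_steps - 1L))
  }
  replica_ensemble(frames, labels = rep("chain", n_replicas))
}

#' Funnel potential parameters for the continuous binding toy
#'
#' Radial well at the origin (the bound basin), a barrier ridge of height
#' `barrier_height` (kT units at reference kT = 1) at `barrier_radius`,
#' modulated by `n_channels` angular exit channels of relative depth
#' `channel_contrast`, plus a soft confining wall.
#'
#' @param barrier_height ridge height in kT units (default 8).
#' @param barrier_radius ridge radius in length units (default 8).
#' @param n_channels number of angular exit channels (default 4).
#' @param channel_contrast relative modulation of the ridge in `[0, 1)`.
#' @param diffusion mobility, equal to the diffusion coefficient
#'   (length^2 / time) at the reference temperature kT = 1.
#' @param wall_radius radius of the confining wall.
#' @param wall_k harmonic wall stiffness.
#' @return list of class `funnel_params`.
#' @export
funnel_params <- function(barrier_height = 8, barrier_radius = 8,
                          n_channels = 4L, channel_contrast = 0.25,
                          diffusion = 1, wall_radius = 30, wall_k = 2) {
  stopifnot(barrier_radius > 0, channel_contrast >= 0, channel_contrast < 1)
  structure(list(barrier_height = barrier_height,
                 barrier_radius = barrier_radius,
                 n_channels = as.integer(n_channels),
                 channel_contrast = channel_contrast,
                 diffusion = diffusion, wall_radius = wall_radius,
                 wall_k = wall_k), class = "funnel_params")
}

#' Potential energy of the funnel toy
#' @param params a [funnel_params()].
#' @param r radius (vectorized).
#' @param theta angle in radians (default 0).
#' @return potential energy (kT units at reference kT = 1).
#' @export
funnel_potential <- function(params, r, theta = 0) {
  u <- (r / params$barrier_radius)^2
  g <- u * exp(1 - u)
  m <- 1 - params$channel_contrast * cos(params$n_channels * theta)
  w <- 0.5 * params$wall_k * pmax(0, r - params$wall_radius)^2
  params$barrier_height * g * m + w
}

#' Simulate 2-D overdamped Langevin dynamics in the binding funnel
#'
#' Euler-Maruyama integration with drift `-D grad U` and noise
#' `sqrt(2 D kT dt)`, where `D` is the mobility (equal to the diffusion
#' coefficient at the reference temperature kT = 1); the Einstein relation
#' holds with fixed mobility, so the `kT -> 0` limit is noiseless and the
#' particle stays at the well minimum. The radial coordinate is exported as
#' the per-frame `cage_distance` observable. The integrator requires the
#' per-step noise displacement `sqrt(2 D kT dt)` to stay below a fifth of
#' the barrier radius; larger steps are rejected at entry.
#'
#' @param params a [funnel_params()].
#' @param n_replicas number of replicas.
#' @param n_steps frames per replica (first frame = start position).
#' @param dt integration step.
#' @param kT temperature in reference units (1 = the unit the barrier height
#'   is expressed in); `kT -> 0` is the zero-noise limit.
#' @param seed master seed; per-replica streams derived from `(seed, r)`.
#' @param start length-2 start position (default the well minimum, origin).
#' @return a [replica_ensemble()] with 2-D coordinate frames and a
#'   `cage_distance` observable.
#' @export
langevin_funnel <- function(params = funnel_params(), n_replicas, n_steps,
                            dt = 0.01, kT = 1, seed = 1L,
                            start = c(0, 0)) {
  stopifnot(inherits(params, "funnel_params"), n_steps >= 1L, dt > 0, kT >= 0)
  step_len <- sqrt(2 * params$diffusion * kT * dt)
  if (step_len > 0.2 * params$barrier_radius)
    stop("dt too large: per-step displacement exceeds 20% of barrier width")
  frames <- vector("list", n_replicas)
  for (r in seq_len(n_replicas)) {
    set.seed(replica_seed(seed, r))
    traj <- cpp_langevin_funnel(as.numeric(start), n_steps - 1L, dt,
                                kT, params$diffusion,
                                params$barrier_height, params$barrier_radius,
                                params$n_channels, params$channel_contrast,
                                params$wall_radius, params$wall_k)
    frames[[r]] <- rbind(matrix(as.numeric(start), 1, 2), traj)
  }
  obs <- lapply(frames, function(f) sqrt(rowSums(f^2)))
  replica_ensemble(frames, times = lapply(frames, function(f)
    seq_len(nrow(f)) * dt), labels = rep("funnel", n_replicas),
    observables = list(cage_distance = obs))
}

#' Impose reseeding-tree connectivity on an ensemble
#'
#' Randomly splits replicas at interval boundaries into parent/child lineage
#' segments, populating `parents` links while preserving every frame and the
#' exact transition statistics (path-through-tree counting on the split
#' ensemble reproduces the counts of the unsplit one). This emulates the
#' bookkeeping left behind by adaptive reseeding without running the
#' controller.
#'
#' @param ensemble a [replica_ensemble()] without parent links.
#' @param interval frames between candidate branch points (>= 1).
#' @param fraction probability of branching at each candidate boundary.
#' @param seed integer seed.
#' @return a [replica_ensemble()] with the same total frame count.
#' @export
emulate_reseeding_tree <- function(ensemble, interval, fraction, seed = 1L) {
  stopifnot(interval >= 1L)
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  if (nrow(ensemble$parents) > 0L)
    stop("ensemble already carries parent links")
  if (fraction == 0) return(ensemble)
  set.seed(as.integer(seed))
  frames <- list(); times <- list(); labels <- character(0)
  obs_names <- names(ensemble$observables)
  obs <- setNames(replicate(length(obs_names), list(), simplify = FALSE),
                  obs_names)
  parents <- data.frame(replica = integer(0), parent = integer(0),
                        branch_frame = integer(0))
  slice <- function(x, idx) if (is.matrix(x)) x[idx, , drop = FALSE] else x[idx]
  for (r in seq_along(ensemble$frames)) {
    n <- frame_count(ensemble$frames[[r]])
    bounds <- seq(interval, n - 1L, by = interval)
    cuts <- bounds[runif(length(bounds)) < fraction]
    seg_start <- c(1L, cuts + 1L)
    seg_end <- c(cuts, n)
    prev_id <- NA_integer_
    for (s in seq_along(seg_start)) {
      idx <- seg_start[s]:seg_end[s]
      id <- length(frames) + 1L
      frames[[id]] <- slice(ensemble$frames[[r]], idx)
      times[[id]] <- ensemble$times[[r]][idx]
      labels[id] <- ensemble$labels[r]
      for (nm in obs_names)
        obs[[nm]][[id]] <- ensemble$observables[[nm]][[r]][idx]
      if (s > 1L) {
        parents <- rbind(parents, data.frame(
          replica = id, parent = prev_id,
          branch_frame = length(seg_start[s - 1L]:seg_end[s - 1L])))
      }
      prev_id <- id
    }
  }
  replica_ensemble(frames, times = times, labels = labels, parents = parents,
                   observables = if (length(obs_names)) obs else NULL,
                   label_set = ensemble$label_set)
}

#' Empirical macrostate rates by core-set first-passage counting
#'
#' Assigns each frame of a long trajectory to the last visited core set and
#' counts completed passages between the cores; rates are events per unit
#' time spent in the departing macrostate. This is the brute-force reference
#' estimator used to validate the TPT pipeline.
#'
#' @param states integer state sequence.
#' @param bound,unbound core state sets.
#' @param time_per_step physical time per step (default 1).
#' @return list with `k_off`, `k_on_rate` (both per unit time), event counts
#'   and macrostate occupancies.
#' @export
empirical_rates <- function(states, bound, unbound, time_per_step = 1) {
  core <- integer(length(states)) # 1 = bound, 2 = unbound, 0 = unassigned
  core[states %in% bound] <- 1L
  core[states %in% unbound] <- 2L
  idx <- which(core != 0L)
  if (length(idx) == 0L) stop("trajectory never visits a core set")
  last <- core[idx][pmax(cumsum(core != 0L), 1L)] # last-visited core fill
  trans <- which(diff(last) != 0L)
  ev_bu <- sum(last[trans] == 1L)
  ev_ub <- sum(last[trans] == 2L)
  t_b <- sum(last == 1L) * time_per_step
  t_u <- sum(last == 2L) * time_per_step
  list(k_off = ev_bu / t_b, k_on_rate = ev_ub / t_u,
       events_bu = ev_bu, events_ub = ev_ub,
       time_bound = t_b, time_unbound = t_u)
}
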