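#' PIGS controller configuration
#'
#' Parameters of the progress-index-guided sampling controller: replica
#' count, decision interval, reseeding cap, and the redundancy metric.
#'
#' @param n_replicas number of concurrently propagated replicas (default 64).
#' @param decision_interval propagation steps between reseeding decisions
#'   (default 100, the analogue of a 100 ps interval at 1 ps per step).
#' @param max_reseed maximum replicas terminated per decision (default
#'   `n_replicas / 2`).
#' @param redundancy_radius distance below which two current replicas count
#'   as mutually redundant (default 2, about the thermal width of the
#'   funnel's bound well).
#' @param history_window decision cycles of history retained for the rare
#'   pool (default 20).
#' @param rare_pool_size number of top rare snapshots eligible as restarts.
#' @param seed master seed.
#' @return list of class `pigs_config`.
#' @export
pigs_config <- function(n_replicas = 64L, decision_interval = 100L,
                        max_reseed = NULL, redundancy_radius = 2,
                        history_window = 20L, rare_pool_size = NULL,
                        seed = 1L) {
  if (is.null(max_reseed)) max_reseed <- n_replicas %/% 2L
  if (max_reseed > n_replicas / 2)
    stop("max_reseed must not exceed half the replica count")
  if (decision_interval < 1L) stop("decision interval must be >= 1 step")
  if (is.null(rare_pool_size)) rare_pool_size <- 2L * max_reseed
  structure(list(n_replicas = as.integer(n_replicas),
                 decision_interval = as.integer(decision_interval),
                 max_reseed = as.integer(max_reseed),
                 redundancy_radius = redundancy_radius,
                 history_window = as.integer(history_window),
                 rare_pool_size = as.integer(rare_pool_size),
                 seed = as.integer(seed)), class = "pigs_config")
}

#' Rank replicas by redundancy and identify rare restart candidates
#'
#' Redundancy score of a replica = number of other current replicas within
#' `radius` of its position; ties break by progress-index position within
#' the pooled sample (earlier on the progress index = denser region = more
#' redundant), then by replica id. Rare candidates are the history snapshots
#' with the largest mean distance to the rest of the history.
#'
#' @param current numeric matrix (replicas x features) of current positions.
#' @param history numeric matrix of recent ensemble snapshots.
#' @param radius redundancy radius.
#' @param n_rare number of rare snapshots to return (default 10).
#' @return list: `order` (replica indices most to least redundant),
#'   `scores`, `rare` (row indices into `history`, rarest first).
#' @export
redundancy_rank <- function(current, history, radius, n_rare = 10L) {
  current <- as.matrix(current)
  if (nrow(current) < 2L) stop("need at least two replicas")
  d <- as.matrix(dist(current))
  scores <- unname(rowSums(d <= radius) - 1L)
  pooled <- rbind(current, as.matrix(history))
  pi_ord <- progress_index(pooled, start = 1L, mode = "exact")
  pi_pos <- match(seq_len(nrow(current)), pi_ord)
  ord <- order(-scores, pi_pos, seq_len(nrow(current)))
  hist_m <- as.matrix(history)
  rare <- if (nrow(hist_m) > 0L) {
    dh <- as.matrix(dist(hist_m))
    rest <- rowMeans(dh)
    head(order(-rest), n_rare)
  } else integer(0)
  list(order = ord, scores = scores, rare = rare)
}

#' One PIGS decision cycle
#'
#' Advances every active replica by `decision_interval` steps with the
#' supplied propagator, then terminates up to `max_reseed` of the most
#' redundant replicas (only those with redundancy > 0) and reseeds each from
#' the rare pool, recording a parent link to the replica and frame the
#' restart snapshot came from. The active replica count is conserved.
#'
#' @param state controller state from [pigs_init()].
#' @param propagator function `(start_point, n_steps)` returning a matrix of
#'   the `n_steps` new frames; RNG is seeded by the controller per call.
#' @param config a [pigs_config()].
#' @return updated controller state.
#' @export
pigs_step <- function(state, propagator, config) {
  ns <- config$decision_interval
  # advance every active replica on its own stream
  for (slot in seq_along(state$active)) {
    id <- state$active[slot]
    set.seed(replica_seed(config$seed,
                          state$stream[id] * 100003L + state$cycle))
    new <- tryCatch(propagator(state$current[slot, ], ns),
                    error = function(e) {
                      state$flagged <<- c(state$flagged, id)
                      NULL
                    })
    if (is.null(new)) next
    state$frames[[id]] <- rbind(state$frames[[id]], new)
    state$current[slot, ] <- new[nrow(new), ]
  }
  state$cycle <- state$cycle + 1L
  # update history reservoir with the current positions
  state$history <- rbind(state$history,
                         cbind(state$current,
                               rep = state$active,
                               frm = vapply(state$active, function(id)
                                 nrow(state$frames[[id]]), numeric(1))))
  max_hist <- config$history_window * config$n_replicas
  if (nrow(state$history) > max_hist)
    state$history <- state$history[seq(nrow(state$history) - max_hist + 1L,
                                       nrow(state$history)), , drop = FALSE]
  d <- ncol(state$current)
  rr <- redundancy_rank(state$current, state$history[, seq_len(d),
                                                     drop = FALSE],
                        config$redundancy_radius,
                        n_rare = config$rare_pool_size)
  victims <- rr$order[rr$scores[rr$order] > 0]
  victims <- head(victims, config$max_reseed)
  if (length(victims) > 0L && length(rr$rare) > 0L) {
    set.seed(replica_seed(config$seed, 777L + state$cycle))
    picks <- rr$rare[1L + (seq_along(victims) - 1L) %% length(rr$rare)]
    for (v in seq_along(victims)) {
      slot <- victims[v]
      old_id <- state$active[slot]
      snap <- state$history[picks[v], ]
      new_id <- length(state$frames) + 1L
      state$frames[[new_id]] <- matrix(numeric(0), 0, d)
      state$stream[new_id] <- config$n_replicas + state$branches + 1L
      state$parents <- rbind(state$parents, data.frame(
        replica = new_id, parent = as.integer(snap["rep"]),
        branch_frame = as.integer(snap["frm"])))
      state$current[slot, ] <- snap[seq_len(d)]
      state$active[slot] <- new_id
      state$branches <- state$branches + 1L
      state$log <- rbind(state$log, data.frame(
        cycle = state$cycle, slot = slot, terminated = old_id,
        reseeded = new_id, parent = as.integer(snap["rep"]),
        branch_frame = as.integer(snap["frm"])))
    }
  }
  state
}

#' Initialize PIGS controller state
#'
#' @param start numeric matrix (`n_replicas` x features) of start positions,
#'   or a single row recycled to all replicas.
#' @param config a [pigs_config()].
#' @return controller state consumed by [pigs_step()].
#' @export
pigs_init <- function(start, config) {
  start <- as.matrix(start)
  if (nrow(start) == 1L)
    start <- start[rep(1L, config$n_replicas), , drop = FALSE]
  d <- ncol(start)
  frames <- lapply(seq_len(config$n_replicas), function(i)
    start[i, , drop = FALSE])
  list(frames = frames, current = start,
       active = seq_len(config$n_replicas),
       stream = seq_len(config$n_replicas),
       parents = data.frame(replica = integer(0), parent = integer(0),
                            branch_frame = integer(0)),
       history = matrix(numeric(0), 0, d + 2L,
                        dimnames = list(NULL, c(paste0("f", seq_len(d)),
                                                "rep", "frm"))),
       cycle = 0L, branches = 0L, flagged = integer(0),
       log = data.frame())
}

#' Run the PIGS controller for a number of decision cycles
#'
#' @inheritParams pigs_step
#' @param start start positions (see [pigs_init()]).
#' @param n_cycles number of decision cycles.
#' @param observable optional function mapping a frame matrix to a per-frame
#'   scalar trace (e.g. the radial cage distance).
#' @return a [replica_ensemble()] covering every replica record (terminated
#'   and active) with parent links, plus attributes `log` (reseeding
#'   bookkeeping) and `flagged` (replicas whose propagation failed).
#' @export
pigs_run <- function(start, propagator, config, n_cycles,
                     observable = NULL) {
  state <- pigs_init(start, config)
  for (i in seq_len(n_cycles)) state <- pigs_step(state, propagator, config)
  keep <- vapply(state$frames, nrow, integer(1)) > 0L
  # renumber replicas densely, remapping parent links
  ids <- which(keep)
  remap <- match(seq_along(state$frames), ids)
  parents <- state$parents
  parents <- parents[keep[parents$replica], , drop = FALSE]
  parents$replica <- remap[parents$replica]
  parents$parent <- remap[parents$parent]
  frames <- state$frames[ids]
  obs <- if (!is.null(observable))
    list(cage_distance = lapply(frames, observable)) else NULL
  ens <- replica_ensemble(frames, labels = rep("pigs", length(frames)),
                          parents = parents, observables = obs)
  attr(ens, "log") <- state$log
  attr(ens, "flagged") <- state$flagged
  ens
}

#' Committor-guided restart selection
#'
#' Selects starting snapshots for a follow-up adaptive-sampling run:
#' non-boundary clusters whose committor to the bound state is strictly
#' below `threshold` (unbound-leaning intermediates), keeping at most
#' `max_clusters` of them by decreasing stationary weight, then drawing
#' `n_picks` member frames round-robin across the chosen clusters.
#'
#' @param model a [estimate_model()] result.
#' @param ctb committor to the bound state ([committor_to_bound()]).
#' @param assignments per-frame cluster ids (the discretized trajectory).
#' @param bounds a [boundary_states()] object (boundary clusters are never
#'   selected).
#' @param threshold strict committor threshold (default 0.5).
#' @param n_picks number of starting frames (default 64).
#' @param max_clusters maximum clusters drawn from (default 10).
#' @param seed integer seed.
#' @return integer vector of `n_picks` frame indices with attribute
#'   `"clusters"` (the clusters selected).
#' @export
committor_restart_selection <- function(model, ctb, assignments, bounds,
                                        threshold = 0.5, n_picks = 64L,
                                        max_clusters = 10L, seed = 1L) {
  elig <- model$states[ctb < threshold]
  elig <- setdiff(elig, c(bounds$B, bounds$U))
  if (length(elig) == 0L) stop("no eligible cluster below the threshold")
  pop <- model$pi[match(elig, model$states)]
  chosen <- elig[order(-pop)][seq_len(min(max_clusters, length(elig)))]
  set.seed(as.integer(seed))
  members <- lapply(chosen, function(cl) which(assignments == cl))
  picks <- integer(n_picks)
  for (k in seq_len(n_picks)) {
    cl <- 1L + (k - 1L) %% length(chosen)
    picks[k] <- if (length(members[[cl]]) == 1L) members[[cl]] else
      sample(members[[cl]], 1L)
  }
  structure(picks, clusters = chosen)
}

#' Count replicas beyond an unbinding threshold over time
#'
#' For each time point, the number of replicas whose observable trace is
#' strictly above `threshold` (instantaneous), or has ever been above it
#' (`cumulative = TRUE`, the first-passage variant).
#'
#' @param traces list of per-replica observable vectors on a common time
#'   grid.
#' @param threshold unbinding threshold (default 10, strict `>`).
#' @param cumulative count first passages instead of instantaneous
#'   exceedances.
#' @return integer vector of counts per time point.
#' @export
unbinding_counter <- function(traces, threshold = 10, cumulative = FALSE) {
  len <- unique(vapply(traces, length, integer(1)))
  if (length(len) != 1L) stop("traces must share a common time grid")
  above <- vapply(traces, function(x) {
    a <- x > threshold
    if (cumulative) a <- cummax(a) > 0
    a
  }, logical(len))
  as.integer(rowSums(matrix(above, nrow = len)))
}

#' Count lineage-aware first crossings of an observable threshold
#'
#' A first crossing is a replica record whose observable strictly exceeds
#' the threshold within its own frames while its parent lineage (up to the
#' branch point) never did — i.e. a genuinely new unbinding event rather
#' than an inherited one. For ensembles without parent links this is simply
#' the number of replicas that ever exceed the threshold.
#'
#' @param ensemble a [replica_ensemble()] carrying the observable.
#' @param threshold crossing threshold (strict `>`; default 10).
#' @param observable observable name (default `"cage_distance"`).
#' @return integer count of first-crossing events.
#' @export
first_crossing_count <- function(ensemble, threshold = 10,
                                 observable = "cage_distance") {
  obs <- ensemble$observables[[observable]]
  if (is.null(obs)) stop("observable not found: ", observable)
  p <- ensemble$parents
  prior_max <- rep(-Inf, length(obs))
  # parents are created before children, so one forward pass suffices
  for (r in seq_along(obs)) {
    row <- p[p$replica == r, ]
    if (nrow(row) == 1L)
      prior_max[r] <- max(prior_max[row$parent],
                          obs[[row$parent]][seq_len(row$branch_frame)])
  }
  sum(vapply(seq_along(obs), function(r)
    prior_max[r] <= threshold && any(obs[[r]] > threshold), logical(1)))
}

#' Langevin-funnel propagator for the PIGS controller
#'
#' @param params a [funnel_params()].
#' @param dt integration step.
#' @param kT temperature.
#' @return function `(start, n_steps)` advancing one replica.
#' @export
funnel_propagator <- function(params, dt = 0.01, kT = 1) {
  force(params); force(dt); force(kT)
  function(start, n_steps) {
    cpp_langevin_funnel(as.numeric(start), as.integer(n_steps), dt, kT,
                        params$diffusion, params$barrier_height,
                        params$barrier_radius, params$n_channels,
                        params$channel_contrast, params$wall_radius,
                        params$wall_k)
  }
}

#' Markov-chain propagator for the PIGS controller
#'
#' States are carried as 1-column matrices so the controller's Euclidean
#' redundancy metric applies to the state index.
#'
#' @param system a [chain_system()].
#' @return function `(start, n_steps)` advancing one replica.
#' @export
chain_propagator <- function(system) {
  cumP <- t(apply(system$P, 1, cumsum))
  function(start, n_steps) {
    matrix(cpp_sample_chain(cumP, as.integer(start[1]),
                            as.integer(n_steps)), ncol = 1)
  }
}
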