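#' Sliding-window transition counts over a tree-connected ensemble
#'
#' Counts ordered state pairs `lag` frames apart along every root-to-leaf
#' lineage path. A reseeded replica inherits the last `lag` frames of its
#' parent lineage as context, so pairs crossing a branch point are counted
#' (the restart continues the parent's phase-space point and is a genuine
#' dynamical transition), while pairs never straddle lineages that are not on
#' the same root-to-leaf path. Each pair is counted exactly once, attributed
#' to the replica owning the later frame; for an unbranched replica of
#' length n this yields n - lag sliding-window counts.
#'
#' @param labels a [replica_ensemble()] whose frames are integer state ids,
#'   or a plain list of integer sequences.
#' @param lag lag time in frames (>= 1).
#' @param n_states state-space size (default: maximum observed id).
#' @param parents optional parent-link data frame when `labels` is a list.
#' @return object of class `count_matrix`: sparse counts `C`, `lag`, and
#'   `pseudocount_mass` (0 for raw counts).
#' @export
count_transitions <- function(labels, lag = 1L, n_states = NULL,
                              parents = NULL) {
  if (inherits(labels, "replica_ensemble")) {
    parents <- labels$parents
    labels <- labels$frames
  }
  if (is.null(parents))
    parents <- data.frame(replica = integer(0), parent = integer(0),
                          branch_frame = integer(0))
  if (lag < 1L) stop("lag must be >= 1")
  if (is.null(n_states)) n_states <- max(unlist(labels, use.names = FALSE))
  # context: last `lag` lineage frames preceding each replica's own frames
  memo <- vector("list", length(labels))
  lineage_tail <- function(r, k) {
    # last k frames of the lineage of replica r (own frames included)
    own <- labels[[r]]
    if (length(own) >= k) return(tail(own, k))
    row <- parents[parents$replica == r, ]
    if (nrow(row) == 0L) return(own)
    parent_part <- lineage_upto(row$parent, row$branch_frame,
                                k - length(own))
    c(parent_part, own)
  }
  lineage_upto <- function(r, upto, k) {
    own <- labels[[r]][seq_len(upto)]
    if (length(own) >= k) return(tail(own, k))
    row <- parents[parents$replica == r, ]
    if (nrow(row) == 0L) return(own)
    c(lineage_upto(row$parent, row$branch_frame, k - length(own)), own)
  }
  ii <- list(); jj <- list(); k <- 0L
  for (r in seq_along(labels)) {
    own <- labels[[r]]
    row <- parents[parents$replica == r, ]
    ctx <- if (nrow(row) == 1L)
      lineage_upto(row$parent, row$branch_frame, lag) else integer(0)
    ext <- c(ctx, own)
    npair <- length(ext) - lag
    if (npair > 0L) {
      k <- k + 1L
      ii[[k]] <- ext[seq_len(npair)]
      jj[[k]] <- ext[seq_len(npair) + lag]
    }
  }
  if (k == 0L) {
    warning("lag not shorter than any segment: empty counts")
    C <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(n_states, n_states))
  } else {
    C <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                              x = 1, dims = c(n_states, n_states))
  }
  structure(list(C = C, lag = as.integer(lag), pseudocount_mass = 0),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d states, %.6g total counts (lag %d, pseudocount mass %.4g)\n",
              nrow(x$C), sum(x$C), x$lag, x$pseudocount_mass))
  invisible(x)
}

#' Geometrically informed pseudocounts
#'
#' Adds a symmetric prior count between structurally similar clusters:
#' medoid distances are min-max normalized, discretized at `bin_width`, and
#' mapped to a linearly decreasing bin weight that reaches zero at the
#' `neighbor_quantile` of the distance distribution. The prior is scaled so
#' the total added mass equals `mass` per cluster, improving the robustness
#' of sparsely sampled transition regions without enforcing symmetry of the
#' raw counts.
#'
#' @param counts a [count_transitions()] result.
#' @param medoid_dist full symmetric matrix of cluster medoid distances.
#' @param bin_width discretization width on the normalized distance scale
#'   (default 0.002).
#' @param mass prior mass added per cluster (default 0.5; 0 = identity).
#' @param neighbor_quantile distance quantile beyond which the prior weight
#'   is zero (default 0.1).
#' @return a `count_matrix` with the prior added and
#'   `pseudocount_mass = mass`.
#' @export
geometric_pseudocounts <- function(counts, medoid_dist, bin_width = 0.002,
                                   mass = 0.5, neighbor_quantile = 0.1) {
  stopifnot(inherits(counts, "count_matrix"))
  if (bin_width <= 0) stop("bin_width must be positive")
  if (mass == 0) return(counts)
  n <- nrow(counts$C)
  d <- as.matrix(medoid_dist)
  if (nrow(d) != n) stop("medoid distances must cover all clusters")
  off <- d[upper.tri(d)]
  rng <- range(off)
  dn <- (d - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
  dn[dn < 0] <- 0
  b <- floor(dn / bin_width)
  b_cut <- max(1, floor(quantile(
    (off - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps),
    neighbor_quantile) / bin_width))
  W <- 1 - b / b_cut
  W[W < 0] <- 0
  W <- (W + t(W)) / 2
  if (sum(W) > 0) W <- W * (mass * n / sum(W))
  out <- counts
  out$C <- counts$C + Matrix::Matrix(W, sparse = TRUE)
  out$pseudocount_mass <- counts$pseudocount_mass + mass
  attr(out, "added_mass") <- sum(W)
  out
}

#' Strongly connected components of the count graph
#'
#' @param counts a [count_transitions()] result.
#' @return list of integer state-id vectors, sorted by decreasing total
#'   snapshot weight (sum of outgoing counts).
#' @export
connected_components <- function(counts) {
  n <- nrow(counts$C)
  trip <- Matrix::summary(methods::as(counts$C, "generalMatrix"))
  trip <- trip[trip$x != 0, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = trip$i, to = trip$j), directed = TRUE,
    vertices = data.frame(name = seq_len(n)))
  comp <- igraph::components(g, mode = "strong")
  groups <- split(seq_len(n), comp$membership)
  w <- vapply(groups, function(s) sum(counts$C[s, , drop = FALSE]),
              numeric(1))
  unname(groups[order(-w)])
}

#' Estimate a Markov state model from transition counts
#'
#' Restricts to the largest strongly connected component (dropped states are
#' reported via the `dropped` element, singletons included), row-normalizes
#' without enforcing symmetry of the counts, and computes the stationary
#' distribution as the leading left eigenvector, polished by power iteration
#' to `pi T = pi` within 1e-12.
#'
#' @param counts a [count_transitions()] result (with or without
#'   pseudocounts).
#' @return object of class `markov_model`: `T` (dense row-stochastic matrix
#'   over the retained component), `pi`, `lag`, `states` (original state
#'   ids retained) and `dropped`.
#' @export
estimate_model <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  if (sum(counts$C) == 0) stop("empty counts")
  comps <- connected_components(counts)
  keep <- sort(comps[[1L]])
  dropped <- setdiff(which(Matrix::rowSums(counts$C) +
                             Matrix::colSums(counts$C) > 0), keep)
  C <- as.matrix(counts$C[keep, keep, drop = FALSE])
  rs <- rowSums(C)
  if (any(rs == 0)) stop("all-zero row inside the connected component")
  T_ <- C / rs
  pi <- stationary_distribution(T_)
  structure(list(T = T_, pi = pi, lag = counts$lag, states = keep,
                 dropped = dropped, counts = counts),
            class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat(sprintf("markov_model: %d states (lag %d), %d dropped outside the largest component\n",
              length(x$states), x$lag, length(x$dropped)))
  invisible(x)
}

stationary_distribution <- function(T_) {
  n <- nrow(T_)
  e <- eigen(t(T_))
  i <- which.min(abs(e$values - 1))
  pi <- Re(e$vectors[, i])
  pi <- abs(pi) / sum(abs(pi))
  # polish: eigen() residuals can exceed the contract on hard matrices
  for (it in seq_len(1000L)) {
    new <- as.numeric(pi %*% T_)
    new <- new / sum(new)
    if (max(abs(new - pi)) < 1e-14) { pi <- new; break }
    pi <- new
  }
  pi
}

#' Implied relaxation timescales of a Markov model
#'
#' `t_i = -lag / log |lambda_i|` for the non-unit eigenvalues sorted by
#' decreasing modulus. Complex eigenvalues (possible because no reversibility
#' is enforced) are flagged. A diagnostic, not a model-selection criterion.
#'
#' @param model a [estimate_model()] result.
#' @param n_timescales how many timescales to report (default 5).
#' @return data frame: `index`, `timescale` (lag units of `model$lag`),
#'   `modulus`, `complex`.
#' @export
implied_timescales <- function(model, n_timescales = 5) {
  ev <- eigen(model$T, only.values = TRUE)$values
  ev <- ev[order(-Mod(ev))]
  if (Mod(ev[1]) > 1 + 1e-8) stop("leading eigenvalue exceeds 1")
  ev <- ev[-1L]
  bad <- which(Mod(ev) >= 1 - 1e-12)
  if (length(bad) > 0L)
    stop("non-stationary eigenvector with |lambda| >= 1: reducible model?")
  k <- min(n_timescales, length(ev))
  ev <- ev[seq_len(k)]
  data.frame(index = seq_len(k) + 1L,
             timescale = -model$lag / log(Mod(ev)),
             modulus = Mod(ev),
             complex = abs(Im(ev)) > 1e-12)
}

#' Implied-timescale scan across lag times
#'
#' Re-counts and re-estimates the model at each lag and reports the slowest
#' implied timescales, flagging non-monotone behaviour.
#'
#' @param labels ensemble or list accepted by [count_transitions()].
#' @param lags integer vector of lag times (frames).
#' @param n_timescales timescales per lag (default 3).
#' @param ... passed to [count_transitions()].
#' @return data frame of timescales per lag with a `non_monotone` attribute.
#' @export
timescale_scan <- function(labels, lags, n_timescales = 3, ...) {
  out <- do.call(rbind, lapply(lags, function(l) {
    m <- estimate_model(count_transitions(labels, lag = l, ...))
    cbind(lag = l, implied_timescales(m, n_timescales))
  }))
  t2 <- out$timescale[out$index == 2L]
  attr(out, "non_monotone") <- any(diff(t2) < 0)
  out
}
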