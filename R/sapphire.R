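#' Progress index: self-similarity ordering of snapshots
#'
#' Greedy construction: the start frame comes first; each subsequent
#' position appends the unvisited frame with the minimum Euclidean distance
#' to the already-visited set (ties break to the lowest frame index). The
#' exact mode costs O(n^2) distance evaluations and is intended for up to
#' ~1e5 frames; the approximate mode orders cluster leaders greedily and
#' refines within clusters by distance to the leader, requiring a fitted
#' [tree_cluster()] model.
#'
#' @param X numeric matrix (frames x features).
#' @param start index of the first frame (default 1).
#' @param mode `"exact"` or `"approximate"`.
#' @param model fitted [tree_cluster()] model (approximate mode).
#' @return integer permutation of frame indices.
#' @export
progress_index <- function(X, start = 1L, mode = c("exact", "approximate"),
                           model = NULL) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  n <- nrow(X)
  if (start < 1L || start > n) stop("start frame out of range")
  if (mode == "exact") {
    ord <- integer(n)
    ord[1L] <- start
    visited <- logical(n); visited[start] <- TRUE
    dmin <- colSums((t(X) - X[start, ])^2)
    dmin[visited] <- Inf
    for (k in seq_len(n - 1L)) {
      nxt <- which.min(dmin) # first index on ties = lowest frame index
      ord[k + 1L] <- nxt
      visited[nxt] <- TRUE
      if (k < n - 1L) {
        dmin <- pmin(dmin, colSums((t(X) - X[nxt, ])^2))
        dmin[visited] <- Inf
      }
    }
    return(ord)
  }
  if (is.null(model)) stop("approximate mode requires a fitted cluster model")
  asg <- model$assignments
  cl_ids <- unique(asg)
  leaders <- t(vapply(cl_ids, function(id) model$leaders[[id]],
                      numeric(ncol(X))))
  start_cl <- match(asg[start], cl_ids)
  cl_ord <- progress_index(leaders, start = start_cl, mode = "exact")
  ord <- integer(0)
  for (ci in cl_ord) {
    members <- which(asg == cl_ids[ci])
    ldr <- leaders[ci, ]
    d <- colSums((t(X[members, , drop = FALSE]) - ldr)^2)
    members <- members[order(d, members)]
    if (cl_ids[ci] == asg[start])
      members <- c(start, setdiff(members, start))
    ord <- c(ord, members)
  }
  ord
}

#' Kinetic cut function along a progress-index ordering
#'
#' At each split position s of the ordering, counts the time-adjacent frame
#' pairs (consecutive in the original dynamics, respecting reseeding
#' segments) with one member among the `window` ordered positions left of
#' the split and the other among the `window` positions right of it — a
#' three-set scheme (left window, right window, rest) where only
#' left-right transitions count. Low cut values mark kinetic barriers; the
#' annotation lane is `-ln(cut + eps)`.
#'
#' @param ordering permutation from [progress_index()] (global frame ids).
#' @param adjacency two-column matrix of time-adjacent global frame pairs,
#'   e.g. from [adjacent_pairs()].
#' @param window frames on each side of the split (default 10000;
#'   auto-shrinks near the edges of the ordering).
#' @param eps regularizing count inside the logarithm (default 0.5).
#' @return data frame: `split` (1 .. n-1), `cut`, `neg_log`.
#' @export
cut_profile <- function(ordering, adjacency, window = 10000, eps = 0.5) {
  n <- length(ordering)
  pos <- integer(max(c(ordering, adjacency)))
  pos[ordering] <- seq_len(n)
  cuts <- numeric(n - 1L)
  if (nrow(adjacency) > 0L) {
    pa <- pos[adjacency[, 1]]; pb <- pos[adjacency[, 2]]
    lo <- pmin(pa, pb); hi <- pmax(pa, pb)
    # pair (lo, hi) crosses split s iff lo in (s-window, s] and
    # hi in (s, s+window]: s in [max(lo, hi-window), min(lo+window-1, hi-1)]
    s1 <- pmax(lo, hi - window); s2 <- pmin(lo + window - 1L, hi - 1L)
    keep <- s1 <= s2 & lo < hi
    d <- tabulate(s1[keep], nbins = n + 1L) -
      tabulate(s2[keep] + 1L, nbins = n + 1L)
    cuts <- cumsum(d)[seq_len(n - 1L)]
  }
  data.frame(split = seq_len(n - 1L), cut = cuts,
             neg_log = -log(cuts + eps))
}

#' Mixing entropy of system labels along an ordering
#'
#' Shannon entropy (nats) of the system-label distribution in a centred
#' rolling window over the progress-index ordering; bounded by the log of
#' the number of label classes (ln 4 = perfect mixing of four systems).
#' The window shrinks symmetrically near the edges.
#'
#' @param ordering permutation of global frame ids.
#' @param labels per-global-frame system labels.
#' @param window rolling window size in frames (default 2000; the figure
#'   convention of 1000 is a config choice).
#' @return numeric entropy lane (nats), one value per ordered position.
#' @export
mixing_entropy <- function(ordering, labels, window = 2000) {
  lab <- labels[ordering]
  n <- length(lab)
  half <- floor(window / 2)
  vapply(seq_len(n), function(i) {
    w <- lab[max(1L, i - half):min(n, i + half)]
    p <- table(w) / length(w)
    -sum(p * log(p))
  }, numeric(1))
}

#' SAPPHIRE annotation table
#'
#' One row per progress-index position carrying the requested per-frame
#' lanes (observable traces, PC values, simulation time, start markers);
#' plotting is left to downstream tools.
#'
#' @param ordering permutation of global frame ids.
#' @param lanes named list of per-frame vectors aligned to global frame ids.
#' @return data frame with `pi_position`, `frame` and one column per lane.
#' @export
sapphire_table <- function(ordering, lanes = list()) {
  n <- length(ordering)
  out <- data.frame(pi_position = seq_len(n), frame = ordering)
  for (nm in names(lanes)) {
    lane <- lanes[[nm]]
    if (length(lane) != n) stop(sprintf("lane '%s' length mismatch", nm))
    out[[nm]] <- lane[ordering]
  }
  out
}
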