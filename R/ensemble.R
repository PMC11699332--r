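#' Tree-connected replica ensemble container
#'
#' A `replica_ensemble` holds a set of trajectory replicas together with the
#' bookkeeping produced by adaptive reseeding: per-frame times, a categorical
#' system label per replica, per-frame scalar observables, and parent links
#' recording where a reseeded replica branched off its parent lineage.
#'
#' @param frames list with one element per replica: either an integer vector
#'   of state indices or a numeric matrix (frames x features).
#' @param times list of per-replica frame times (strictly increasing); by
#'   default frames are numbered `1..n` within each replica.
#' @param labels character vector, one system label per replica.
#' @param parents data frame with columns `replica`, `parent`, `branch_frame`
#'   (one row per replica that was reseeded). `branch_frame` indexes the
#'   parent's own frames; the child's first frame is the dynamical successor
#'   of that parent frame.
#' @param observables named list of per-frame scalar traces; each element is a
#'   list of numeric vectors aligned with `frames`.
#' @param label_set declared finite set of admissible labels (defaults to the
#'   labels present).
#'
#' @return an object of class `replica_ensemble`.
#' @export
replica_ensemble <- function(frames, times = NULL, labels = NULL,
                             parents = NULL, observables = NULL,
                             label_set = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  nfr <- vapply(frames, frame_count, integer(1))
  if (is.null(times)) times <- lapply(nfr, seq_len)
  if (is.null(labels)) labels <- rep("system", length(frames))
  if (is.null(label_set)) label_set <- unique(labels)
  if (is.null(parents)) {
    parents <- data.frame(replica = integer(0), parent = integer(0),
                          branch_frame = integer(0))
  }
  obj <- structure(list(frames = frames, times = times,
                        labels = as.character(labels),
                        parents = parents, observables = observables,
                        label_set = label_set),
                   class = "replica_ensemble")
  validate_ensemble(obj)
  obj
}

frame_count <- function(x) if (is.matrix(x)) nrow(x) else length(x)

#' @export
print.replica_ensemble <- function(x, ...) {
  nfr <- vapply(x$frames, frame_count, integer(1))
  cat(sprintf("replica_ensemble: %d replicas, %d frames total\n",
              length(x$frames), sum(nfr)))
  cat(sprintf("  labels: %s\n", paste(x$label_set, collapse = ", ")))
  cat(sprintf("  parent links: %d; observables: %s\n", nrow(x$parents),
              if (is.null(x$observables)) "none"
              else paste(names(x$observables), collapse = ", ")))
  invisible(x)
}

validate_ensemble <- function(ens) {
  nfr <- vapply(ens$frames, frame_count, integer(1))
  if (length(ens$labels) != length(ens$frames))
    stop("one label per replica required")
  if (!all(ens$labels %in% ens$label_set))
    stop("labels outside the declared label set")
  for (r in seq_along(ens$frames)) {
    tt <- ens$times[[r]]
    if (length(tt) != nfr[r]) stop("times misaligned with frames")
    if (nfr[r] > 1L && any(diff(tt) <= 0))
      stop(sprintf("times not strictly increasing in replica %d", r))
  }
  p <- ens$parents
  if (nrow(p) > 0L) {
    if (any(p$replica < 1L | p$replica > length(ens$frames)) ||
        any(p$parent < 1L | p$parent > length(ens$frames)))
      stop("parent link references an unknown replica")
    if (any(p$branch_frame < 1L) || any(p$branch_frame > nfr[p$parent]))
      stop("branch frame does not exist in parent replica")
    if (anyDuplicated(p$replica)) stop("a replica may have only one parent")
  }
  if (!is.null(ens$observables)) {
    for (nm in names(ens$observables)) {
      ob <- ens$observables[[nm]]
      if (length(ob) != length(ens$frames) ||
          !all(vapply(ob, length, integer(1)) == nfr))
        stop(sprintf("observable '%s' misaligned with frames", nm))
    }
  }
  invisible(TRUE)
}

#' Total number of frames in an ensemble
#' @param ens a [replica_ensemble()].
#' @return integer frame count summed over replicas.
#' @export
total_frames <- function(ens) sum(vapply(ens$frames, frame_count, integer(1)))

#' Global frame index table
#'
#' Frames are numbered consecutively replica by replica; this table maps the
#' global index used by the progress-index and SAPPHIRE tools back to
#' (replica, frame-within-replica, time, label).
#'
#' @param ens a [replica_ensemble()].
#' @return data frame with columns `global`, `replica`, `frame`, `time`,
#'   `label`.
#' @export
frame_table <- function(ens) {
  nfr <- vapply(ens$frames, frame_count, integer(1))
  data.frame(global = seq_len(sum(nfr)),
             replica = rep(seq_along(ens$frames), nfr),
             frame = unlist(lapply(nfr, seq_len), use.names = FALSE),
             time = unlist(ens$times, use.names = FALSE),
             label = rep(ens$labels, nfr))
}

#' Pool replica frames into a single matrix
#' @param ens a [replica_ensemble()] whose frames are feature vectors.
#' @return numeric matrix (total frames x features), rows ordered as in
#'   [frame_table()].
#' @export
pooled_frames <- function(ens) {
  if (!is.matrix(ens$frames[[1]]))
    return(matrix(unlist(ens$frames, use.names = FALSE), ncol = 1))
  do.call(rbind, ens$frames)
}

#' Time-adjacent frame pairs, respecting reseeding connectivity
#'
#' Returns all pairs of frames that are dynamically adjacent in the original
#' time progression: consecutive frames within a replica's own segment, plus
#' the pair joining a parent's branch frame to the first frame of each child
#' reseeded from it. Used by the kinetic cut function.
#'
#' @param ens a [replica_ensemble()].
#' @return two-column integer matrix of global frame indices.
#' @export
adjacent_pairs <- function(ens) {
  nfr <- vapply(ens$frames, frame_count, integer(1))
  offs <- c(0L, cumsum(nfr))
  pairs <- vector("list", length(ens$frames) + nrow(ens$parents))
  k <- 0L
  for (r in seq_along(ens$frames)) {
    if (nfr[r] > 1L) {
      idx <- offs[r] + seq_len(nfr[r])
      k <- k + 1L
      pairs[[k]] <- cbind(idx[-nfr[r]], idx[-1L])
    }
  }
  p <- ens$parents
  for (i in seq_len(nrow(p))) {
    k <- k + 1L
    pairs[[k]] <- cbind(offs[p$parent[i]] + p$branch_frame[i],
                        offs[p$replica[i]] + 1L)
  }
  out <- do.call(rbind, pairs[seq_len(k)])
  if (is.null(out)) out <- matrix(integer(0), ncol = 2)
  out
}

# deterministic per-replica RNG stream: changing the replica count never
# perturbs the streams of existing replicas
replica_seed <- function(seed, replica) {
  as.integer((as.double(seed) * 48271 + replica * 16807) %% 2147483647)
}
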