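#' Multi-resolution tree clustering by leader descent
#'
#' Streaming tree clustering in Euclidean feature space: each frame descends
#' the tree from the coarsest level, joining at every level the first
#' existing child node (in creation order) whose leader lies within the level
#' radius, otherwise spawning a new node led by the frame itself. Level radii
#' are spaced geometrically from `r_max` (coarsest) down to `r_min`
#' (leaves). The result is deterministic given the input frame order; set
#' `shuffle_seed` for a seeded-shuffle sensitivity check.
#'
#' @param X numeric matrix (frames x features).
#' @param r_min leaf-level cluster radius (default 0.2).
#' @param r_max coarsest cluster radius (default 3.5).
#' @param n_levels number of tree levels (default 8; 1 = flat leader
#'   clustering at `r_min`).
#' @param shuffle_seed optional seed for shuffling the insertion order (the
#'   stored assignments are always reported in original frame order).
#' @return object of class `tree_clustering`: `radii`, `nodes` (data frame
#'   `id`, `level`, `parent`, `leader` frame index), `path` (frames x levels
#'   node-id matrix), `assignments` (leaf node per frame) and `leaders`
#'   (leader coordinates by node id).
#' @export
tree_cluster <- function(X, r_min = 0.2, r_max = 3.5, n_levels = 8,
                         shuffle_seed = NULL) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop("empty input")
  if (n_levels < 1L) stop("n_levels must be >= 1")
  if (n_levels > 1L && r_min >= r_max) stop("require r_min < r_max")
  radii <- if (n_levels == 1L) r_min else
    exp(seq(log(r_max), log(r_min), length.out = n_levels))
  order_in <- seq_len(nrow(X))
  if (!is.null(shuffle_seed)) {
    set.seed(as.integer(shuffle_seed))
    order_in <- sample(order_in)
  }
  nodes_level <- integer(0); nodes_parent <- integer(0)
  nodes_leader <- integer(0)
  children <- list() # by node id; index 0 handled via roots
  roots <- integer(0)
  leaders <- list()
  path <- matrix(NA_integer_, nrow(X), n_levels)
  new_node <- function(level, parent, frame) {
    id <- length(nodes_level) + 1L
    nodes_level[id] <<- level; nodes_parent[id] <<- parent
    nodes_leader[id] <<- frame
    children[[id]] <<- integer(0)
    leaders[[id]] <<- X[frame, ]
    if (parent == 0L) roots[length(roots) + 1L] <<- id
    else children[[parent]] <<- c(children[[parent]], id)
    id
  }
  for (f in order_in) {
    x <- X[f, ]
    parent <- 0L
    for (lev in seq_len(n_levels)) {
      cand <- if (parent == 0L) roots else children[[parent]]
      hit <- 0L
      if (length(cand) > 0L) {
        ldr <- matrix(unlist(leaders[cand], use.names = FALSE),
                      ncol = ncol(X), byrow = TRUE)
        d2 <- rowSums((ldr - matrix(x, length(cand), ncol(X),
                                    byrow = TRUE))^2)
        ok <- which(d2 <= radii[lev]^2)
        if (length(ok) > 0L) hit <- cand[ok[1L]]
      }
      if (hit == 0L) hit <- new_node(lev, parent, f)
      path[f, lev] <- hit
      parent <- hit
    }
  }
  structure(list(radii = radii, n_levels = n_levels,
                 nodes = data.frame(id = seq_along(nodes_level),
                                    level = nodes_level,
                                    parent = nodes_parent,
                                    leader = nodes_leader),
                 children = children, roots = roots, leaders = leaders,
                 path = path, assignments = path[, n_levels],
                 insertion_order = order_in),
            class = "tree_clustering")
}

#' @export
print.tree_clustering <- function(x, ...) {
  cat(sprintf("tree_clustering: %d frames, %d levels (radii %.4g .. %.4g), %d leaves\n",
              nrow(x$path), x$n_levels, x$radii[1], x$radii[x$n_levels],
              length(unique(x$assignments))))
  invisible(x)
}

#' Re-assign frames through a fitted clustering tree
#'
#' Descends the fitted tree with the same first-match rule used during
#' construction; frames seen during fitting reproduce their stored
#' assignments exactly.
#'
#' @param model a [tree_cluster()] model.
#' @param X numeric matrix of frames to assign.
#' @param level tree level of the returned assignments (default: leaves).
#' @return integer vector of node ids (`NA` where a frame matches no node
#'   within the level radius).
#' @export
assign_frames <- function(model, X, level = model$n_levels) {
  X <- as.matrix(X)
  out <- integer(nrow(X))
  for (f in seq_len(nrow(X))) {
    x <- X[f, ]
    parent <- 0L
    for (lev in seq_len(level)) {
      cand <- if (parent == 0L) model$roots else model$children[[parent]]
      cand <- cand[model$nodes$level[cand] == lev]
      hit <- NA_integer_
      if (length(cand) > 0L) {
        ldr <- matrix(unlist(model$leaders[cand], use.names = FALSE),
                      ncol = ncol(X), byrow = TRUE)
        d2 <- rowSums((ldr - matrix(x, length(cand), ncol(X),
                                    byrow = TRUE))^2)
        ok <- which(d2 <= model$radii[lev]^2)
        if (length(ok) > 0L) hit <- cand[ok[1L]]
      }
      if (is.na(hit)) { parent <- NA_integer_; break }
      parent <- hit
    }
    out[f] <- parent
  }
  out
}

#' Fold the outermost leaf layers onto their parents
#'
#' Re-expresses assignments at tree level `n_levels - n_layers`, coarsening
#' the partition while conserving every frame.
#'
#' @param model a [tree_cluster()] model.
#' @param n_layers number of leaf layers to fold inward (default 3; 0 is the
#'   identity).
#' @return a `tree_clustering` truncated to the coarser level.
#' @export
fold_leaf_layers <- function(model, n_layers = 3) {
  if (n_layers == 0L) return(model)
  if (n_layers >= model$n_levels)
    stop("n_layers must be smaller than the number of levels")
  lev <- model$n_levels - n_layers
  out <- model
  out$n_levels <- lev
  out$radii <- model$radii[seq_len(lev)]
  # node table keeps all ids (ids index rows); deeper nodes become inert
  out$children <- lapply(model$children, function(ch)
    ch[model$nodes$level[ch] <= lev])
  out$path <- model$path[, seq_len(lev), drop = FALSE]
  out$assignments <- out$path[, lev]
  out
}

#' Medoid frame of every cluster
#'
#' The member frame minimizing the summed Euclidean distance to all other
#' members — an actual snapshot usable as the cluster's representative
#' ("centroid snapshot"). Ties break to the lowest frame index.
#'
#' @param model a [tree_cluster()] model (leaf assignments are used).
#' @param X the feature matrix the model was fitted on.
#' @return named integer vector: cluster id -> medoid frame index.
#' @export
medoid_frames <- function(model, X) {
  X <- as.matrix(X)
  groups <- split(seq_len(nrow(X)), model$assignments)
  out <- vapply(groups, function(idx) {
    if (length(idx) == 1L) return(idx)
    sub <- X[idx, , drop = FALSE]
    d <- as.matrix(dist(sub))
    idx[which.min(rowSums(d))]
  }, integer(1))
  out
}

#' Pairwise distances between cluster medoids
#'
#' @param model a [tree_cluster()] model.
#' @param X the feature matrix the model was fitted on.
#' @return symmetric distance matrix with cluster ids as dimnames.
#' @export
medoid_distances <- function(model, X) {
  med <- medoid_frames(model, X)
  d <- as.matrix(dist(as.matrix(X)[med, , drop = FALSE]))
  dimnames(d) <- list(names(med), names(med))
  d
}
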