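#' Periodicity-safe principal components of dihedral-angle trajectories
#'
#' Each angle column (degrees) is expanded to its sine and cosine before PCA,
#' so clusters straddling the +/-180 degree seam stay compact.
#'
#' @param angles numeric matrix (frames x angles, degrees) with named
#'   columns.
#' @param k number of components to keep (default 10).
#' @return as [pca_reduce()], with loadings over the (sin, cos) expansion.
#' @export
dihedral_pca <- function(angles, k = 10) {
  angles <- as.matrix(angles)
  if (nrow(angles) < 2L) stop("need at least two frames")
  if (k > 2L * ncol(angles)) stop("k exceeds twice the angle count")
  rad <- angles * pi / 180
  expanded <- cbind(sin(rad), cos(rad))
  nm <- colnames(angles)
  if (is.null(nm)) nm <- paste0("angle", seq_len(ncol(angles)))
  colnames(expanded) <- c(paste0("sin_", nm), paste0("cos_", nm))
  pca_reduce(expanded, k = k)
}

# 36-degree pseudorotation sectors, counter-clockwise from P = 0
pucker_sectors <- c("C3'-endo", "C4'-exo", "O4'-endo", "C1'-exo", "C2'-endo",
                    "C3'-exo", "C4'-endo", "O4'-exo", "C1'-endo", "C2'-exo")

#' Sugar-pucker pseudorotation phase and amplitude
#'
#' Altona-Sundaralingam convention from the five ring torsions nu0..nu4
#' (degrees): `tan P = ((nu4 + nu1) - (nu3 + nu0)) / (2 nu2 (sin 36 + sin
#' 72))`, amplitude `tau_m = nu2 / cos P`. The canonical RNA modes map to
#' `P in [0, 36)` (C3'-endo) and `P in [144, 180)` (C2'-endo); other phases
#' are labelled by their 36-degree sector.
#'
#' @param nu numeric vector of the five ring torsions (degrees) or a matrix
#'   with five columns (one row per frame).
#' @param tol amplitude below which the ring is treated as planar and the
#'   phase undefined (default 1 degree).
#' @return data frame with `P` (phase, degrees in `[0, 360)`), `tau_m`
#'   (amplitude, degrees) and `class`.
#' @export
pseudorotation <- function(nu, tol = 1) {
  nu <- if (is.matrix(nu)) nu else matrix(nu, nrow = 1)
  if (ncol(nu) != 5L) stop("five ring torsions required")
  num <- (nu[, 5] + nu[, 2]) - (nu[, 4] + nu[, 1])
  den <- 2 * nu[, 3] * (sin(36 * pi / 180) + sin(72 * pi / 180))
  P <- atan2(num, den) * 180 / pi
  tau_m <- nu[, 3] / cos(P * pi / 180)
  planar <- !is.finite(tau_m) | abs(tau_m) <= tol
  if (any(planar)) stop("phase undefined: planar ring (amplitude ~ 0)")
  P <- P %% 360
  cls <- pucker_sectors[floor(P / 36) + 1L]
  data.frame(P = P, tau_m = tau_m, class = cls)
}

#' Ring torsions from pseudorotation parameters
#'
#' Generating formula `nu_j = tau_m * cos(P + 144 (j - 2))`, `j = 0..4`;
#' the round-trip inverse of [pseudorotation()].
#'
#' @param P phase (degrees).
#' @param tau_m amplitude (degrees).
#' @return numeric vector nu0..nu4 (degrees).
#' @export
pucker_torsions <- function(P, tau_m) {
  j <- 0:4
  tau_m * cos((P + 144 * (j - 2)) * pi / 180)
}

#' Kullback-Leibler divergence between two histograms
#'
#' `sum_i p_i log(p_i / q_i)` in nats after pseudocount regularization and
#' renormalization of both histograms.
#'
#' @param p,q non-negative count/weight vectors over the same bins; if named
#'   or carrying a `breaks` attribute, binning identity is checked.
#' @param pseudocount weight added to every bin before normalization
#'   (required > 0 when any `q` bin is empty).
#' @return divergence in nats (>= 0).
#' @export
kl_divergence <- function(p, q, pseudocount = 0) {
  if (length(p) != length(q)) stop("mismatched bin counts")
  if (!is.null(names(p)) && !is.null(names(q)) && !identical(names(p), names(q)))
    stop("mismatched bin edges")
  bp <- attr(p, "breaks"); bq <- attr(q, "breaks")
  if (!is.null(bp) && !is.null(bq) && !isTRUE(all.equal(bp, bq)))
    stop("mismatched bin edges")
  if (any(q == 0) && pseudocount <= 0)
    stop("empty reference bins: a positive pseudocount is required")
  p <- p + pseudocount; q <- q + pseudocount
  p <- p / sum(p); q <- q / sum(q)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / q[nz]))
}

#' Pairwise mutual information between dihedral angles
#'
#' Plug-in mutual information (nats) from 2-D histograms on equal-width
#' periodic bins spanning (-180, 180]; the diagonal carries the marginal
#' entropies. The Miller-Madow bias estimate `(K_xy - K_x - K_y + 1)/(2n)`
#' is attached as the `"bias"` attribute, since plug-in MI inflates coupling
#' on finite samples.
#'
#' @param angles numeric matrix (frames x angles, degrees).
#' @param bins number of bins per angle (default 24, >= 2).
#' @return symmetric matrix of mutual information (nats) with attribute
#'   `"bias"` (matrix of Miller-Madow corrections to subtract).
#' @export
mutual_information_matrix <- function(angles, bins = 24) {
  angles <- as.matrix(angles)
  if (ncol(angles) < 2L) stop("need at least two angles")
  if (bins < 2L) stop("bins must be >= 2")
  n <- nrow(angles)
  edges <- seq(-180, 180, length.out = bins + 1L)
  wrap <- ((angles + 180) %% 360) - 180
  idx <- matrix(findInterval(wrap, edges, all.inside = TRUE), nrow = n)
  d <- ncol(angles)
  ent <- function(counts) {
    p <- counts / sum(counts); p <- p[p > 0]
    -sum(p * log(p))
  }
  H <- vapply(seq_len(d), function(i) ent(tabulate(idx[, i], bins)),
              numeric(1))
  mi <- diag(H, d); bias <- matrix(0, d, d)
  for (i in seq_len(d - 1L)) {
    for (j in (i + 1L):d) {
      joint <- tabulate((idx[, i] - 1L) * bins + idx[, j], bins * bins)
      Hij <- ent(joint)
      mi[i, j] <- mi[j, i] <- H[i] + H[j] - Hij
      k_xy <- sum(joint > 0)
      k_x <- sum(tabulate(idx[, i], bins) > 0)
      k_y <- sum(tabulate(idx[, j], bins) > 0)
      bias[i, j] <- bias[j, i] <- (k_xy - k_x - k_y + 1) / (2 * n)
    }
  }
  dimnames(mi) <- list(colnames(angles), colnames(angles))
  structure(mi, bias = bias)
}

#' Per-group relative cluster populations
#'
#' Cross-tabulates cluster assignments against group labels (e.g. force
#' field x methylation state) and reports, for the `top_n` globally most
#' populated clusters, each group's relative weight. Weights within a group
#' sum to 1 over all clusters.
#'
#' @param assignments integer/character cluster labels per frame.
#' @param groups group label per frame, aligned with `assignments`.
#' @param top_n number of clusters to report, ordered by total weight.
#' @return data frame: `cluster`, `total_weight`, one relative-weight column
#'   per group.
#' @export
cluster_population_report <- function(assignments, groups, top_n = 10) {
  if (length(assignments) != length(groups))
    stop("labels not aligned with assignments")
  tab <- table(cluster = assignments, group = groups)
  rel <- sweep(tab, 2, colSums(tab), "/")
  total <- rowSums(tab) / sum(tab)
  ord <- order(-total)
  keep <- head(ord, top_n)
  out <- data.frame(cluster = rownames(tab)[keep],
                    total_weight = as.numeric(total[keep]))
  for (g in colnames(rel)) out[[g]] <- as.numeric(rel[keep, g])
  out
}
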