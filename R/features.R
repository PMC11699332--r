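#' Residue-residue contact frequencies over a frame window
#'
#' A residue pair is in contact in a frame when the minimum distance between
#' any of their heavy atoms is strictly below `cutoff`. Frequencies are the
#' fraction of window frames in contact.
#'
#' @param coords data frame with columns `frame`, `residue`, `atom`, `x`,
#'   `y`, `z` (one row per heavy atom per frame).
#' @param cutoff contact cutoff in Angstrom (default 5; strict `<`).
#' @param window frame numbers to include (default: all frames present).
#' @return object of class `contact_map`: data frame with `res_i`, `res_j`
#'   (`res_i < res_j` by order of appearance), `frequency`, plus `cutoff` and
#'   `window` attributes.
#' @export
contact_frequencies <- function(coords, cutoff = 5, window = NULL) {
  req <- c("frame", "residue", "atom", "x", "y", "z")
  if (!all(req %in% names(coords))) stop("coords must have columns: ",
                                         paste(req, collapse = ", "))
  if (is.null(window)) window <- sort(unique(coords$frame))
  coords <- coords[coords$frame %in% window, , drop = FALSE]
  if (nrow(coords) == 0L) stop("empty frame window")
  residues <- unique(coords$residue)
  if (length(residues) < 2L) stop("need at least two residues")
  frames <- sort(unique(coords$frame))
  pairs <- t(utils::combn(length(residues), 2))
  hits <- matrix(0, nrow(pairs), 1)
  for (f in frames) {
    fc <- coords[coords$frame == f, , drop = FALSE]
    xyz <- split(as.matrix(fc[, c("x", "y", "z")]),
                 factor(fc$residue, levels = residues))
    xyz <- lapply(xyz, function(v) matrix(v, ncol = 3))
    for (k in seq_len(nrow(pairs))) {
      a <- xyz[[pairs[k, 1]]]; b <- xyz[[pairs[k, 2]]]
      if (is.null(a) || is.null(b) || nrow(a) == 0L || nrow(b) == 0L)
        stop("residue without atoms in frame ", f)
      d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
      if (min(d2) < cutoff^2) hits[k] <- hits[k] + 1
    }
  }
  out <- data.frame(res_i = residues[pairs[, 1]],
                    res_j = residues[pairs[, 2]],
                    frequency = as.numeric(hits) / length(frames))
  structure(out, cutoff = cutoff, window = range(window),
            class = c("contact_map", "data.frame"))
}

#' Residue pairs whose contact frequency changes across two windows
#'
#' Retains pairs whose absolute contact-frequency difference between an early
#' and a late window strictly exceeds `threshold`; an explicit exclude list
#' replaces by-hand pruning of uninformative pairs (e.g. termini).
#'
#' @param map_early,map_late [contact_frequencies()] maps over the same
#'   residue universe and cutoff.
#' @param threshold strict differential threshold (default 0.35).
#' @param exclude optional two-column matrix/data frame of residue pairs to
#'   drop regardless of the differential.
#' @return data frame of retained pairs with both frequencies and the
#'   absolute difference.
#' @export
differential_contact_pairs <- function(map_early, map_late, threshold = 0.35,
                                       exclude = NULL) {
  key <- function(m) paste(m$res_i, m$res_j, sep = "\r")
  if (!identical(sort(key(map_early)), sort(key(map_late))))
    stop("contact maps cover different residue pairs")
  if (!identical(attr(map_early, "cutoff"), attr(map_late, "cutoff")))
    stop("contact maps built with different cutoffs")
  late <- map_late[match(key(map_early), key(map_late)), ]
  out <- data.frame(res_i = map_early$res_i, res_j = map_early$res_j,
                    freq_early = map_early$frequency,
                    freq_late = late$frequency,
                    abs_diff = abs(map_early$frequency - late$frequency))
  # strict threshold with a guard against floating-point noise at the cut
  out <- out[out$abs_diff - threshold > 1e-9, , drop = FALSE]
  if (!is.null(exclude) && nrow(out) > 0L) {
    exc <- apply(exclude, 1, function(p)
      paste(sort(as.character(p)), collapse = "\r"))
    own <- mapply(function(a, b) paste(sort(c(a, b)), collapse = "\r"),
                  out$res_i, out$res_j)
    out <- out[!(own %in% exc), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Expand retained residue pairs into interatomic distance descriptors
#'
#' For protein residues, the alpha carbon and the most distant side-chain
#' heavy atom represent the residue (glycine collapses to the alpha carbon
#' alone); for RNA residues, C4', O3' and the glycosidic nitrogen (N9 for
#' purines, N1 for pyrimidines). The exhaustive atom-pair cross product
#' yields 4 features per protein-protein pair, 9 per RNA-RNA pair and 6 per
#' intermolecular pair.
#'
#' @param pairs data frame with columns `res_i`, `res_j` (residue names).
#' @param residue_info data frame with columns `residue`, `kind` (one of
#'   `"protein"`, `"purine"`, `"pyrimidine"`) and `sidechain_atom` (most
#'   distant side-chain heavy atom for protein residues; `NA` for glycine).
#' @return data frame of feature descriptors: `res_i`, `atom_i`, `res_j`,
#'   `atom_j`, `kind` (intra-protein / intra-RNA / intermolecular).
#' @export
atom_pair_features <- function(pairs, residue_info) {
  atoms_for <- function(res) {
    row <- residue_info[residue_info$residue == res, , drop = FALSE]
    if (nrow(row) != 1L) stop("residue not annotated: ", res)
    switch(row$kind,
      protein = {
        sc <- row$sidechain_atom
        if (is.na(sc) || !nzchar(sc)) "CA" else unique(c("CA", sc))
      },
      purine = c("C4'", "O3'", "N9"),
      pyrimidine = c("C4'", "O3'", "N1"),
      stop("unknown residue kind for ", res))
  }
  kind_of <- function(res)
    if (residue_info$kind[residue_info$residue == res] == "protein")
      "protein" else "rna"
  out <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    ri <- as.character(pairs$res_i[k]); rj <- as.character(pairs$res_j[k])
    ai <- atoms_for(ri); aj <- atoms_for(rj)
    grid <- expand.grid(atom_i = ai, atom_j = aj, stringsAsFactors = FALSE)
    kind <- if (kind_of(ri) == "protein" && kind_of(rj) == "protein")
      "intra-protein" else if (kind_of(ri) == "rna" && kind_of(rj) == "rna")
        "intra-RNA" else "intermolecular"
    out[[k]] <- data.frame(res_i = ri, atom_i = grid$atom_i, res_j = rj,
                           atom_j = grid$atom_j, kind = kind)
  }
  do.call(rbind, out)
}

#' Sigmoidal distance transform
#'
#' `phi(x) = 1 - (1 + exp(-(x - chi)/tau_s))^{-1}`: strictly decreasing,
#' 0.5 at the midpoint `chi`, approaching 1 for short and 0 for long
#' distances. With the defaults (`chi` = 15 A, `tau_s` = 2.5 A) the curve is
#' roughly linear around 15 A and within 2% of its asymptotes at 5 and 25 A,
#' homogenizing the unbound state.
#'
#' @param x distances (vector or matrix; applied elementwise).
#' @param chi midpoint in Angstrom.
#' @param tau_s smoothness in Angstrom (> 0).
#' @return transformed values in (0, 1), same shape as `x`.
#' @export
sigmoid_transform <- function(x, chi = 15, tau_s = 2.5) {
  if (tau_s <= 0) stop("tau_s must be positive")
  1 / (1 + exp((x - chi) / tau_s))
}

#' Principal-component reduction of a feature matrix
#'
#' Columns are centred (no variance scaling: sigmoid features already share
#' the (0,1) scale) and projected onto the top `k` components.
#'
#' @param features numeric matrix (frames x features).
#' @param k number of components to keep (default 7).
#' @return list with `scores` (frames x k), `loadings` (features x k,
#'   orthonormal), `explained` (per-component variance fractions) and
#'   `center`.
#' @export
pca_reduce <- function(features, k = 7) {
  features <- as.matrix(features)
  if (k > ncol(features)) stop("k exceeds the feature count")
  if (nrow(features) <= k) stop("need more frames than components")
  p <- prcomp(features, center = TRUE, scale. = FALSE)
  expl <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x[, seq_len(k), drop = FALSE],
       loadings = p$rotation[, seq_len(k), drop = FALSE],
       explained = expl[seq_len(k)], center = p$center)
}
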