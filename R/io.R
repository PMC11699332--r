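fmt_num <- function(x) {
  if (is.integer(x) || is.character(x)) return(x)
  sprintf("%.17g", x) # full double precision for lossless round-trips
}

#' Write a replica ensemble as TSV with a parent-link sidecar
#'
#' Frames go to `<path>_frames.tsv` (columns: replica, frame, time, label,
#' then `state` for discrete ensembles or `f1..fd` for feature frames, plus
#' one `obs_*` column per observable); parent links go to
#' `<path>_parents.tsv` (replica, parent, branch_frame). Numeric values are
#' written at full double precision so the round-trip is lossless.
#'
#' @param ensemble a [replica_ensemble()].
#' @param path file path prefix.
#' @return the two file paths, invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  ft <- frame_table(ensemble)
  discrete <- !is.matrix(ensemble$frames[[1]])
  if (discrete) {
    ft$state <- unlist(ensemble$frames, use.names = FALSE)
  } else {
    M <- pooled_frames(ensemble)
    colnames(M) <- paste0("f", seq_len(ncol(M)))
    ft <- cbind(ft, as.data.frame(M))
  }
  for (nm in names(ensemble$observables))
    ft[[paste0("obs_", nm)]] <- unlist(ensemble$observables[[nm]],
                                       use.names = FALSE)
  ft$global <- NULL
  out <- as.data.frame(lapply(ft, fmt_num), stringsAsFactors = FALSE)
  names(out) <- names(ft)
  f1 <- paste0(path, "_frames.tsv"); f2 <- paste0(path, "_parents.tsv")
  write.table(out, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ensemble$parents, f2, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(frames = f1, parents = f2))
}

#' Read a replica ensemble written by [write_ensemble()]
#'
#' @param path file path prefix used at write time.
#' @return a [replica_ensemble()].
#' @export
read_ensemble <- function(path) {
  f1 <- paste0(path, "_frames.tsv"); f2 <- paste0(path, "_parents.tsv")
  ft <- read.table(f1, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  for (col in c("replica", "frame", "time", "label"))
    if (!col %in% names(ft)) stop("missing column in frames table: ", col)
  parents <- if (file.exists(f2)) {
    p <- read.table(f2, sep = "\t", header = TRUE)
    for (col in c("replica", "parent", "branch_frame"))
      if (!col %in% names(p))
        stop("malformed parent link table: missing ", col)
    p
  } else NULL
  reps <- sort(unique(ft$replica))
  fcols <- grep("^f[0-9]+$", names(ft), value = TRUE)
  ocols <- grep("^obs_", names(ft), value = TRUE)
  frames <- vector("list", length(reps)); times <- frames
  labels <- character(length(reps))
  obs <- setNames(replicate(length(ocols), vector("list", length(reps)),
                            simplify = FALSE), sub("^obs_", "", ocols))
  for (k in seq_along(reps)) {
    rows <- ft[ft$replica == reps[k], , drop = FALSE]
    rows <- rows[order(rows$frame), , drop = FALSE]
    frames[[k]] <- if (length(fcols) > 0L)
      as.matrix(rows[, fcols, drop = FALSE]) else as.integer(rows$state)
    times[[k]] <- rows$time
    labels[k] <- rows$label[1]
    for (oc in ocols) obs[[sub("^obs_", "", oc)]][[k]] <- rows[[oc]]
  }
  if (length(fcols) > 0L)
    frames <- lapply(frames, function(m) { dimnames(m) <- NULL; m })
  replica_ensemble(frames, times = times, labels = labels,
                   parents = parents,
                   observables = if (length(ocols)) obs else NULL)
}

#' Write a sparse count/transition matrix in Matrix Market format
#' @param counts a `count_matrix` or sparse Matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_counts_mtx <- function(counts, path) {
  M <- if (inherits(counts, "count_matrix")) counts$C else counts
  Matrix::writeMM(methods::as(M, "generalMatrix"), path)
  invisible(path)
}

#' Read a Matrix Market file as a count matrix
#' @param path file written by [write_counts_mtx()].
#' @param lag lag in frames to attach (default 1).
#' @return a `count_matrix`.
#' @export
read_counts_mtx <- function(path, lag = 1L) {
  structure(list(C = methods::as(Matrix::readMM(path), "CsparseMatrix"),
                 lag = as.integer(lag), pseudocount_mass = 0),
            class = "count_matrix")
}

#' Pipeline configuration with the method's default thresholds
#'
#' Every stage parameter in one nested list: contact cutoff 5 A and
#' differential threshold 0.35; sigmoid midpoint chi = 15 A and smoothness
#' tau_s = 2.5 A; 7 retained components; tree-clustering radii 0.2-3.5 with
#' 8 levels and 3 folded leaf layers; MSM lag 1 frame (1 ns per frame by
#' convention) with geometric pseudocounts at bin width 0.002; unbound
#' definition 25 A, unbinding event threshold 10 A, committor threshold 0.5;
#' bootstrap 1% removal, 20 repeats, 90% level; SAPPHIRE cut window 10000
#' and mixing-entropy window 2000.
#'
#' @param ... named overrides, e.g. `msm = list(lag = 2)` (merged
#'   shallowly per section).
#' @return nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    system = "chain",
    synth = list(n_metastable = 2L, p_intra = 0.15, p_escape = 0.002,
                 p_return = 0.04, block_size = 3L,
                 n_replicas = 64L, n_steps = 2000L,
                 reseed_interval = 0L, reseed_fraction = 0,
                 funnel = list(barrier_height = 8, barrier_radius = 8,
                               n_channels = 4L, channel_contrast = 0.25,
                               diffusion = 1, wall_radius = 30, wall_k = 2),
                 dt = 0.01, kT = 1),
    features = list(contact_cutoff = 5, diff_threshold = 0.35,
                    chi = 15, tau_s = 2.5, n_components = 7L),
    cluster = list(r_min = 0.2, r_max = 3.5, n_levels = 8L,
                   fold_layers = 3L),
    msm = list(lag = 1L, time_per_frame = 1, pseudo_mass = 0.5,
               bin_width = 0.002, neighbor_quantile = 0.1),
    tpt = list(u_cutoff = 25, unbind_threshold = 10,
               committor_threshold = 0.5, concentration = 1),
    bootstrap = list(removal_fraction = 0.01, repeats = 20L, level = 0.90),
    sapphire = list(cut_window = 10000L, entropy_window = 2000L),
    pigs = list(n_replicas = 64L, decision_interval = 100L,
                max_reseed = 32L, redundancy_radius = 2,
                history_window = 20L),
    rna = list(n_components = 10L, cluster_radius = 2.159, mi_bins = 24L,
               top_n = 10L)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Write / read a pipeline configuration as YAML
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `read_config` returns a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_config(config, tmp)
  unname(tools::md5sum(tmp))
}
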