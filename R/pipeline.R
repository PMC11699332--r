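#' Run the analysis pipeline
#'
#' Composes the package's stages under a single [pipeline_config()]:
#'
#' * `synth` — generate the synthetic ensemble (discrete metastable chain or
#'   2-D Langevin binding funnel) with reseeding-tree connectivity.
#' * `featurize` — sigmoid-transform the frame coordinates and reduce by PCA
#'   (continuous ensembles; discrete ensembles pass through).
#' * `cluster` — multi-resolution tree clustering with leaf folding.
#' * `msm` — sliding-window transition counts (tree-aware), geometric
#'   pseudocounts, model estimation.
#' * `tpt` — boundary states, committors, reactive flux, rate constants and
#'   bootstrap confidence intervals.
#' * `sapphire` — progress index, kinetic cut profile and mixing entropy.
#' * `pigs-sim` — run the PIGS controller on the funnel propagator.
#' * `rna-compare` — dihedral PCA, joint clustering, population table, KL
#'   divergence and mutual information for two or more angle ensembles
#'   (supplied as `config$rna$angles`, a named list of matrices).
#'
#' Stages run in the order given, consuming upstream artifacts from the
#' returned list; when `out_dir` is set, each stage also writes its
#' artifacts (TSV / Matrix Market) plus a `provenance_<stage>.yaml` record
#' with the config hash, seed and package version.
#'
#' @param config a [pipeline_config()].
#' @param stages character vector of stage names, run in order.
#' @param out_dir optional output directory for file artifacts.
#' @param artifacts artifact list from a previous call (to resume).
#' @return named artifact list.
#' @export
run_pipeline <- function(config, stages, out_dir = NULL,
                         artifacts = list()) {
  need <- function(nm, stage) {
    if (is.null(artifacts[[nm]]))
      stop(sprintf("stage '%s' needs artifact '%s': run the producing stage first",
                   stage, nm))
    artifacts[[nm]]
  }
  emit <- function(stage, writer) {
    if (is.null(out_dir)) return(invisible(NULL))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writer(out_dir)
    yaml::write_yaml(list(stage = stage, config_md5 = config_hash(config),
                          seed = config$seed,
                          package = as.character(packageVersion("msmpath"))),
                     file.path(out_dir, paste0("provenance_", stage, ".yaml")))
  }
  for (stage in stages) {
    artifacts <- switch(
      stage,
      synth = {
        a <- artifacts
        if (config$system == "chain") {
          sys <- build_chain_system(config$synth$n_metastable,
                                    p_intra = config$synth$p_intra,
                                    p_escape = config$synth$p_escape,
                                    p_return = config$synth$p_return %||%
                                      (20 * config$synth$p_escape),
                                    block_size = config$synth$block_size,
                                    seed = config$seed)
          ens <- sample_markov_trajectories(sys, config$synth$n_replicas,
                                            config$synth$n_steps,
                                            seed = config$seed)
        } else {
          sys <- do.call(funnel_params, config$synth$funnel)
          ens <- langevin_funnel(sys, config$synth$n_replicas,
                                 config$synth$n_steps, dt = config$synth$dt,
                                 kT = config$synth$kT, seed = config$seed)
        }
        if (config$synth$reseed_interval > 0 &&
            config$synth$reseed_fraction > 0)
          ens <- emulate_reseeding_tree(ens, config$synth$reseed_interval,
                                        config$synth$reseed_fraction,
                                        seed = config$seed)
        a$system <- sys; a$ensemble <- ens
        emit("synth", function(d)
          write_ensemble(ens, file.path(d, "ensemble")))
        a
      },
      featurize = {
        a <- artifacts
        ens <- need("ensemble", "featurize")
        if (!is.matrix(ens$frames[[1]])) {
          a$features <- NULL # discrete states need no featurization
          a
        } else {
          # distances to fixed anchor points stand in for the interatomic
          # distance set; the sigmoid homogenizes the unbound region
          M <- pooled_frames(ens)
          anchors <- matrix(c(0, 0, 12, 0, -6, 10.392, -6, -10.392),
                            ncol = 2, byrow = TRUE)
          D2 <- outer(rowSums(M^2), rowSums(anchors^2), "+") -
            2 * M %*% t(anchors)
          Feat <- sigmoid_transform(sqrt(pmax(D2, 0)),
                                    chi = config$features$chi,
                                    tau_s = config$features$tau_s)
          k <- min(config$features$n_components, ncol(Feat))
          a$features <- pca_reduce(Feat, k = k)
          emit("featurize", function(d)
            write.table(a$features$scores, file.path(d, "features.tsv"),
                        sep = "\t", quote = FALSE, row.names = FALSE))
          a
        }
      },
      cluster = {
        a <- artifacts
        ens <- need("ensemble", "cluster")
        if (!is.matrix(ens$frames[[1]])) {
          # discrete chain: states are the discretization
          pooled <- unlist(ens$frames, use.names = FALSE)
          a$assignments <- pooled
          a$cluster_X <- matrix(as.numeric(pooled), ncol = 1)
          a$medoid_obs <- setNames(
            as.numeric(sort(unique(pooled))),
            sort(unique(pooled)))
        } else {
          X <- if (!is.null(a$features)) a$features$scores else
            pooled_frames(ens)
          cm <- tree_cluster(X, r_min = config$cluster$r_min,
                             r_max = config$cluster$r_max,
                             n_levels = config$cluster$n_levels)
          if (config$cluster$fold_layers > 0)
            cm <- fold_leaf_layers(cm, config$cluster$fold_layers)
          a$cluster_model <- cm
          a$cluster_X <- X
          lv <- sort(unique(cm$assignments))
          a$assignments <- match(cm$assignments, lv) # dense cluster ids
          med <- medoid_frames(cm, X) # ordered by sorted node id = lv
          obs <- unlist(ens$observables$cage_distance, use.names = FALSE)
          a$medoid_obs <- setNames(obs[med], seq_along(lv))
        }
        ft <- frame_table(ens)
        emit("cluster", function(d)
          write.table(data.frame(replica = ft$replica, frame = ft$frame,
                                 cluster = a$assignments),
                      file.path(d, "assignments.tsv"), sep = "\t",
                      quote = FALSE, row.names = FALSE))
        a
      },
      msm = {
        a <- artifacts
        ens <- need("ensemble", "msm")
        asg <- need("assignments", "msm")
        ft <- frame_table(ens)
        seqs <- split(asg, ft$replica)
        counts <- count_transitions(seqs, lag = config$msm$lag,
                                    parents = ens$parents)
        a$raw_counts <- counts
        if (config$msm$pseudo_mass > 0) {
          X <- need("cluster_X", "msm")
          if (!is.null(a$cluster_model)) {
            md <- medoid_distances(a$cluster_model, X)
            # re-index to dense cluster ids
            ord <- order(as.integer(rownames(md)))
            md <- md[ord, ord]
          } else {
            ids <- sort(unique(asg))
            md <- as.matrix(dist(matrix(as.numeric(ids), ncol = 1)))
          }
          counts <- geometric_pseudocounts(counts, md,
                                           bin_width = config$msm$bin_width,
                                           mass = config$msm$pseudo_mass,
                                           neighbor_quantile =
                                             config$msm$neighbor_quantile)
        }
        a$counts <- counts
        a$model <- estimate_model(counts)
        emit("msm", function(d) {
          write_counts_mtx(counts, file.path(d, "counts.mtx"))
          write.table(data.frame(state = a$model$states, pi = a$model$pi),
                      file.path(d, "stationary.tsv"), sep = "\t",
                      quote = FALSE, row.names = FALSE)
        })
        a
      },
      tpt = {
        a <- artifacts
        model <- need("model", "tpt")
        ens <- need("ensemble", "tpt")
        asg <- need("assignments", "tpt")
        ft <- frame_table(ens)
        start_clusters <- unique(asg[ft$frame == 1L])
        bounds <- if (config$system == "chain" &&
                      inherits(a$system, "chain_system")) {
          boundary_states(intersect(a$system$bound, model$states),
                          intersect(a$system$unbound, model$states))
        } else {
          define_boundaries(model, a$medoid_obs, start_clusters,
                            u_cutoff = config$tpt$u_cutoff)
        }
        a$bounds <- bounds
        lag_time <- config$msm$lag * config$msm$time_per_frame
        a$tpt <- tpt_kinetics(a$counts, bounds, lag_time = lag_time,
                              C = config$tpt$concentration)
        a$bootstrap <- bootstrap_rates(
          a$raw_counts, bounds, lag_time = lag_time,
          C = config$tpt$concentration,
          removal_fraction = config$bootstrap$removal_fraction,
          repeats = config$bootstrap$repeats,
          level = config$bootstrap$level, seed = config$seed)
        k <- a$tpt$constants
        a$summary <- data.frame(
          constant = c("k_on", "k_off", "K_D"),
          estimate = c(k$k_on, k$k_off, k$K_D),
          lower = a$bootstrap$ci$lower, upper = a$bootstrap$ci$upper)
        emit("tpt", function(d) {
          write.table(data.frame(state = model$states, pi = model$pi,
                                 q_plus = a$tpt$q_plus,
                                 q_minus = a$tpt$q_minus),
                      file.path(d, "committors.tsv"), sep = "\t",
                      quote = FALSE, row.names = FALSE)
          write.table(a$summary, file.path(d, "rate_summary.tsv"),
                      sep = "\t", quote = FALSE, row.names = FALSE)
        })
        a
      },
      sapphire = {
        a <- artifacts
        ens <- need("ensemble", "sapphire")
        X <- if (!is.null(a$features)) a$features$scores else
          need("cluster_X", "sapphire")
        ord <- progress_index(X, start = 1L, mode = "exact")
        adj <- adjacent_pairs(ens)
        n <- nrow(X)
        win <- min(config$sapphire$cut_window, floor(n / 2))
        prof <- cut_profile(ord, adj, window = win)
        ft <- frame_table(ens)
        ent <- mixing_entropy(ord, ft$label,
                              window = config$sapphire$entropy_window)
        lanes <- list(time = ft$time, entropy_position = ent[order(ord)])
        if (!is.null(ens$observables$cage_distance))
          lanes$cage_distance <- unlist(ens$observables$cage_distance,
                                        use.names = FALSE)
        tab <- sapphire_table(ord, lanes = lanes[names(lanes) != "entropy_position"])
        tab$mixing_entropy <- ent
        a$sapphire <- list(ordering = ord, cut = prof, table = tab)
        emit("sapphire", function(d)
          write.table(tab, file.path(d, "sapphire.tsv"), sep = "\t",
                      quote = FALSE, row.names = FALSE))
        a
      },
      `pigs-sim` = {
        a <- artifacts
        fp <- do.call(funnel_params, config$synth$funnel)
        pc <- pigs_config(n_replicas = config$pigs$n_replicas,
                          decision_interval = config$pigs$decision_interval,
                          max_reseed = config$pigs$max_reseed,
                          redundancy_radius = config$pigs$redundancy_radius,
                          history_window = config$pigs$history_window,
                          seed = config$seed)
        ens <- pigs_run(matrix(0, 1, 2), funnel_propagator(fp,
                                                           config$synth$dt,
                                                           config$synth$kT),
                        pc, n_cycles = config$pigs$n_cycles %||% 20L,
                        observable = function(f) sqrt(rowSums(f^2)))
        a$pigs_ensemble <- ens
        emit("pigs-sim", function(d) {
          write_ensemble(ens, file.path(d, "pigs"))
          write.table(attr(ens, "log"), file.path(d, "pigs_log.tsv"),
                      sep = "\t", quote = FALSE, row.names = FALSE)
        })
        a
      },
      `rna-compare` = {
        a <- artifacts
        angles <- config$rna$angles
        if (is.null(angles) || length(angles) < 2L)
          stop("rna-compare needs config$rna$angles: a named list of >= 2 angle matrices")
        joint <- do.call(rbind, angles)
        groups <- rep(names(angles), vapply(angles, nrow, integer(1)))
        pca <- dihedral_pca(joint, k = min(config$rna$n_components,
                                           2L * ncol(joint)))
        cm <- tree_cluster(pca$scores, r_min = config$rna$cluster_radius,
                           r_max = config$rna$cluster_radius * 16,
                           n_levels = 5L)
        asg <- as.integer(factor(cm$assignments))
        pops <- cluster_population_report(asg, groups,
                                          top_n = config$rna$top_n)
        lv <- sort(unique(asg))
        hist_by <- lapply(split(asg, groups), tabulate, nbins = max(lv))
        kl <- outer(names(hist_by), names(hist_by),
                    Vectorize(function(i, j)
                      kl_divergence(hist_by[[i]], hist_by[[j]],
                                    pseudocount = 0.5)))
        dimnames(kl) <- list(names(hist_by), names(hist_by))
        mi <- lapply(angles, mutual_information_matrix,
                     bins = config$rna$mi_bins)
        a$rna <- list(pca = pca, assignments = asg, groups = groups,
                      populations = pops, kl = kl, mi = mi)
        emit("rna-compare", function(d) {
          write.table(pops, file.path(d, "cluster_populations.tsv"),
                      sep = "\t", quote = FALSE, row.names = FALSE)
          write.table(kl, file.path(d, "kl_divergence.tsv"), sep = "\t",
                      quote = FALSE)
        })
        a
      },
      stop("unknown stage: ", stage)
    )
  }
  artifacts
}

`%||%` <- function(a, b) if (is.null(a)) b else a
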