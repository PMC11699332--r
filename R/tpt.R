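#' Boundary-state definition for transition path theory
#'
#' @param B integer set of bound-state cluster ids.
#' @param U integer set of unbound-state cluster ids.
#' @return object of class `boundary_states`.
#' @export
boundary_states <- function(B, U) {
  B <- sort(unique(as.integer(B))); U <- sort(unique(as.integer(U)))
  if (length(B) == 0L || length(U) == 0L) stop("boundary state empty")
  if (length(intersect(B, U)) > 0L) stop("bound and unbound states overlap")
  structure(list(B = B, U = U), class = "boundary_states")
}

#' Define bound/unbound boundary states from observables and start frames
#'
#' The unbound set U collects clusters whose medoid ("centroid snapshot")
#' observable strictly exceeds `u_cutoff` (default 25 Angstrom for the
#' cage-N6 distance); the bound set B is the union of clusters containing at
#' least one starting snapshot. Overlap is an error: a start frame inside an
#' unbound cluster violates the two-state imposition.
#'
#' @param model a [estimate_model()] result.
#' @param medoid_observable numeric vector of the per-cluster medoid
#'   observable, named or indexed by cluster id (must cover the component).
#' @param start_clusters cluster ids containing the starting snapshots.
#' @param u_cutoff unbound threshold (strict `>`; default 25).
#' @return a [boundary_states()] object.
#' @export
define_boundaries <- function(model, medoid_observable, start_clusters,
                              u_cutoff = 25) {
  ids <- model$states
  obs <- if (!is.null(names(medoid_observable)))
    medoid_observable[as.character(ids)] else medoid_observable[ids]
  if (any(is.na(obs))) stop("observable undefined for some component clusters")
  U <- ids[obs > u_cutoff]
  B <- intersect(ids, unique(as.integer(start_clusters)))
  boundary_states(B, U) # validates non-empty and disjoint
}

bounds_index <- function(model, bounds) {
  iB <- match(bounds$B, model$states); iU <- match(bounds$U, model$states)
  if (any(is.na(iB)) || any(is.na(iU)))
    stop("boundary states outside the model's connected component")
  list(B = iB, U = iU, I = setdiff(seq_along(model$states), c(iB, iU)))
}

#' Forward committor
#'
#' Probability, per state, that the chain reaches the unbound set U before
#' the bound set B; fixed to 0 on B and 1 on U, solved on the intermediates
#' from `q+_i = sum_j T_ij q+_j` as a sparse linear system.
#'
#' @param model a [estimate_model()] result.
#' @param bounds a [boundary_states()] object.
#' @return committor vector named by cluster id.
#' @export
forward_committor <- function(model, bounds) {
  ix <- bounds_index(model, bounds)
  n <- length(model$states)
  q <- numeric(n); q[ix$U] <- 1
  if (length(ix$I) > 0L) {
    A <- diag(length(ix$I)) - model$T[ix$I, ix$I, drop = FALSE]
    b <- model$T[ix$I, ix$U, drop = FALSE] %*% rep(1, length(ix$U))
    sol <- tryCatch(solve(A, b), error = function(e)
      stop("singular committor system (disconnected intermediates): ",
           conditionMessage(e)))
    q[ix$I] <- sol
  }
  setNames(as.numeric(q), model$states)
}

#' Backward committor
#'
#' Probability that the chain last came from B rather than U, computed on
#' the time-reversed chain `Ttilde_ij = pi_j T_ji / pi_i` with boundary
#' values 1 on B and 0 on U. Equals `1 - q+` only under detailed balance.
#'
#' @inheritParams forward_committor
#' @return backward committor vector named by cluster id.
#' @export
backward_committor <- function(model, bounds) {
  if (any(model$pi <= 0)) stop("stationary probability vanishes on the component")
  ix <- bounds_index(model, bounds)
  n <- length(model$states)
  Trev <- t(model$T * model$pi) / model$pi # Ttilde_ij = pi_j T_ji / pi_i
  q <- numeric(n); q[ix$B] <- 1
  if (length(ix$I) > 0L) {
    A <- diag(length(ix$I)) - Trev[ix$I, ix$I, drop = FALSE]
    b <- Trev[ix$I, ix$B, drop = FALSE] %*% rep(1, length(ix$B))
    q[ix$I] <- solve(A, b)
  }
  setNames(as.numeric(q), model$states)
}

#' Committor toward the bound state
#'
#' The forward committor of the reversed reaction (reach B before U); the
#' quantity thresholded at 0.5 to declare a state part of the intact
#' complex, and the selection score for committor-guided restarts. Kept as
#' an explicit, named quantity because it equals `1 - q+` only for
#' reversible models.
#'
#' @inheritParams forward_committor
#' @return committor-to-bound vector named by cluster id.
#' @export
committor_to_bound <- function(model, bounds) {
  forward_committor(model, boundary_states(B = bounds$U, U = bounds$B))
}

#' Reactive flux and total reactive current
#'
#' `f_ij = pi_i T_ij q-_i q+_j`, its non-negative net part
#' `f+_ij = max(0, f_ij - f_ji)` (diagonal zero), and the total current
#' F computed independently as the net outflow of B and the net inflow into
#' U; the two must agree (stationarity), which is asserted.
#'
#' @inheritParams forward_committor
#' @param q_plus,q_minus committors from [forward_committor()] /
#'   [backward_committor()].
#' @param tol relative tolerance for the flux-conservation assertion.
#' @return list with `f`, `f_plus`, `F_BU`, `F_UB`.
#' @export
reactive_flux <- function(model, bounds, q_plus, q_minus, tol = 1e-8) {
  ix <- bounds_index(model, bounds)
  f <- model$pi * model$T * outer(q_minus, q_plus)
  fp <- f - t(f); fp[fp < 0] <- 0; diag(fp) <- 0
  notB <- setdiff(seq_along(model$states), ix$B)
  notU <- setdiff(seq_along(model$states), ix$U)
  F_BU <- sum(fp[ix$B, notB, drop = FALSE])
  F_UB <- sum(f[notU, ix$U, drop = FALSE]) # net inflow into U
  if (abs(F_BU - F_UB) > tol * max(F_BU, F_UB, .Machine$double.xmin))
    stop(sprintf("flux conservation violated: F_BU=%.3e, F_UB=%.3e",
                 F_BU, F_UB))
  list(f = f, f_plus = fp, F_BU = F_BU, F_UB = F_UB)
}

#' Forward and backward TPT rates
#'
#' `nu_BU = F_BU / (tau sum_i pi_i q-_i)` and
#' `nu_UB = F_UB / (tau sum_i pi_i (1 - q-_i))`, the unbinding and binding
#' rates per unit time.
#'
#' @param F_BU,F_UB total reactive currents from [reactive_flux()].
#' @param pi stationary distribution.
#' @param q_minus backward committor.
#' @param lag lag time tau in physical units (> 0).
#' @return list with `nu_BU`, `nu_UB`.
#' @export
tpt_rates <- function(F_BU, F_UB, pi, q_minus, lag) {
  if (lag <= 0) stop("lag must be positive")
  denom_b <- sum(pi * q_minus); denom_u <- sum(pi * (1 - q_minus))
  if (denom_b == 0 || denom_u == 0) stop("zero rate denominator")
  list(nu_BU = F_BU / (lag * denom_b), nu_UB = F_UB / (lag * denom_u))
}

#' Solute concentration of a single copy in a cubic box
#'
#' `C = 1 / (N_A side^3)` converted to mol/L.
#'
#' @param box_side box side length in Angstrom (> 0).
#' @return concentration in molar.
#' @export
ligand_box_concentration <- function(box_side) {
  stopifnot(box_side > 0)
  n_avogadro <- 6.02214076e23
  1 / (n_avogadro * (box_side * 1e-9)^3) # side in dm: 1 A = 1e-9 dm
}

#' Mass-action rate constants and dissociation constant
#'
#' Maps the TPT rates onto a two-state rate law: the intact-complex
#' concentration is the stationary weight of states whose committor to the
#' bound state strictly exceeds 0.5, `[LR] = C sum_i pi_i 1[ctb_i > 0.5]`;
#' with a single copy of each species `[L] = [R] = C - [LR]`, so
#' `k_on = nu_UB / ([L][R])`, `k_off = nu_BU / [LR]`, `K_D = k_off / k_on`.
#'
#' @param nu_BU,nu_UB rates from [tpt_rates()] (per unit time).
#' @param pi stationary distribution.
#' @param ctb committor to the bound state ([committor_to_bound()]).
#' @param C total solute concentration (molar), see
#'   [ligand_box_concentration()].
#' @param threshold committor threshold declaring the complex intact
#'   (default 0.5, strict `>`).
#' @return list with `k_on` (1/(M time)), `k_off` (1/time), `K_D` (molar),
#'   `LR`, `L`, `R` (molar).
#' @export
rate_constants <- function(nu_BU, nu_UB, pi, ctb, C, threshold = 0.5) {
  stopifnot(C > 0, all(ctb >= 0 - 1e-12), all(ctb <= 1 + 1e-12))
  LR <- C * sum(pi[ctb > threshold])
  L <- C - LR
  if (LR == 0 || L == 0) stop("degenerate two-state mapping")
  k_on <- nu_UB / (L * L)
  k_off <- nu_BU / LR
  list(k_on = k_on, k_off = k_off, K_D = k_off / k_on, LR = LR, L = L, R = L)
}

#' Kemeny constant of a Markov model
#'
#' `K = sum_{i >= 2} 1 / (1 - lambda_i)` over the non-unit eigenvalues
#' (complex pairs cancel; the residual imaginary part must stay below 1e-8).
#' Cross-checked against the mean first-passage identity
#' `K = sum_j pi_j m_ij` for a sampled row, which is invariant to the
#' starting row i.
#'
#' @param model a [estimate_model()] result (irreducible by construction).
#' @param check cross-check against the first-passage identity (default
#'   TRUE; skipped above 1500 states).
#' @return Kemeny constant in lag units.
#' @export
kemeny_constant <- function(model, check = TRUE) {
  ev <- eigen(model$T, only.values = TRUE)$values
  ev <- ev[order(-Mod(ev), Mod(Im(ev)))]
  if (sum(Mod(ev) >= 1 - 1e-10) > 1L) stop("reducible model")
  K <- sum(1 / (1 - ev[-1L]))
  if (abs(Im(K)) > 1e-8 * max(1, abs(Re(K))))
    stop("imaginary residue in Kemeny sum")
  K <- Re(K)
  if (check && length(model$pi) <= 1500L) {
    m <- mean_first_passage(model) / model$lag # back to lag units
    K2 <- sum(model$pi * m[1L, ])
    if (abs(K - K2) > 1e-8 * max(1, abs(K)))
      stop(sprintf("Kemeny cross-check failed: eigen %.12g vs MFPT %.12g",
                   K, K2))
  }
  K
}

#' Mean first-passage time matrix of a Markov model
#'
#' Via the fundamental matrix `Z = (I - T + 1 pi')^{-1}`:
#' `m_ij = (Z_jj - Z_ij) / pi_j`, `m_ii = 0` (lag units).
#'
#' @param model a [estimate_model()] result.
#' @return matrix of mean first-passage times.
#' @export
mean_first_passage <- function(model) {
  n <- length(model$pi)
  Z <- solve(diag(n) - model$T + matrix(1, n, 1) %*% t(model$pi))
  m <- (matrix(diag(Z), n, n, byrow = TRUE) - Z) /
    matrix(model$pi, n, n, byrow = TRUE)
  diag(m) <- 0
  m * model$lag
}

#' Lump states of a count matrix into macrostates
#'
#' @param counts a [count_transitions()] result.
#' @param partition integer vector mapping every state id to a macrostate id
#'   (total on the state space).
#' @return a `count_matrix` over the macrostates.
#' @export
lump_states <- function(counts, partition) {
  n <- nrow(counts$C)
  if (length(partition) != n) stop("partition must cover every state")
  macro <- as.integer(factor(partition))
  k <- max(macro)
  if (k < 2L) stop("lumping to a single state leaves no dynamics")
  S <- Matrix::sparseMatrix(i = seq_len(n), j = macro, x = 1,
                            dims = c(n, k))
  out <- counts
  out$C <- Matrix::t(S) %*% counts$C %*% S
  attr(out, "macro_ids") <- sort(unique(partition))
  out
}

#' Kemeny-constant lumping diagnostics
#'
#' Quantifies the shortcuts a lumping introduces: the Kemeny constant of the
#' lumped network as a percentage of the full-resolution one (values well
#' below 100% flag drastic shortcuts).
#'
#' @param counts a [count_transitions()] result.
#' @param partition as in [lump_states()].
#' @return list with `K_full`, `K_lumped`, `percent`.
#' @export
lumping_diagnostics <- function(counts, partition) {
  K_full <- kemeny_constant(estimate_model(counts), check = FALSE)
  K_lump <- kemeny_constant(estimate_model(lump_states(counts, partition)),
                            check = FALSE)
  list(K_full = K_full, K_lumped = K_lump,
       percent = 100 * K_lump / K_full)
}

#' End-to-end TPT kinetics from a count matrix
#'
#' Convenience composition: model estimation, committors, reactive flux,
#' TPT rates and mass-action constants.
#'
#' @param counts a [count_transitions()] result.
#' @param bounds a [boundary_states()] object.
#' @param lag_time physical lag time (default: the count lag in frames).
#' @param C solute concentration (default 1, reduced units).
#' @return list with `model`, `q_plus`, `q_minus`, `ctb`, `flux`, `rates`,
#'   `constants`.
#' @export
tpt_kinetics <- function(counts, bounds, lag_time = counts$lag, C = 1) {
  model <- estimate_model(counts)
  qp <- forward_committor(model, bounds)
  qm <- backward_committor(model, bounds)
  ctb <- committor_to_bound(model, bounds)
  flux <- reactive_flux(model, bounds, qp, qm)
  rates <- tpt_rates(flux$F_BU, flux$F_UB, model$pi, qm, lag_time)
  konst <- rate_constants(rates$nu_BU, rates$nu_UB, model$pi, ctb, C)
  list(model = model, q_plus = qp, q_minus = qm, ctb = ctb, flux = flux,
       rates = rates, constants = konst)
}

#' Count-subsampling confidence intervals for the rate constants
#'
#' Each repeat removes `removal_fraction` of the total raw count mass by a
#' multivariate-hypergeometric draw (counts removed at random, without
#' replacement), re-runs the full estimation pipeline and records k_on,
#' k_off and K_D; empirical percentile intervals are returned. Repeats that
#' disconnect the boundary states are discarded and logged; more than half
#' discarded is an error.
#'
#' @param counts raw (integer) [count_transitions()] result, total >= 100.
#' @param bounds a [boundary_states()] object.
#' @param lag_time physical lag time.
#' @param C solute concentration (molar or reduced).
#' @param removal_fraction fraction of counts removed per repeat (default
#'   0.01).
#' @param repeats number of repeats (default 20).
#' @param level confidence level (default 0.90).
#' @param seed integer seed.
#' @param pseudocounts optional list(`medoid_dist`, `bin_width`, `mass`,
#'   `neighbor_quantile`) re-applied after each subsampling.
#' @return list with `estimate` (full-data constants), `ci` (data frame:
#'   constant, lower, upper), `samples`, `discarded`.
#' @export
bootstrap_rates <- function(counts, bounds, lag_time = counts$lag, C = 1,
                            removal_fraction = 0.01, repeats = 20,
                            level = 0.90, seed = 1L, pseudocounts = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  if (removal_fraction < 0 || removal_fraction >= 1)
    stop("removal_fraction must be in [0, 1)")
  total <- sum(counts$C)
  if (total < 100) stop("need at least 100 counts to subsample")
  apply_pseudo <- function(cm) {
    if (is.null(pseudocounts)) return(cm)
    do.call(geometric_pseudocounts, c(list(cm), pseudocounts))
  }
  point <- tpt_kinetics(apply_pseudo(counts), bounds, lag_time, C)$constants
  set.seed(as.integer(seed))
  m_remove <- round(removal_fraction * total)
  trip <- Matrix::summary(methods::as(counts$C, "generalMatrix")) # i, j, x
  samples <- matrix(NA_real_, repeats, 3,
                    dimnames = list(NULL, c("k_on", "k_off", "K_D")))
  discarded <- 0L
  for (b in seq_len(repeats)) {
    x <- trip$x
    if (m_remove > 0) {
      rem <- m_remove; left <- sum(x)
      for (k in seq_along(x)) {
        if (rem == 0) break
        take <- rhyper(1, x[k], left - x[k], rem)
        x[k] <- x[k] - take; rem <- rem - take; left <- left - x[k] - take
      }
    }
    cm <- counts
    cm$C <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = x,
                                 dims = dim(counts$C))
    res <- tryCatch(tpt_kinetics(apply_pseudo(cm), bounds, lag_time, C),
                    error = function(e) NULL)
    if (is.null(res)) { discarded <- discarded + 1L; next }
    samples[b, ] <- c(res$constants$k_on, res$constants$k_off,
                      res$constants$K_D)
  }
  if (discarded > repeats / 2)
    stop("more than half of the bootstrap repeats disconnected the network")
  if (discarded > 0L)
    message(discarded, " bootstrap repeat(s) discarded (disconnected network)")
  a <- (1 - level) / 2
  ok <- stats::complete.cases(samples)
  ci <- data.frame(constant = colnames(samples),
                   lower = apply(samples[ok, , drop = FALSE], 2, quantile,
                                 probs = a),
                   upper = apply(samples[ok, , drop = FALSE], 2, quantile,
                                 probs = 1 - a))
  rownames(ci) <- NULL
  list(estimate = point, ci = ci, samples = samples[ok, , drop = FALSE],
       discarded = discarded)
}
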