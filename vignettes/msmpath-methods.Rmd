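---
title: "Quantifying unbinding kinetics from adaptively sampled replica ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying unbinding kinetics from adaptively sampled replica ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msmpath)
```

## The problem

Dissociation of a short, flexible ligand — here the motivating case is an
m6A-methylated RNA trinucleotide leaving the aromatic cage of a YTH reader
domain — happens on microsecond timescales, far beyond what a single
molecular-dynamics replica can sample. The practical strategy is
(i) *adaptive sampling*: run many replicas, periodically terminate redundant
ones and reseed them from rare configurations, which produces a
tree-connected ensemble; (ii) *Markov state modelling* of the discretized
ensemble; and (iii) *transition path theory* (TPT) to convert the model plus
a two-state (bound/unbound) imposition into committors, reactive fluxes and
mass-action rate constants (k_on, k_off, K_D).

`msmpath` implements this machinery end to end, together with the
featurization (differential contact maps, sigmoid distance transforms, PCA),
the multi-resolution tree clustering, progress-index (SAPPHIRE) annotation,
the PIGS-style adaptive-sampling controller, dihedral-ensemble comparison
tools for RNA in water, and — crucially — synthetic dynamics generators with
*analytic* kinetic ground truth, so that every stage of the pipeline is
testable without any trajectory downloads.

## The model

A trajectory ensemble discretized into clusters yields sliding-window
transition counts at lag $\tau$; reseeding branch points are handled by
path-through-tree counting: a child replica inherits the last $\tau$ frames
of its parent lineage as context, because a reseeded replica continues its
parent's phase-space point, so pairs straddling the branch are genuine
dynamical transitions, while pairs never connect lineages that do not lie on
one root-to-leaf path. Counts are row-normalized *without* enforcing
reversibility; the stationary distribution $\pi$ is the leading left
eigenvector.

With bound set $B$ (clusters containing starting snapshots) and unbound set
$U$ (clusters whose medoid cage distance strictly exceeds 25 Å), the
forward committor $q^+$ solves a sparse linear system with boundary values
0 on $B$ and 1 on $U$; the backward committor $q^-$ solves the analogous
system on the time-reversed chain. The reactive flux is
$f_{ij} = \pi_i T_{ij} q^-_i q^+_j$, its one-way part
$f^+_{ij} = \max(0, f_{ij} - f_{ji})$, and the total reactive current
$F_{BU}$ is computed independently as the net outflow of $B$ and the net
inflow into $U$; the two must agree to $10^{-8}$ relative or the model is
rejected as inconsistent. Rates are
$\nu_{BU} = F_{BU} / (\tau \sum_i \pi_i q^-_i)$ and
$\nu_{UB} = F_{UB} / (\tau \sum_i \pi_i (1 - q^-_i))$. Mass action with one
copy of ligand and receptor in a box of concentration $C$ assigns
$[LR] = C \sum_i \pi_i \mathbf{1}[q^{\mathrm{bound}}_i > 0.5]$,
$[L] = [R] = C - [LR]$, and
$k_\mathrm{on} = \nu_{UB}/([L][R])$, $k_\mathrm{off} = \nu_{BU}/[LR]$,
$K_D = k_\mathrm{off}/k_\mathrm{on}$.

Two conventions deserve explicit names. First, the committor *to the bound
state* used for the intact-complex indicator and for restart selection is
computed as the forward committor of the reversed reaction (reach $B$ before
$U$), not as $1 - q^+$, because the two differ for non-reversible models;
`committor_to_bound()` keeps this an explicit quantity. Second, because
$\nu_{BU}$ already normalizes the flux by the reactant population, dividing
by $[LR]$ once more makes $k_\mathrm{off}$ exact only in the limit where the
bound basin carries most of the stationary weight — the regime of a
predominantly bound complex, which is the regime the method is designed for
and the regime our synthetic defaults emulate. The parameter-recovery
analysis below quantifies the residual (about 2% for a 95% bound basin).

### Network diagnostics

The Kemeny constant $K = \sum_{i \ge 2} (1 - \lambda_i)^{-1}$ — the
stationary-weighted mean first-passage time from any state, invariant to the
starting state — is used to detect whether lumping clusters into $B$ and $U$
introduces shortcuts: `lumping_diagnostics()` reports the lumped network's
$K$ as a percentage of the full-resolution value. For non-reversible
matrices the sum runs over the complex spectrum (conjugate pairs cancel; a
residual imaginary part above $10^{-8}$ is an error), and the eigenvalue
formula is cross-checked internally against the fundamental-matrix identity
$K = \sum_j \pi_j m_{ij}$.

Statistical uncertainty is assessed by count subsampling: each bootstrap
repeat removes 1% of the raw transition-count mass by a multivariate
hypergeometric draw (counts removed literally at random, without
replacement), re-runs estimation through rate constants, and the 90%
empirical percentile interval over 20 repeats is reported. Repeats that
disconnect the boundary states are discarded and logged; more than half
discarded is an error.

## Featurization

Contact maps count a residue pair as in contact when the minimum
heavy-atom distance is strictly below 5 Å; differential pairs are those
whose contact frequency changes by strictly more than 0.35 between an early
and a late window. All strict inequalities follow the published thresholds
(5 Å, 0.35, 25 Å, 10 Å, committor 0.5). Manual pruning of uninformative
pairs (termini) is an explicit exclude list, never hardcoded. Retained
residue pairs expand to atom pairs: Cα plus the most distant side-chain
heavy atom per protein residue (glycine collapses to Cα alone, since its
most distant side-chain heavy atom is undefined), and C4', O3' plus the
glycosidic nitrogen per RNA residue — 4, 9 and 6 distances for
intra-protein, intra-RNA and intermolecular pairs respectively.

Distances pass through the sigmoid $\varphi(x) = 1 - (1 + e^{(x-\chi)/\tau_s})^{-1}$
to homogenize the unbound state. The midpoint $\chi$ and smoothness
$\tau_s$ are not published; the defaults $\chi = 15$ Å, $\tau_s = 2.5$ Å
put the curve within 2% of its asymptotes at 5 and 25 Å, matching the
qualitative description, and both are configuration keys. PCA retains 7
components by default, with centring only — all sigmoid features already
share the (0,1) scale, so variance scaling would inflate noise directions.

## Clustering and the progress index

The multi-resolution tree clustering inserts frames by leader descent:
at each level (radii geometrically spaced from `r_max` = 3.5 down to
`r_min` = 0.2; 8 levels by default, a chosen value since no level count is
published), a frame joins the first existing node within the level radius
or spawns a new one. Insertion order is the input frame order, which makes
results reproducible and matches streaming behaviour; a seeded shuffle is
available as a sensitivity check. The three outermost leaf layers can be
folded onto their parents (`fold_leaf_layers()`). Cluster representatives
are medoids — actual snapshots — because the unbound-state rule needs a
"centroid snapshot" with observables attached.

The progress index greedily appends the unvisited frame closest to the
visited set (ties to the lowest frame index). The exact mode is quadratic
and documented for up to ~1e5 frames; the approximate mode orders cluster
leaders by the same greedy rule and refines within clusters by
distance-to-leader, our committed reading of the cluster-mediated scheme.
SAPPHIRE annotation lanes include the kinetic cut function — at each split
of the ordering, the number of time-adjacent transitions (respecting
reseeding segments) between the 10,000 ordered positions left and right of
the split, a three-set scheme in which only left-right transitions count —
reported as $-\ln(\mathrm{cut} + 1/2)$; the 1/2 keeps zero-cut barriers
finite without distorting high-cut regions. The mixing-entropy lane uses a
centred rolling window of 2000 snapshots by default, with 1000 as the
common figure-annotation alternative — the window is a config key rather
than a silently fixed constant. Its ceiling is $\ln 4 \approx 1.386$ nats
for four perfectly interleaved systems.

## The adaptive-sampling controller

The PIGS controller propagates `n_replicas` (default 64) replicas and makes
a reseeding decision every `decision_interval` steps (default 100, the
analogue of a 100 ps interval), terminating at most `max_reseed` (default
32) replicas. The precise published heuristic lives in supplementary
material that is not restated in the main text; the committed, documented
interpretation here is: a replica's redundancy is the number of other
current replicas within `redundancy_radius` of it, ties broken by
progress-index position in the pooled recent sample (earlier = denser =
more redundant); rare restart candidates are the history snapshots with the
largest mean distance to the rest of the history window. The ranking
function is pluggable so alternatives can be swapped in, and whether the
rare pool uses the full history or a recent window is a config key
(default: the last 20 decision cycles). Reseeded replicas restart from the
chosen snapshot with fresh noise streams derived from (seed, branch
counter), and a parent link records the donor replica and frame, so
controller output feeds `count_transitions()` unchanged.

Committor-guided restart selection mirrors the follow-up-run strategy:
non-boundary clusters with committor-to-bound strictly below 0.5, at most
10 of them by decreasing stationary weight, supply 64 starting frames drawn
round-robin.

## Synthetic ground truth and what it does (not) show

Two generators define the study conditions:

* **Metastable chain** (`build_chain_system()`): blocks of 3 microstates
  with intra-block hop probability 0.15 and cross-block probabilities
  0.002 (escape) / 0.04 (return). The 20:1 asymmetry makes the bound block
  carry ~95% of the stationary weight — a predominantly bound complex with
  rare barrier crossings, the regime of the real system. Stationary
  distribution, committors, mean first-passage times and the Kemeny
  constant all come from direct linear solves and serve as oracles.
* **2-D Langevin funnel** (`langevin_funnel()`): a radial well at the
  origin, a barrier ridge of 8 kT at radius 8 (length units read as Å so
  the 10/25 Å rules apply), modulated by 4 angular exit channels with
  contrast 0.25 — the cheapest geometry reproducing multiple low-populated
  unbinding pathways; mobility 1, dt 0.01 (per-step noise displacement
  0.14, far below the barrier width; checked at entry), soft wall at 30.
  The radial coordinate is exported as the cage-distance observable.

These toys emulate the tree connectivity, label structure and two-basin
kinetics of reseeded replica ensembles. They do not emulate
high-dimensional degenerate feature spaces, force-field error, or the
internal heterogeneity of real bound/unbound states — so green tests
demonstrate the correctness of the estimators, not the accuracy of any MD
force field.

Problem sizes used by the validation suite and the acceptance script are
chosen for statistical resolution: the parameter-recovery experiment uses a
64 x 30,000-step ensemble against a 4-million-step direct reference
trajectory (relative standard errors of roughly 3% and 2%), the walker
oracles use 1e5 walkers per state, and the controller comparison uses 16
replicas for 60 decision cycles against an equal-aggregate-step control,
repeated over seeds.

## Worked example

```{r example, eval = FALSE}
sys <- build_chain_system(2, seed = 1)      # 6-state bound/unbound chain
ens <- sample_markov_trajectories(sys, 64, 30000, seed = 1, start = 1)
counts <- count_transitions(ens, lag = 1)
bounds <- boundary_states(sys$bound, sys$unbound)
kin <- tpt_kinetics(counts, bounds, lag_time = 1, C = 1)
kin$constants[c("k_on", "k_off", "K_D")]
bootstrap_rates(counts, bounds, seed = 1)$ci
```

## Numerical choices and degenerate inputs

* Stationary vectors from `eigen()` are polished by power iteration to
  $\|\pi T - \pi\|_\infty < 10^{-12}$.
* Committor systems are solved directly; disconnected intermediates make
  the system singular and raise an error naming the condition.
* The pseudocount prior (`geometric_pseudocounts()`) min-max-normalizes
  medoid distances, discretizes at bin width 0.002 (the one published
  value), and applies a linearly decreasing bin weight that reaches zero at
  a configurable neighbour quantile (default 0.1), scaled to a total mass
  of 0.5 per cluster. The decay shape, cutoff quantile and mass are
  committed interpretations of an under-specified prior; all three are
  config keys.
* Strict-threshold comparisons guard against floating-point noise at the
  cut with a 1e-9 margin.
* Planar sugar rings (pseudorotation amplitude ~ 0) raise "phase
  undefined" rather than returning an arbitrary phase; pucker phases
  outside the two canonical sectors are labelled by their 36-degree sector
  name rather than forced into a binary call.
* KL divergence defaults to cluster-population vectors (the shared-state
  construct of the joint clustering); PC-space histograms are the
  documented alternative, since the distribution underlying published
  divergence values is not stated.
* Mutual information uses 24 equal-width periodic bins per angle with the
  Miller-Madow bias reported alongside, because plug-in MI inflates
  coupling on finite samples.

## Known limitations

* Non-reversible estimation means spectral quantities use moduli and the
  Kemeny sum runs over a complex spectrum; strongly oscillatory chains
  could stress the $10^{-8}$ imaginary-residue tolerance.
* The mass-action mapping is exact only for strongly two-state systems; for
  shallow basins the k_off convention above deviates from first-passage
  rates by a factor approaching $1/\pi_B$.
* No reactive-flux pathway decomposition is provided: only total-flux
  quantities are computed, since pathway decompositions are known to be
  inconclusive for flexible polyvalent binders with many low-populated
  routes.
* The exact reseeding heuristic and approximate-progress-index schedule of
  the original tools are not fully specified in print; both implementations
  here are committed interpretations, config-exposed where the choice
  matters.
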