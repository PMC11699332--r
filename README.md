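# msmpath

Markov state models and transition path theory for adaptively sampled,
tree-connected trajectory ensembles — the analysis machinery needed to
quantify how a short flexible ligand (the motivating system is an
m6A-methylated RNA trinucleotide) unbinds from a protein reader domain when
the process is far too slow for a single simulation replica.

## What it does

Given a replica ensemble with reseeding connectivity (or one generated by
the built-in synthetic toys), `msmpath` provides every stage of the
kinetics pipeline:

* **Featurization** — residue contact maps (strict 5 Å rule), differential
  pair selection (strict 0.35 rule), atom-pair expansion (4/9/6 distances
  per intra-protein / intra-RNA / intermolecular residue pair), the sigmoid
  distance transform `φ(x) = 1 − (1 + exp((x−χ)/τ_s))⁻¹`, and PCA reduction.
* **Tree clustering** — streaming leader-descent clustering across
  geometrically spaced radii (0.2–3.5 by default), leaf folding, medoid
  snapshots.
* **MSM estimation** — sliding-window transition counts that respect
  reseeding branch points (path-through-tree counting), geometrically
  informed pseudocounts (bin width 0.002), non-reversible row
  normalization, strong-component restriction, implied timescales.
* **TPT kinetics** — forward/backward committors by sparse linear solve,
  reactive fluxes `f_ij = π_i T_ij q⁻_i q⁺_j` with an internal
  flux-conservation assertion, rates
  `ν_BU = F_BU/(τ Σ π_i q⁻_i)`, mass-action constants
  `k_on = ν_UB/([L][R])`, `k_off = ν_BU/[LR]`, `K_D = k_off/k_on` with
  `[LR] = C Σ π_i 1[q_bound > 0.5]`, Kemeny-constant lumping diagnostics,
  and 90% confidence intervals from 1%-count-removal bootstraps (20
  repeats).
* **SAPPHIRE annotation** — exact and cluster-approximate progress index,
  kinetic cut profiles, mixing entropy, annotation tables.
* **PIGS controller** — redundancy-based replica termination and reseeding
  on pluggable propagators (discrete chains, a 2-D Langevin binding
  funnel), committor-guided restart selection, unbinding-event counting.
* **RNA ensemble comparison** — periodicity-safe dihedral PCA,
  Kullback–Leibler divergence, mutual information with Miller–Madow bias,
  sugar-pucker pseudorotation (Altona–Sundaralingam).
* **Synthetic ground truth** — metastable chains with analytic stationary
  distributions, committors, mean first-passage times and Kemeny constants
  (direct linear solves), and a funnel potential with angular exit
  channels, so the whole pipeline is validated against known answers.

## Worked example

A six-state chain with a deep bound basin (blocks of three microstates,
cross-block hop probabilities 0.002 out / 0.04 back) stands in for a
predominantly bound complex:

```r
library(msmpath)
sys    <- build_chain_system(2, seed = 1)   # bound states 1:3, unbound 4:6
ens    <- sample_markov_trajectories(sys, 64, 30000, seed = 1, start = 1)
counts <- count_transitions(ens, lag = 1)
bounds <- boundary_states(sys$bound, sys$unbound)
kin    <- tpt_kinetics(counts, bounds, lag_time = 1, C = 1)
unlist(kin$constants[c("k_on", "k_off", "K_D")])
#>         k_on        k_off          K_D
#> 4.9263936771 0.0007216796 0.0001464925
bootstrap_rates(counts, bounds, seed = 1)$ci
#>   constant        lower        upper
#> 1     k_on 4.8610274349 4.9933917523
#> 2    k_off 0.0007184655 0.0007234244
#> 3      K_D 0.0001445591 0.0001484705
```

Units are reduced (per lag step, box concentration C = 1). The estimated
`k_off` of 7.2e-4 per step sits within a few percent of the analytic
transition-path-theory value for this chain (7.0e-4) and of the
first-passage rate counted on a long direct simulation (6.9e-4); the
bootstrap interval reflects the 1%-removal subsampling, not the full
sampling error. `run_pipeline()` composes the same stages — including the
continuous funnel with featurization and clustering — under a single
`pipeline_config()`, and writes TSV/MatrixMarket artifacts plus provenance
records when given an output directory.

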