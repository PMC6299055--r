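# podnet

Social network analysis of photo-identification encounter data for
individually identifiable animals, written for behavioural ecologists
studying small resident populations — coastal dolphins being the
archetype — whose data arrive as "gambit of the group" records: on each
encounter, every identified member of a group is assumed associated with
every other.

## What it computes

Starting from three CSV files (encounters, group memberships, an
individual registry), the package covers the full analysis chain used in
cetacean social-structure studies:

- **Association indices.** The half-weight index for a dyad with `x`
  periods together, `y_ab` periods both identified apart and `y_a`, `y_b`
  periods only one identified:

  `HWI = x / (x + y_ab + (y_a + y_b)/2)`

  plus the gregariousness-corrected variant
  `HWIG_ab = HWI_ab · ΣHWI / (s_a s_b)` with `s_i` the row strength.
- **Non-random association.** The Manly–Bejder within-sample permutation
  test: a Markov chain of 2×2 checkerboard swaps inside single sampling
  periods holds group sizes and individual sighting frequencies fixed
  while the SD and CV of the dyadic indices are compared with their
  permuted distributions. The chain kernel is compiled (Rcpp) and runs
  20,000 permutations in seconds.
- **Temporal dynamics.** Standardized lagged association rates g'(τ)
  with denominator-weighted moving-average windows, temporal jackknife
  standard errors, a within-period identity-permutation null rate, and
  the four exponential social-organisation models (constant companions,
  casual acquaintances, CC+CA, two-level CA) fitted by binomial maximum
  likelihood and ranked by `QAIC = −2logL/ĉ + 2K`.
- **Social units.** Average-linkage hierarchical clustering with the
  cophenetic correlation coefficient, Newman's eigenvector modularity
  method with Kernighan–Lin fine-tuning, and the modularity-optimal
  dendrogram cut (`Q = Σ_c [W_c/T − (S_c/2T)²]`, strength-based
  "gregariousness" null).
- **Node metrics.** Strength, reach, affinity, eigenvector centrality,
  weighted clustering coefficient, betweenness and closeness on
  `1/index` edge lengths, with per-cluster summary tables and GraphML
  export.
- **Population statistics.** Social differentiation S (the CV of true
  dyadic association probabilities) by beta-binomial maximum likelihood
  with bootstrap SEs, the correlation r between true and estimated
  indices, Mantel tests of class structure, strict-majority assignment
  of encounters to clusters, diel-partitioning tables with Fisher's
  exact test, sex composition of groups, and trawler-interaction
  summaries by individual, cluster and gear.
- **A fission–fusion society simulator** (`simulate_society()`) with
  known ground truth — cluster labels, true dyadic probabilities, diel
  schedules, interaction propensities — so that every stage above can be
  validated by parameter-recovery studies without any field data.

## Worked example

```r
library(podnet)

sim <- simulate_society(society_preset("paper-like", seed = 1))
tab <- apply_restrictions(sim$encounters)   # >= 4 sightings, >= 2 years
pm  <- build_period_matrices(tab, period_length_days = 1)
h   <- hwi(dyad_counts(pm))

permutation_test(pm, n_perm = 20000, seed = 42)
#> Within-sample permutation test (20000 permutations, 2265 flips between saves)
#>   SD: observed 0.1204, random 0.0978, P = 0
#>   CV: observed 1.4184, random 1.1248, P = 0

eigenvector_communities(h)
#> Cluster assignment (eigenvector): 3 clusters of sizes 19/13/6
#>   modularity Q = 0.4271 (strength/gregariousness null)

social_differentiation(dyad_counts(pm), n_bootstrap = 500, seed = 7)
#> Social differentiation (beta-binomial ML, 703 dyads)
#>   S = 1.176 (SE 0.054)
#>   r = 0.784 (SE 0.014), bootstrap with 500 replications
```

The observed SD of the dyadic indices exceeds every permuted value
(P ≈ 0): companionship is non-random. The eigenvector method recovers
the three planted clusters exactly (the generator's ground truth is in
`sim$truth`), with modularity well above the conventional 0.3 threshold
for a meaningful division, and S ≈ 1.2 indicates a well-differentiated
society whose index matrix is a good proxy for the true one (r ≈ 0.78).

`run_pipeline()` chains every stage, writes CSV/JSON/Newick/GraphML
outputs plus figures into an output directory, and returns all stage
objects; a single seed is fanned out deterministically to each
stochastic stage.

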