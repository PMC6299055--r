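---
title: "Methods: association analysis of photo-ID encounter data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: association analysis of photo-ID encounter data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(podnet)
```

podnet implements the standard analysis chain for "gambit of the group"
photo-identification data: every identified member of an encountered
group is treated as associated with every other member, a day (or a
multi-day window) is the sampling period, and all downstream inference
is built on per-period group-by-individual incidence matrices. This
vignette records the models, the parameters that matter, the numerical
choices, and what the built-in simulator does and does not emulate.

## Data restriction

Association indices are biased by rarely seen animals, so the filter
`apply_restrictions()` keeps only individuals seen on at least 4
occasions *and* in at least 2 calendar years (both configurable);
mother-dependent calves are removed first because their presence is not
independent of the mother's. Same-day encounters whose retained
membership sets are identical are treated as repeat records of one group
and deduplicated to the earliest record. Two choices here were genuinely
open:

- *Which membership defines a "different group" on the same day?* We
  compare retained-membership sets, not full sets: two records that
  differ only in a transient are the same social unit for every
  statistic we compute.
- *Order of operations.* Deduplication can push an individual below the
  sighting thresholds, so the filter iterates to a fixed point. This
  makes restriction idempotent, which the tests assert.

Individuals that never survive the filter are dropped from the incidence
matrices entirely rather than kept as all-zero columns; this matters for
the null association rate, whose scale is 1/(N−1).

Multi-day periods tile forward from the first observation date; daily
periods are anchored at local midnight.

## Association indices

For each unordered dyad the period tallies are `x` (together), `y_ab`
(both identified, never together) and `y_a`, `y_b` (only one
identified). The half-weight index `x/(x + y_ab + (y_a+y_b)/2)` is used
because group coverage is incomplete in photo-ID work. Note the
algebraic consequence `d = (seen_a + seen_b)/2`: the denominator depends
only on how often each animal was identified, which is what makes the
permutation chain below cheap. Dyads never co-identified in any period
have an undefined index; we define it as 0 and warn.

The gregariousness-corrected index
`HWIG_ab = HWI_ab · ΣHWI/(s_a s_b)` (row strengths `s`, ordered-pair
total `ΣHWI`) removes the tendency of sociable animals to show inflated
indices with everyone. Under equal gregariousness HWIG is a constant
rescaling of HWI (factor N/(N−1) when all indices are equal): it
preserves structure, not scale, and the tests lock exactly that
property.

## Permutation test for non-random association

The Manly–Bejder within-sample test randomises group membership while
holding fixed (i) every group size and (ii) every individual's number of
identifications per period, by a Markov chain of 2×2 checkerboard swaps
confined to a single period's matrix — flips never move an animal across
periods. The SD and CV of the dyadic indices are saved along the chain;
one-sided p-values (greater) express the preferred/avoided-companion
alternative, with a two-sided option.

Chain schedule: the proposal picks a period with probability
proportional to its matrix size, then a uniform 2×2 submatrix, swapping
when it is a checkerboard; staying put otherwise keeps the kernel
symmetric. Saves are taken every `flips_between_saves` steps. The
default is adaptive — five times the number of occupied incidence cells,
at least 1000, with a burn-in of ten times that — because saves taken
faster than the chain mixes under-disperse the null and inflate the
test. We calibrated this on the simulator's random-association society:
with the adaptive schedule the empirical type-I error at α = 0.05 sits
inside the binomial 95% interval over 200 replicates (the acceptance
suite re-runs this check). The kernel is compiled and maintains the
joint-count matrix incrementally, so 20,000 saved permutations on a
~115-period record take seconds.

The test refuses degenerate inputs (no dyadic variation, or no period
with two groups) rather than returning a vacuous p-value.

## Standardized lagged association rate

For ordered period pairs (j, k), lag measured between period midpoints
in days, the estimator accumulates over individuals A and partners B:
numerator `a_j(A,B)·a_k(A,B)` and denominator
`a_j(A,B)·1[A identified in k]·n_k(A)`, with `n_k(A)` the number of
identified associates of A in k. For permanent groups of size g under
full identification this plateaus at exactly 1/(g−1), which anchors the
scale in tests. Terms are sorted by lag and pooled greedily into
non-overlapping windows whose summed denominator reaches the
`moving_average_size` (default 8000 associations); a trailing window
under half the target is pooled with its neighbour. Windows are plotted
at the denominator-weighted mean lag.

- **Jackknife SEs** omit one sampling period at a time with window
  boundaries frozen; a window that loses its whole denominator yields a
  missing SE and a warning rather than a silent zero.
- **The null rate** permutes individual identities uniformly within
  each period (group sizes and identification counts preserved) and
  re-aggregates with the observed window map; for dyadic groups and
  uniform detection it converges to 1/(N−1), an analytic limit the tests
  check. It is defined by permutation rather than a closed form so that
  the same machinery is testable on any design.
- **Model fitting.** Each window contributes
  `num ~ Binomial(den, g(τ̄))` to a likelihood; the four standard models
  are CC `g = a`, CA `g = a·e^(−bτ)`, CC+CA `g = a + c·e^(−bτ)` and 2CA
  `g = a·e^(−bτ) + c·e^(−dτ)` with a, c ∈ [0,1] and b, d ≥ 0 (units:
  1/days). The CC maximum likelihood estimate is the pooled proportion
  (closed form); the others are fitted by Nelder–Mead on
  logit/log-transformed parameters from several starts. Overdispersion
  ĉ is the Pearson χ²/df of the most general model (2CA), floored at 1,
  and `QAIC = −2logL/ĉ + 2K` ranks the models. Binomial
  quasi-likelihood was chosen over least squares so that QAIC has a
  principled likelihood underneath it. Window counts are dependent
  across overlapping period pairs; ĉ absorbs that overdispersion, which
  is precisely why QAIC rather than AIC is used. Whether "8000
  associations" counts numerator or denominator terms was ambiguous; we
  accumulate denominators, the quantity that controls estimator
  precision.

## Social units

`average_linkage()` clusters on dissimilarity 1 − index and reports
merge heights back on the index scale, plus the cophenetic correlation
coefficient as the validity check for a hierarchical reading (exactly
ultrametric input gives CCC = 1).

Modularity uses the standard Newman weighted form
`Q = Σ_c [W_c/T − (S_c/2T)²]`. Because the expected association of a
dyad under this null is the normalised product of row strengths, this
form *is* the gregariousness-corrected ("modularity-G") variant when
applied to association indices; a uniform-expectation null is available
as the plain alternative and both are labelled in outputs.
`eigenvector_communities()` recursively bisects by the sign of the
leading eigenvector of the generalized modularity matrix B^(g), with
Kernighan–Lin fine-tuning (full sweeps that move every vertex once and
keep the best intermediate state); when the spectrum says indivisible
the sweep still gets one chance from the most favourable single
exclusion. On planted two- and three-block matrices with N ≤ 8 the
method matches exhaustive maximisation over all partitions in the test
suite. `best_dendrogram_cut()` scans the midpoints between consecutive
merge heights, returns the argmax-Q cut with the full (threshold, Q)
curve, breaks ties towards fewer clusters, and reports singleton
clusters as their own cluster *plus* a nearest-cluster suggestion by
mean index — outliers are surfaced, never silently reassigned.

## Node metrics

Strength, reach (`A·s`), affinity (reach/strength), power-iteration
eigenvector centrality (unit norm, non-negative), the max(a)-normalised
weighted clustering coefficient, and betweenness/closeness on edge
lengths 1/a. Closeness is scaled `100·(n−1)/Σd` within an individual's
connected component; the ×100 scaling is a reporting convention, flagged
in the documentation because closeness conventions differ across
packages, and disconnected networks are flagged rather than silently
patched. Path-based metrics (betweenness, closeness) are delegated to
igraph; everything else is closed-form linear algebra checked against
brute-force loops in the tests.

## Social differentiation and class tests

Dyadic joint counts are modelled as
`x_ab ~ BetaBinomial(round(d_ab), μ, θ)` — half-weight denominators are
non-integral, so they are rounded half-up — fitted by maximum
likelihood. S is the CV of the fitted Beta;
`r = sqrt(Var(p)/(Var(p) + E[p(1−p)/d]))` comes from the variance
decomposition of the index estimator and tends to 1 as effort grows.
SEs bootstrap over dyads (default 10,000 replications). The near-zero-S
boundary is handled by the binomial limit of the likelihood at θ → 0.

The Mantel class test correlates the index matrix with the same-class
indicator matrix under simultaneous row/column permutation and reports
the standardised t, the two-tailed p, and both one-tailed proportions —
the sidedness of published "P = 1.0"-style results is ambiguous, so all
three are exposed. Fisher's exact test (via `fisher.test`, the
conventional sum of tables no more probable than the observed) drives
the diel-partitioning contrast of morning [07:00, 13:00] versus evening
(18:00, 21:00] encounter counts; encounters join a cluster by strict
majority of retained members, ties and memberless encounters are set
aside. Group sex composition counts only groups with ≥ 2 known-sex
members, ignoring unsexed animals — a classification floor, since
"single-sex" groups with unsexed members may in truth be mixed. Trawler
interactions are counted as gear events: an encounter with both gears
contributes one event per gear, so gear counts sum to the total.

## The society simulator

`simulate_society()` generates a fission–fusion society with known
truth. Default conditions describe a small resident coastal population:
clusters of 19/13/6 animals surveyed over 9 years (~14 survey days per
year across morning/afternoon/evening bins, mostly summer), giving
roughly 115–140 usable encounters of 38 residents after restriction.
Members attend an occasion of their cluster with probability
w = 0.3; attendees fuse into one group with probability 0.7 or split
into 2–4 subgroups; animals from other clusters spill into a group with
probability b = 0.01, so mixed groups have a clear majority plus a few
outsiders. Cluster availability is diel-structured (the first cluster
in the core area only in the morning, the second only in the evening,
the third indifferent), detection is 0.7 per group, identification 0.95
per member, transients arrive Poisson(5) per year and are seen in a
single year, four mother-dependent calves ride along with their
mothers, and trawler-interaction propensity is concentrated in the
first cluster (0.5 per encounter vs 0.02/0.08), with a
0.6/0.35/0.05 pair/bottom/both gear mix. These values were chosen once
to emulate the scale and structure of a long-term coastal dolphin
photo-ID study; presets `paper-like`, `null-random` (association
structure off — the type-I calibration condition) and `two-clique-toy`
ship as YAML.

Ground truth includes the expected half-weight index per dyad:
within-cluster `w·q_same`, where
`q_same = 0.7 + 0.3·mean(1/{2,3,4}) ≈ 0.81` is the co-grouping
probability given joint attendance (joint attendance w² over half the
summed attendance w gives the factor w), and b between clusters. The
convergence of empirical indices to this truth at high effort is a
test.

What the generator does *not* emulate: spatial movement and home
ranges, demography (births, deaths, emigration), photographic quality
variation, temporal trends in social structure (true association
probabilities are lag-independent, so the generating SLAR model is CC
by construction), and observer effects beyond Bernoulli detection and
identification. Passing recovery studies therefore show the estimators
work under idealised sampling of a structured society, not that any
particular field data set meets these assumptions.

## Numerical choices and problem sizes

Sample SDs use the n−1 denominator throughout. Likelihood probabilities
are clamped to [1e−12, 1 − 1e−12]. Modularity ties break towards fewer
clusters. The master seed of `run_pipeline()` is fanned out through
fixed affine offsets to per-stage seeds, so any stage can be reproduced
in isolation; all seeds stay below 2³¹.

The test suite runs its Monte-Carlo studies at sizes chosen for tight
feedback: clustering recovery over 100 simulated societies, type-I
calibration over 200 replicates of 1000 permutations each,
differentiation recovery over 100 beta-binomial draws of 500 dyads at
d̄ = 30, and model selection over 100 simulated SLAR curves of 8 windows
with denominators of 8000. The acceptance script runs the full pipeline
once at publication-scale settings (20,000 permutations, 10,000
bootstrap replications).

## Known limitations

- The moving-average windowing is non-overlapping and greedy; published
  analyses sometimes use sliding windows, so window placement (not the
  underlying terms) can differ between implementations.
- Betweenness/closeness conventions vary across software; values are
  comparable within podnet analyses, not across packages.
- The beta-binomial treats rounded half-weight denominators as fixed
  binomial sizes, ignoring their sampling variability.
- QAIC's absolute scale depends on the likelihood constant and on ĉ;
  only differences (ΔQAIC) are interpretable.
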