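---
title: "Subtype discovery with the 3C strategy: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subtype discovery with the 3C strategy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(threec)
```

This vignette is the package's account of the science it implements: the
model behind each stage, the tunable parameters and why their defaults are
what they are, what the synthetic-data generator does and does not
emulate, and the numerical choices made where the design was genuinely
open.

## The problem

Clinical diagnoses on the dementia spectrum (CN, SMC, EMCI, LMCI, AD) are
assigned by thresholding a handful of cognitive instruments. They are
informative but crude: a single diagnostic label may cover several
pathophysiological entities with different biomarker profiles. Purely
unsupervised clustering of all available variables is no remedy — most
variables are irrelevant, and clustering degrades quickly with irrelevant
dimensions. The 3C strategy threads this needle:

* **Categorize** variables by what they *mean* (knowledge-driven):
  assigned diagnosis DX, clinical measurements CM (manifestations of the
  disease), potential biomarkers pBM (biological measures with no asserted
  clinical meaning).
* **Cluster** subjects on a *screened* subset of CMs, where screening is
  supervised by DX — using the diagnosis as a hint about relevance without
  accepting it as truth — and the clustering itself is unsupervised.
* **Classify**: ask which pBMs separate the new clusters, with multiplicity
  control honest about the two-stage selection. The pBMs never participate
  in forming the clusters, so the signatures are not self-fulfilling.

## Stage models and parameters

### Random-forest screening (cluster stage, step 1)

Relevance of each CM for DX is measured by permutation importance
averaged over `n_forests_threshold = 50` forests (the published default of
the two-step screening procedure this follows), each of
`num_trees = 100` trees (package default; raising it buys smoother
importance estimates at proportional cost). The *thresholding* step drops
CMs whose mean importance falls below the minimum of a regression-tree fit
of importance sd against importance rank: for irrelevant variables the
importance fluctuates around zero with a characteristic sd, and the tree's
minimum predicted value estimates that noise floor. The *interpretation*
step then fits nested forests on the top-1, top-2, … surviving variables
(`n_forests_interpretation = 25` forests each) and keeps the smallest
prefix whose mean out-of-bag error is within one sd (across the 25
forests) of the best prefix's error — a parsimony rule that actively
de-duplicates redundant predictors. Zero-variance CMs are removed up
front; they carry no information and their importance is identically zero.

Two consequences worth knowing:

* the sd band means the selected set is the smallest *adequate* set, not
  the set of all marginally informative variables;
* selection is invariant to CM column order up to forest randomness, which
  is controlled by the explicit `seed`.

### k-medoids with Manhattan distance (cluster stage, step 2)

Subjects are clustered around observed exemplars (medoids) under the
Manhattan (L1) metric, which is less dominated by single extreme variables
than squared Euclidean distance and pairs naturally with the rank-based
classify stage. The optimizer is PAM: greedy BUILD initialization followed
by best-improvement SWAP passes. Single-start PAM, however, can land in a
local optimum several percent above the global one even on tiny problems;
`kmedoids_manhattan()` therefore runs one BUILD start plus
`nstart − 1 = 9` seeded random starts and keeps the lowest-cost SWAP
result (ties favor the BUILD start, keeping the classical behavior the
default). On 200 random instances small enough for exhaustive medoid
search, the multi-start version matches the exact optimum on all of them.
Assignments always satisfy the model contract — each subject to its
nearest medoid, ties to the lowest medoid index — and `cost` is the sum
of Manhattan distances to own medoids. When `k` equals the number of
distinct rows the solution is written down directly (every distinct row a
medoid, cost 0).

Screened CMs enter the distance unstandardized by default: the screening
already restricts to comparably scaled, DX-relevant variables, and the
original formulation is silent on scaling. Standardize beforehand if your
CMs live on wildly different scales.

### Gap statistic and the candidate range for k

The within-cluster dispersion is `W_k = Σ_r D_r / (2 n_r)` with `D_r` the
sum of within-cluster pairwise Manhattan distances counted in both orders.
`B = 50` reference data sets are drawn uniformly over the per-feature
range box of the observed data (the simple reference; a PCA-aligned box is
deliberately not offered since the Manhattan/medoid setting has no natural
rotation), clustered identically, and
`Gap(k) = mean_b log W*_kb − log W_k` with the standard-error term
carrying the `sqrt(1 + 1/B)` factor. `choose_k_candidates()` translates
the curve into advice: a *drop* at k means `gap(k+1) < gap(k)`; with two
or more drops the inclusive range from the first through the second drop
is returned (a curve dropping after 3 and again after 8 suggests
candidates 3–8); with exactly one drop the classical one-standard-error
rule gives a singleton; with none, the largest k is returned with a
warning. The final k is a required, explicit analyst input to the
pipeline — combining statistical candidates with subject-matter review is
part of the method, not a gap to be automated away.

### Signature testing and hierarchical FDR

Stage 1 screens the M candidate pBMs with Kruskal–Wallis tests (midranks,
tie correction, chi-square reference) and Benjamini–Hochberg at budget
`q = 0.05`. Stage 2 tests each selected pBM's k(k−1)/2 cluster pairs with
two-sided Wilcoxon rank-sum tests — exact enumeration when the pooled
sample is ≤ 20 without ties, otherwise the normal approximation with tie
and continuity corrections — and applies BH *within each selected pBM's
pair family* at the selection-adjusted level `q·S/M` (S = number selected
of M screened). Testing selected families at q·S/M preserves the average
FDR over the selected families; with 51 selected of 170 candidates the
working level is 0.05·51/170 = 0.015. Whether the original analysis pooled
all pairwise p-values or adjusted per family is not documented; the
per-family reading matches the selection-adjusted formulation it cites,
and `pool_pairs = TRUE` provides the pooled alternative. The sign of a
rejected pair follows the mean-rank direction. Every decision in this
stage depends on ranks only, so strictly monotone transforms of a pBM
change nothing — tested as an invariant.

Pairs involving a cluster with fewer than two subjects are reported
untestable (sign 0, p absent) rather than tested.

### Reporting layer

Profiles map each variable to pooled empirical quantiles
`(midrank − 1)/(n − 1)` — pooling across clusters is what makes cluster
medians comparable on one axis, and this convention sends the observed
minimum to 0 (healthy end) and maximum to 1 (rather than the rank/n
alternative, which reaches neither endpoint). Variables oriented "higher
is better" are flipped using the catalog's direction field; variables with
direction `none` are excluded with a warning, since orientation is
clinical knowledge the package refuses to guess. Cluster medians carry
order-statistic CIs from the Binomial(n, ½) distribution: lower endpoint
`x_(l)` with l the largest integer whose binomial CDF at l−1 is ≤
(1−level)/2, upper endpoint analogously. Which tail-rounding convention
underlies published ribbons is unstated; this standard rule guarantees
≥ level coverage for continuous data (at n = 24, theoretical coverage is
0.977) and is property-tested for empirical coverage. Variable ordering
uses average-linkage hierarchical clustering of median-profile vectors
(Euclidean), with dendrogram leaves reordered by mean profile value so the
ordering is canonical up to reflection. The signature heatmap organizes
the three-state codes with average linkage on Manhattan distances, under
which a 0↔±1 disagreement counts half a +1↔−1 disagreement.

## The synthetic-data generator

`simulate_cohort()` plants a known truth in data shaped like a baseline
clinical cohort. Defaults are the package's study conditions: 650
subjects (a typical complete-case cohort size), k = 6 subtypes, 144 CMs
of which 5 are informative, 170 pBMs of which 20 carry shifts, effect
size 4, DX label-shift noise 0.1, cell missingness 0.001 + 0.001 per
severity level.

* **Latent severity and DX.** Each subject's severity is its cluster index
  mapped to equally spaced scores plus a within-cluster jitter; DX is the
  five-level quantile cut of severity, with probability `dx_noise = 0.1`
  of a one-level shift. DX is therefore a genuinely crude, overlapping
  surrogate of the planted structure — the premise the whole strategy
  rests on.
* **Informative CMs** share that latent severity: cluster centers spaced
  `effect_size` apart along the severity axis, plus the subject's shared
  within-cluster jitter, plus independent unit noise (Gaussian by default;
  `heavy_tails = TRUE` switches to scaled t with 3 df for probing the
  rank-based stages). Sharing the jitter matters: it makes each
  additional informative CM genuinely sharpen the severity estimate, so
  the interpretation step's error curve keeps improving across the
  informative set instead of treating the CMs as interchangeable copies
  and keeping only one. Five informative among 139 noise CMs is the
  regime in which the two-stage screen operates as intended — a small
  relevant minority hidden in a large irrelevant majority.
* **pBMs.** Each signal pBM shifts by `effect_size` standard deviations in
  one or two designated clusters; null pBMs are iid. The planted
  (pBM, cluster-pair) differences are recorded for oracle checks.
* **Directions.** Half of all generated variables are oriented
  "higher = worse" and half "higher = better", forcing the reporting layer
  to handle orientation explicitly.
* **Missingness** is injected per cell with probability
  `base + gradient × severity level`, emulating cohorts where missingness
  is informative of diagnosis. The DX column itself is never masked (the
  masking model conditions on it). The small default rates are chosen so
  that, across ~175 measurement columns, complete-case filtering produces
  the characteristic subject-heavy, variable-light reduction of such
  cohorts rather than discarding everyone.

What the generator does **not** emulate: correlated within-cluster CM
structure (covariance is diagonal — the original cohort's covariance is
uncharacterized), mixed variable types among CMs/pBMs (all continuous),
imaging-derived spatial structure, longitudinal visits, and real
instrument floor/ceiling effects. Passing tests on generated data
therefore demonstrate that the pipeline recovers the kind of structure it
is designed for; they do not certify behavior under every pathology of
real clinical data.

## Preprocessing conventions

* **Complete cases, variables first.** Variables with missing fraction
  above 0.3 are dropped, then any subject with a remaining missing cell.
  The order is a deliberate choice: in cohorts with informative
  missingness the reduction should be variable-light and subject-heavy.
  No imputation is offered — when missingness is informative of
  diagnosis, imputation would inject the diagnosis into every variable.
* **Redundancy.** Continuous pairs with |Pearson r| > 0.99 lose the later
  variable in catalog order (deterministic; catalog order is
  user-controlled); discrete variables with Gini impurity
  1 − Σ p² < 0.05 are dropped; constant continuous variables count as
  Gini-degenerate. The pass is idempotent.
* **Domain composites** are row sums of item scores; items must share a
  severity direction, which the composite inherits.
* **Monotone transforms.** Candidates are identity, log, square root
  (shifted only when the domain requires it) and rank-normal scores; the
  selection criterion is |sample skewness| alone — the original
  methodology also names linearity and variance homogeneity, without
  formulas, so this is a documented simplification. Rank-normal scores
  have essentially zero skewness by construction and would otherwise
  always win; the earliest candidate within `max(0.1, 2·√(6/n))` of the
  minimum is preferred — the tolerance is twice the skewness estimator's
  own sampling sd under symmetry, so a less interpretable transform must
  beat a simpler one by more than estimation noise.

## Numerical choices and degenerate inputs

* All stochastic steps take explicit integer seeds; PAM restarts save and
  restore the caller's RNG state so surrounding simulations (e.g. the gap
  statistic's reference draws) are unaffected.
* Constant vectors: Kruskal–Wallis returns H = 0, p = 1; the quantile
  transform returns 0.5 everywhere with a warning; `monotone_transform()`
  returns the input flagged degenerate; the gap statistic refuses fully
  constant data.
* Tie-breaks are fixed and documented: nearest-medoid ties to the lowest
  medoid index; correlated-pair drops keep the earlier catalog variable;
  transform near-ties keep the simpler transform; equal-cost PAM starts
  keep the BUILD solution.
* `bb_adjusted_level()` computes q·S/M in double precision; 0.05·51/170
  agrees with 0.015 to ~1e−18, so exact comparisons should be read at
  printed precision.

## Problem sizes used in the checks

The package's test suite exercises the full pipeline at the default
cohort scale (n = 650, 144 CMs, 170 pBMs, k = 6) once, and uses smaller
cohorts (n = 120–400) for per-module properties. Monte-Carlo checks use
500 replicates for the screening-stage FDR (n = 300, 4 clusters, 20
signal + 150 null pBMs, 2 SD effects), 200 random instances for the
exhaustive k-medoids oracle (n ≤ 9, k ≤ 3), full enumeration for Wilcoxon
(m, n ≤ 6), 1000 random vectors for the BH step-up oracle, 20 seeds of
three-blob simulations for the gap statistic (B = 50), and 2000
replicates (n = 24 each) for median-CI coverage. These sizes are the
package's standing definition of "desk scale": large enough for the
asymptotic approximations involved, small enough to re-run routinely.

## Known limitations

* The interpretation step returns the smallest adequate CM set; highly
  collinear informative CMs will be represented, not exhaustively listed.
* The gap statistic's uniform-box reference is simple and can be
  conservative for elongated clusters.
* Monotone-transform selection considers skewness only.
* The generator's diagonal covariance understates the difficulty of real
  cohorts with correlated measurement batteries.
* Signature signs summarize pairwise mean-rank direction; they do not
  quantify effect sizes.
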