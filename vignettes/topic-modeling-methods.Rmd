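---
title: "Disease-topic modeling of the EHR phenome: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disease-topic modeling of the EHR phenome: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(genotopics)
```

## The problem

A phenome-wide association study tests one variant against thousands of
phenotypes one at a time. Diseases, however, arrive in correlated bundles —
an individual with coronary atherosclerosis tends also to carry
hyperlipidemia and hypertension codes — and a per-phenotype scan both pays
for every test at the Bonferroni counter and cannot see these bundles as
units. `genotopics` factorizes the phenome first: it learns a small set of
disease *topics* from the binary individual×phecode matrix and then tests
each individual's topic loading against the genotype, reducing thousands of
correlated tests to a handful of interpretable ones.

## Model and solver

With `X` the n×m binary phenotype matrix, the package minimizes

$$\min_{W \ge 0,\, H \ge 0}\; \lVert X - WH\rVert_F^2
  + \lambda\left[\gamma\,(\lVert W\rVert_1 + \lVert H\rVert_1)
  + \tfrac{1}{2}(1-\gamma)\,(\lVert W\rVert_F^2 + \lVert H\rVert_F^2)\right]$$

`W` (n×k) gives each individual's relevance to each topic; `H` (k×m) gives
each topic's weight on each phecode; the elastic-net term encourages sparse
topics, reflecting the assumption that an individual carries a small set of
diseases.

Three conventions deserve emphasis:

* **λ is literal.** The penalty enters exactly as written, with no
  rescaling by `n` or `m`. Some libraries multiply their regularization
  constant by a matrix dimension; a λ tuned there is not the same λ here.
* **Solver.** Cyclic HALS coordinate descent: each column of `W` (row of
  `H`) has a closed-form nonnegative minimizer of its quadratic subproblem,
  with the L1 penalty entering as a constant shift `-λγ` in the numerator
  and the L2 penalty as `+λ(1-γ)` in the denominator, followed by
  projection onto `[0, ∞)`. Because every update solves its subproblem
  exactly, the objective trace is non-increasing; the test suite asserts
  this on every fit it makes, and checks the analytic gradients behind the
  updates against finite differences.
* **Initialization.** Default is uniform random on
  `[0, sqrt(mean(X)/k)]` under an explicit seed, so fits are exactly
  reproducible; deterministic NNDSVD is available via `init = "nndsvd"`.
  Convergence is declared when the relative objective change per sweep
  falls below `tol` (default `1e-6`, cap 500 sweeps).

Tunable parameters, defaults, and why:

| parameter | default | meaning |
|---|---|---|
| `k` | 6 | number of topics; chosen from the SVD scree (`scree()`) of the column-centered matrix — look for the elbow |
| `lam` | 0.2 | elastic-net weight; 0 disables regularization |
| `gamma` | 0.5 | L1 share of the penalty; 1 = pure lasso-style sparsity |
| `t` | 10 | descriptor size for all topic metrics (ranked-table size; word-cloud style displays typically use more) |

Degenerate inputs: all-zero phecode columns are retained (their `H`
entries are driven to 0 by the penalty); an all-zero matrix is rejected;
`k` may not exceed `min(n, m)`. Argmax topic assignment breaks ties toward
the lowest topic index and returns `NA` for an all-zero loading row.

## Topic quality metrics

* **Descriptors** (`top_descriptors`): the `t` largest-weight phecodes per
  topic; weight ties break lexicographically so results are deterministic.
* **Dependency** (`topic_dependency`): mean pairwise Jaccard between
  descriptor sets. 0 = disjoint topics, 1 = identical; high values flag
  redundant topics.
* **Coherence** (`topic_coherence`): UMass form — for descriptors ranked
  `w_1, ..., w_t`, the mean over ordered pairs of
  `log((D(w_i, w_j) + 1) / D(w_j))` with `D` counting individuals. The
  exact co-occurrence formula behind this choice is one of the genuinely
  open design points; UMass with ε = 1 was chosen because it needs nothing
  but the fitted corpus, and it is isolated behind one function so a
  different formula is a one-function change. Pairs whose lower-ranked
  descriptor never occurs are undefined and dropped with a warning.
* **Stability / agreement** (`topic_agreement`, `stability_scan`): the k×k
  Jaccard matrix between two models' descriptor sets is matched one-to-one
  by a hand-written O(k³) Hungarian algorithm (tested against exhaustive
  permutation search up to k = 6), and the agreement score is the mean
  matched similarity. `stability_scan` refits over a grid of λ, γ, k and
  seeds and scores each fit against a reference model, the standard way to
  check that topic meaning does not hinge on the tuning parameters.

## The association analyses

`topic_association` runs both tests the workflow relies on:

* **Pearson correlation** of each `W` column with the allele count
  (0/1/2), two-sided p from the t-distribution on n−2 df.
* **Logistic regression** of carrier status on predictors. Carrier coding
  reads "allele count ≥ 1 → 1": for a low-MAF variant the homozygous-minor
  class is tiny (0.6% at MAF 0.077), so the dichotomy is the practical
  outcome coding. The default is one *joint* model with all k topic
  columns plus age and sex — a single coefficient table with one row per
  topic and covariate — because the topic loadings compete for the same
  variance and a joint fit adjusts each topic for the others;
  `joint = FALSE` gives the marginal per-topic variant. Wald z-tests are
  reported, matching common PheWAS practice.

`phewas` is the conventional comparison: one logistic regression per
phecode with the phecode as outcome and allele count, age and sex as
predictors (the conventional orientation), with a Bonferroni threshold of
`alpha / #tested`. Phecodes with fewer than 20 cases (or fewer than 20
controls) are skipped as unstable; 20 is our floor, not an external
standard. Both ordinary model fits go through `stats::glm`; the test suite
cross-checks them against a hand-written likelihood maximized
independently, and checks the Pearson test against the closed form at
1e-12.

## The synthetic cohort generator

No clinical cohort ships with the package, so `simulate_cohort` generates
data with exactly the structure the analysis assumes:

1. `H_true`: k topic rows with disjoint cores of `core_size` phecodes at
   `core_weight` (default 1.0) and `background_weight` (default 0.01)
   elsewhere. Disjoint cores make descriptor recovery unambiguous.
2. `W_true`: i.i.d. Gamma(`loading_shape` = 0.5, scale 1) loadings.
3. A Hardy–Weinberg genotype at `maf` (default 0.077, the motivating
   low-frequency variant's cohort value).
4. A planted effect: `W[i, t] += effect_beta * g[i]` on one target topic —
   additive, so the signal the Pearson test assumes is linear by
   construction.
5. Phenotypes `X_ij ~ Bernoulli(1 - exp(-(W_true H_true)_ij))`. The
   complementary-log link maps any nonnegative intensity smoothly into
   `[0, 1)` and is monotone in the intensity; no generative model for `X`
   is prescribed by the workflow itself, so this is a stand-in chosen for
   smoothness over `min(1, intensity)`-style clipping.
6. Age ~ Normal(70.3, 12.3²) truncated at 18 years and sex ~
   Bernoulli(0.528), independent of genotype by default;
   `confound_age_sex = TRUE` shifts carriers' age and sex so
   covariate-adjustment tests have a real confounder to absorb.

The default cohort size is n = 3000 individuals × m = 400 phecodes with
k = 6 topics — a desk-scale analogue of a biobank EHR cohort that keeps a
full multi-seed recovery study in minutes on one CPU while preserving the
regime that matters (sparse matrix, ~7% density, low-MAF genotype,
modest per-allele effect `effect_beta` = 0.8 giving r ≈ 0.45 at this n).

**What the generator does *not* emulate** — and hence what passing
recovery tests do and do not show: real phenomes have heavy-tailed phecode
prevalence, hierarchically correlated codes, comorbidity correlations
*between* topics, and coding-intensity artifacts (utilization), none of
which are present here. Recovery of planted cores shows the solver and
metrics work as specified; it does not certify performance on real EHR
data. One concrete consequence we document rather than hide: on real data,
topic dependency falls as k grows from 5 to 15, because small-k topics
share the phenome's dominant prevalent codes. The symmetric generator has
no such shared dominant codes, so fitted descriptor sets are disjoint
(dependency ≈ 0) whenever k ≤ the planted topic count, and splitting or
empty topics make dependency *rise* for larger k — the real-data direction
is not reproducible from this generator, and the corresponding qualitative
check in the acceptance suite fails by design rather than being weakened.

```{r, eval = FALSE}
coh <- simulate_cohort(sim_config(seed = 1))
fit <- fit_nmf(coh$X, k = 6, seed = 1)
descriptor_core_recovery(top_descriptors(fit, t = 10), coh)
```

## Numerical choices and edge cases

* Seeds: every stochastic step takes an explicit seed; package functions
  never touch the caller's global RNG state (`withr::with_seed`
  internally). A cohort is a deterministic function of its full
  `sim_config`, including the seed.
* The Frobenius residual is computed as
  `||X||² - 2<W, XHᵀ> + <WᵀW, HHᵀ>`, never via the dense n×m residual, so
  large sparse matrices stay sparse.
* A HALS denominator of zero (empty topic under λ(1−γ) = 0) zeroes the
  corresponding column rather than dividing by zero.
* Hungarian matching with unequal topic counts pads the smaller side with
  empty topics (similarity 0) and flags the result.
* Monotonicity of the objective trace is asserted with 1e-10 absolute
  slack to absorb floating-point rounding in the trace itself.

## Problem sizes used in validation

The shipped validation suite fits the default 3000×400 cohort across 5
seeds for descriptor recovery, 20 seeded cohorts for planted-association
detection, and 200 reduced cohorts (400×100, k = 4) for the null
calibration of the per-topic Pearson test — the null rejection-rate
property is size-invariant (genotype independent of `X` implies uniform
p-values for any function of `X`), so the smaller size trades nothing but
variance of the estimated rate. Published-scale inputs (≈12,800×1,850)
run through the identical code paths; only the matrix is larger.

## Known limitations

* Presence/absence phenotypes only; diagnosis-code counts are not used.
* Single SNP, no linkage disequilibrium, no population stratification or
  genetic risk scores; ICD-9-style maps only (any two-column map file
  works, but no ICD-10 hierarchy logic is applied).
* The coherence formula is one defensible choice among several (NPMI and
  embedding-based variants are out of scope).
* The generator's distributional choices (Gamma loadings, complementary-log
  link) are stand-ins, as flagged above, not estimates from any cohort.
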