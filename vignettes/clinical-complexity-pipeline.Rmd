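---
title: "Phenotyping clinical complexity in youth mental health episodes of care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping clinical complexity in youth mental health episodes of care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(youthcomplexity)
```

## The problem

Youth primary mental health services practice a "no wrong door" policy and
therefore see everything from mild distress to severe, multi-domain need.
Service planners want a data-driven way to segment episodes of care (EOCs)
by *clinical complexity* — not just diagnosis and severity, but the
combination of clinical and psychosocial factors that drives clinical
workload. `youthcomplexity` implements such a segmentation for cohorts
shaped like a youth mental health minimum data set: per-visit clinical
measures and flags are reduced to 13 binary complexity indicators, episodes
are clustered into complexity phenotypes, and cluster membership is related
to demographic risk factors.

The pipeline has five statistical stages, each exposed as ordinary
functions and sequenced by `run_pipeline()`:

1. **Indicator mapping** (`derive_indicators()`): 13 binary indicators from
   raw fields, with any-visit ("ever during the episode") aggregation.
2. **Multiple imputation** (`impute_indicators()`): chained-equation
   logistic imputation of missing indicators, m completed datasets.
3. **Consensus clustering** (`consensus_kmeans()`, `select_k()`): k-means
   consensus clustering integrated over subsamples *and* imputations.
4. **Correlation network** (`pooled_tetrachoric()`, `mds_layout()`):
   pairwise tetrachoric correlations pooled across imputations, with a
   classical MDS layout for plotting.
5. **Risk-factor regression** (`fit_pooled()`): multinomial logistic
   regression of cluster membership on demographics, pooled by Rubin's
   rules and reported as relative risk ratios (RRRs).

Because real minimum-data-set extracts are confidential, the package ships
a first-class synthetic cohort generator (`generate_cohort()`) that emulates
one, so every stage is testable end to end.

## The indicator layer

An episode's raw material is a visit table with scale scores and
check-box flags. The default 13 indicators (`default_indicator_set()`) are:

| indicator | rule |
|---|---|
| very high psychological distress | K10 total > 30 at any visit |
| low quality of life | MyLifeTracker total < 40 (configurable) |
| low functioning | SOFAS ≤ 60 |
| later illness stage | clinician stage ≥ 2 |
| severe/complex disorder | psychotic, bipolar, personality or neurodevelopmental diagnosis |
| self-harm / suicidality | primary presenting issue |
| AOD treatment issue | visit flag |
| trauma history | visit flag |
| housing issues | visit flag |
| NEET | not in employment, education or training |
| education/employment issue | presenting issue |
| government benefits | visit flag |
| co-occurring difficulties | visit flag |

Three conventions matter:

* **Any-visit OR.** An indicator is 1 if its rule fires at *any* visit —
  episodes are assessed over their whole course, and adding a visit can
  only switch an indicator on, never off (a tested monotonicity property).
* **Missing vs absent.** Scale-based indicators are *missing* when the
  scale was never administered in the episode; check-box flags are 0 when
  the visit form exists and the box is unticked. This mirrors form-driven
  data collection.
* **Thresholds are parameters.** The K10 cut (strict `> 30`) and SOFAS cut
  (`≤ 60`) are published clinical conventions; the MLT cut has no
  published value, so `complexity_thresholds(mlt_low = ...)` exposes it
  (default 40) rather than hard-coding a guess. The severe-diagnosis list
  is likewise a configurable category set, since the package does not
  process raw DSM code lists.

Episodes missing *all* 13 indicators carry no information for the
clustering and are removed by `exclusion_filter()`, which reports the
accounting (`n_total = n_excluded + n_retained`, always conserved).

## Multiple imputation of binary indicators

Item missingness below the all-missing stratum is handled by chained
equations on the indicator layer (the analysis operates on indicators, so
no attempt is made to impute raw continuous scores). Each missing cell is
initialised by an observed-prevalence draw; the items are then swept in
ascending-missingness order for 10 cycles. Each item's conditional model
is a main-effects logistic regression on the other 12 indicators with a
small ridge penalty (1e-4) so sparse items and quasi-separation cannot
destabilise the fit; coefficients are drawn from their approximate
posterior before each redraw, which is what makes the imputation "proper"
enough for Rubin's rules to give near-nominal interval coverage (a tested
property: ≥ 90% empirical coverage of a planted prevalence at nominal
95%). Auxiliary covariates can be supplied but are off by default.
The default is m = 20 completed datasets; simulation-heavy tests and the
acceptance script use m = 5 at n ≈ 4,000, which keeps running times in
minutes without changing any qualitative behaviour.

Rubin's rules themselves live in `pool_scalars()`: pooled estimate = mean;
total variance = within + (1 + 1/m) · between; degrees of freedom by
Barnard–Rubin when a finite complete-data df is supplied, classical
otherwise. Correlations are pooled on the Fisher-z scale
(`pool_fisher_z()`).

## Consensus clustering over imputations

A single k-means run on ~10^5 binary rows is cheap but unstable: local
optima and sampling noise move boundaries. The package's
`consensus_kmeans()` therefore integrates two ensembles at once:

* over **imputations** — every completed dataset contributes runs, so
  imputation uncertainty propagates into the consensus; and
* over **subsamples** — within each completed dataset, R = 100 replicates
  (default) each cluster a p = 0.8 subsample drawn without replacement,
  using k-means with k-means++ initialisation on the raw 0/1 columns
  (all items share the same scale, so no standardisation by default;
  `scale_items` exposes the switch).

The consensus matrix divides pair co-clustering counts by pair co-sampling
counts. Never-co-sampled pairs (vanishingly rare at these settings) are
filled with the global mean consensus and logged. The final partition is
deliberately *not* the best single k-means run: it is the average-linkage
hierarchical cut of `1 − consensus` at k, which uses the full ensemble.
Labels are then renumbered by mean indicator burden, so cluster 1 is always
"low complexity" and cluster k "high complexity"; on the default 4-cluster
configuration the burden ordering low → distress → psychosocial → high is a
tested invariant.

Empty base-run clusters are handled with one re-seeded retry, after which a
reduced-k replicate is accepted — bounded retries keep runs deterministic
given the seed. Determinism is end-to-end: one master seed yields
per-imputation and per-stage substreams, and identical configurations
produce byte-identical artefact files.

### Choosing k

`select_k()` reports, per candidate k, the proportion of ambiguous
clustering (PAC): the share of consensus entries inside (0.1, 0.9). The
recommended k minimises PAC, but the return is deliberately advisory — in
clinical use the number of clusters is chosen for interpretability, and the
pipeline records the recommendation and any override separately. Two
behaviours of PAC are worth knowing:

* On clean structure, PAC collapses towards zero for every k at or above
  the planted k, and the argmin between those near-zero values is noise.
  Recovery of the planted k is therefore a *replicate-level* property
  (tested as ≥ 4 of 5 replicate simulations), not a single-draw guarantee.
* On homogeneous data with no subgroup structure, PAC stays high for all
  k ≥ 2; `select_k()` flags this as `no_structure` (PAC minimum above
  0.4).

## Tetrachoric correlation network

Associations between binary indicators are measured as tetrachoric
correlations: each pair is modelled as a dichotomised latent bivariate
normal, with thresholds fixed from the margins and the latent correlation
maximising the multinomial likelihood of the 2×2 table. Rectangle
probabilities come from a single-integral reduction of the bivariate normal
CDF evaluated by adaptive quadrature at absolute tolerance 1e-10
(`pbvnorm()`), which makes the likelihood trustworthy enough to verify the
maximiser against a brute-force grid search in the tests. Zero cells get a
0.5 continuity correction to every cell; estimates are clamped to ±0.999;
a degenerate margin returns an explicit `NA`.

Per-imputation matrices are pooled entry-wise on the Fisher-z scale; a pair
undefined in more than half the imputations is flagged missing. The layout
for network plots is classical (Torgerson) MDS on `√(2(1 − ρ))` after a
nearest-positive-semidefinite eigenvalue-clipping repair, centred, with a
sign convention fixing orientation. Classical MDS was chosen over spring
layouts because multidimensional scaling is the named visualisation; the
repo emits plot-ready coordinates and edge lists rather than styled
figures.

A limitation to keep in mind: the synthetic generator's latent-class
structure leaves indicators conditionally independent within clusters, so
its pooled correlation matrix has a long eigenvalue tail and *no* 2-D
embedding can reproduce it with low raw stress (stress-0 ≈ 0.4). The
layout tests therefore assert what a 2-D map can honestly deliver on such
data — correlated blocks (distress–quality-of-life; housing–NEET–benefits)
embed adjacently, and 2-D strictly improves on 1-D — rather than a small
absolute stress value, which would only be attainable for genuinely
low-dimensional correlation structures.

## Multinomial regression of cluster membership

`fit_multinomial()` is a Newton–Raphson maximum-likelihood fit with
step-halving (the log-likelihood is non-decreasing across iterations, a
tested invariant), run to gradient max-norm < 1e-8, with the inverse
observed information as covariance. Quasi-separation triggers one logged
retry with ridge 1e-6. The default model (`model_spec()`) regresses
cluster membership (reference: low complexity) on gender (reference
female), age group, Indigenous status, CALD background, and IRSAD
socio-economic tertile jointly with remoteness via a full interaction
(exposed as a switch). Coefficients exponentiate to relative risk ratios;
`rrr_percent_increase()` renders an RRR of 3.41 as "241% higher".

Cluster labels are treated as fixed when fitting: the consensus solution is
a single partition, and only quantities that involve imputed values are
fitted per completed dataset and pooled (`fit_pooled()` reduces exactly to
the single fit when given one complete dataset). Centre-clustered standard
errors are out of scope; the model is a plain multinomial fit, as reported.

## The synthetic cohort generator

`generator_config()` + `generate_cohort()` produce a two-table cohort
(episode demographics, per-visit measures) from a latent-class model:

* **Cluster mixture.** Default shares (0.398, 0.199, 0.218, 0.185) over
  four phenotypes, matching the published segmentation of 81,622 EOCs.
* **Indicator profiles.** `default_indicator_profiles()` is a stylised
  reconstruction of the four phenotypes from their qualitative
  descriptions (the study's within-cluster prevalence table is in
  unavailable supplementary material): a low-complexity majority; a
  distress phenotype (K10/MLT/SOFAS-driven); a psychosocial phenotype
  (similarly distressed plus housing/NEET/vocational/benefits); a
  high-complexity phenotype (later stage, severe disorders, trauma,
  co-occurring difficulties). Defining contrasts are ≥ 0.5 in
  probability; overall implied prevalences land near the published
  margins (distress ≈ 56% > 50%, low functioning ≈ 46%).
* **Separable profiles.** For recovery and k-selection experiments,
  `separable_indicator_profiles()` builds deliberately cleaner,
  near-binary profiles whose pairwise mean absolute probability gap
  across all 13 items is ≥ 0.5. Recovery claims (ARI ≥ 0.9 under 20%
  MCAR) are statements about separable planted truth, not about the
  overlapping clinical phenotypes, where no clustering method could
  achieve them.
* **Inverse-threshold sampling.** Continuous measures are generated by
  drawing the binary state first, then sampling the score uniformly from
  the matching side of the cut-point at a randomly chosen signal visit —
  so the indicator mapping reproduces planted states exactly on complete
  data (a tested round-trip).
* **Visit counts.** 1 + negative-binomial with cluster-specific means
  (4.0, 4.0, 2.9, 7.1 — the psychosocial phenotype under-engages, the
  high-complexity phenotype over-engages) and dispersion 1.5, chosen to
  reproduce the over-dispersion implied by a median of 2 (IQR 1–5)
  against a mean of 4.
* **Demographics.** Cluster probabilities are tilted on the
  multinomial-logit scale by per-level log-RRRs
  (`default_demographic_effects()`), so planted effects sit on exactly the
  scale the regression reports: gender-diverse → high complexity log(3.41),
  Indigenous → psychosocial log(1.85), male protective for the moderate
  clusters, CALD protective, higher IRSAD and greater remoteness
  protective. Because the tilt *is* a multinomial logit, the full-model
  regression is correctly specified and its coverage is testable.
* **Centres.** Per-centre cluster prevalences follow a Dirichlet around
  the global mixture with concentration 20 (113 centres by default),
  which reproduces spreads of low-complexity prevalence on the order of
  20–65% across centres; `centre_mixing = Inf` gives identical centres.
* **Missingness.** An all-missing stratum (default 14.1% of episodes —
  the share excluded from the analytic sample) plus independent
  episode-by-source MCAR removal, with a MAR option that tilts the odds
  for one covariate level. The two presenting-issue indicators share one
  raw field and so share missingness, as they would on a real form.

What the generator does *not* emulate: within-cluster indicator
correlation beyond the latent class, postcode-level geography, DSM code
lists, free-text fields, longitudinal change across visits in severity,
or informative (MNAR) missingness. Tests passing on this generator
demonstrate that the machinery recovers known structure under its stated
assumptions — not that real cohorts satisfy those assumptions.

## Numerical choices, in one place

* Chained equations: 10 sweeps, ascending-missingness order, ridge 1e-4,
  posterior coefficient draws via the Cholesky root.
* Consensus: R = 100, p = 0.8, k-means++ / Lloyd with `iter.max` 100; one
  re-seed on an empty cluster; never-co-sampled pairs get the global mean.
* PAC window (0.1, 0.9); `no_structure` above 0.4.
* Tetrachoric: quadrature tolerance 1e-10, optimiser tolerance 1e-7,
  clamp ±0.999, 0.5 continuity correction on zero cells.
* Multinomial: gradient tolerance 1e-8, ≤ 200 Newton iterations,
  step-halving, ridge 1e-6 retry on separation.
* Percentages render half-up to one decimal, recomputed from integer
  counts at render time.
* Problem sizes in tests and the acceptance script: recovery at
  n = 4,000 (m = 5, R = 50), k-selection replicates at n = 600 (R = 20),
  estimator calibration at n = 2,000, regression recovery at
  n = 10,000–50,000. These sizes were chosen so each experiment's
  sampling error is comfortably inside the property being asserted.

## A small worked run

```{r example, eval = FALSE}
library(youthcomplexity)

cfg <- pipeline_config(
  output_dir = tempfile("complexity-run-"),
  generator = generator_config(n_episodes = 2000, seed = 42,
                               missing_rate_item = 0.15),
  m = 5, k = 4, consensus_R = 50, seed = 42
)
res <- run_pipeline(cfg)

res$accounting$clusters      # cluster n and % of retained episodes
res$model$table              # RRRs with 95% CIs vs low complexity
res$network$edge_list        # tetrachoric edges for plotting
```

## Known limitations

* The 13 default indicator definitions and the four default profiles are
  reconstructions from qualitative descriptions; both are configurable
  and should be re-derived when the authoritative definitions are
  available.
* The consensus matrix is dense (n × n); beyond n ≈ 20,000 memory becomes
  the binding constraint and the matrix export is off by default above
  n = 2,000.
* PAC-based k selection is advisory by design; on very clean or very
  large data it will not discriminate among adequate k values.
* Imputation assumes MAR given the other indicators (plus optional
  covariates); MNAR mechanisms are out of scope.
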