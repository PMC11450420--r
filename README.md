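# youthcomplexity

Data-driven phenotyping of **clinical complexity** for episodes of care
(EOCs) in youth primary mental health services.

Youth-specific primary care services accept everyone — which means they
treat young people ranging from mild, first-episode distress to severe
multi-domain need. For service planning and resource allocation it helps
to segment the caseload by complexity: not diagnosis alone, but the joint
pattern of clinical severity and psychosocial adversity. This package
implements that segmentation for cohorts shaped like a youth mental health
minimum data set, and ships a synthetic cohort generator so the entire
pipeline is testable without confidential service data. It is written for
biostatisticians and health-services researchers working with
episode-of-care extracts.

## The method

Each episode is reduced to 13 binary complexity indicators
x ∈ {0,1}¹³ (very high distress K10 > 30, low functioning SOFAS ≤ 60, low
quality of life, later illness stage, severe disorder, self-harm
presentation, AOD treatment issue, trauma history, housing issues, NEET,
education/employment issue, government benefits, co-occurring
difficulties), coded 1 if the rule fires at **any** visit. Episodes
missing all 13 are excluded, with conserved accounting
(n_total = n_excluded + n_retained).

The statistical core is **k-means consensus clustering integrated over
multiple imputations**. Missing indicators are imputed by chained
logistic equations into m completed datasets; within each completed
dataset, R subsamples of fraction p are clustered by k-means
(k-means++ initialisation), and the consensus matrix

    M(i, j) = (# runs where i, j co-cluster) / (# runs where i, j co-sampled)

is accumulated over *all* m × R runs. The final partition is the
average-linkage hierarchical cut of 1 − M at k, with labels ordered by
mean indicator burden (cluster 1 = lowest complexity). The number of
clusters is diagnosed by PAC — the proportion of consensus entries inside
(0.1, 0.9) — with the PAC-minimising k returned as an advisory
recommendation.

Around the core:

* pairwise **tetrachoric correlations** between indicators (maximum
  likelihood under the latent bivariate-normal threshold model), pooled
  across imputations on the Fisher-z scale, with a classical MDS layout
  for network plots;
* **multinomial logistic regression** of cluster membership on
  demographics (Newton–Raphson to gradient norm < 1e-8), with
  coefficients pooled by **Rubin's rules**
  (T = Ū + (1 + 1/m)·B) and reported as relative risk ratios with 95%
  CIs against the low-complexity reference;
* a seeded **synthetic MDS generator** with planted latent-class
  structure, demographic effects on the multinomial-logit scale,
  negative-binomial visit counts, per-centre Dirichlet mixing and
  configurable (MCAR/MAR + all-missing stratum) missingness.

## Worked example

```r
library(youthcomplexity)

cfg <- pipeline_config(
  output_dir = file.path(tempdir(), "complexity-run"),
  generator = generator_config(n_episodes = 2000, seed = 42,
                               missing_rate_item = 0.15),
  m = 5, k = 4, consensus_R = 50, seed = 42
)
res <- run_pipeline(cfg)

res$accounting$totals
#> $n_total   [1] 2000
#> $n_excluded [1] 293
#> $n_retained [1] 1707
#> $pct_excluded [1] 14.7

res$accounting$clusters
#>   cluster     n   pct
#> 1       1   620  36.3
#> 2       2   375  22
#> 3       3   381  22.3
#> 4       4   331  19.4
```

293 episodes (14.7%) had no complexity indicator observed and were
excluded; the consensus solution over 5 imputations × 50 subsample runs
splits the remaining 1,707 into a low-complexity plurality (36.3%), two
moderate clusters and a high-complexity cluster (19.4%). The
characteristics table shows the phenotypes behaving as designed — the
indicator burden rises monotonically across clusters, cluster 3
(psychosocial complexity) under-engages with treatment and cluster 4
over-engages:

```r
dplyr::select(res$characteristics, cluster, n, mean_visits, mean_indicator_count)
#>   cluster     n mean_visits mean_indicator_count
#> 1       1   620        4.11                0.623
#> 2       2   375        4.52                2.90
#> 3       3   381        3.12                5.04
#> 4       4   331        6.38                6.08

res$network
#> <tetra_network> 13 items pooled from 5 dataset(s);
#>   strongest edge severe_disorder - trauma_history (rho = 0.75)
```

The pooled regression reports RRRs against the low-complexity reference;
at n = 2,000 the planted gender-diverse effect on high complexity is
recovered with a wide interval (RRR 2.18, 95% CI 1.15–4.14); at the
study-scale n it converges to its planted value of 3.41 (see the
acceptance script below).

Every artefact (cohort CSVs, indicator matrix with missingness mask,
per-imputation datasets, consensus labels and diagnostics, network edge
list and layout, the RRR table, report tables and a manifest with
checksums) is written under `output_dir`; identical configs produce
byte-identical numeric outputs. A thin command-line dispatcher over the
same functions is installed at `inst/cli/complexity.R`
(`Rscript complexity.R run-all --config config.yaml`).

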