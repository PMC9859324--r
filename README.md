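# oxylife

Bayesian spatial analysis of the ecological association between ambient
oxygen concentration and regional life expectancy, with hierarchical
clustering of cause-of-death burden profiles.

Low barometric pressure at high elevation lowers the partial pressure of
oxygen; below roughly 140 mmHg (about 1500 m of elevation) ambient hypoxia
becomes physiologically relevant. `oxylife` implements a complete,
reproducible pipeline for studying how regional life expectancy relates to
ambient oxygen while adjusting for socioeconomic and climatic covariates and
for spatial dependence between neighbouring regions:

1. **Derived covariates** — oxygen partial pressure from barometric pressure
   (`pressure × 0.2093 × 7.5` mmHg from kPa), average years of education,
   health technicians per 1,000 population, station-to-region aggregation.
2. **Descriptive comparison** — regions split at the 140 mmHg cut-off;
   normality-routed summaries (mean ± SD or median (P25–P75)) and
   Mann–Whitney U tests between the groups.
3. **Covariate screening** — Pearson correlation filter (|r| > 0.7, the
   member of a collinear pair with the higher univariate DIC is dropped)
   followed by backward stepwise selection by DIC.
4. **Spatial model gate** — Global Moran's I of the fixed-effects residuals
   under inverse-distance weights, with a permutation test; positive spatial
   autocorrelation (p < 0.05) selects the CAR model, otherwise the IID model.
5. **Bayesian regression** — a from-scratch Gibbs sampler for both models,
   with DIC and adjusted R².
6. **Burden profiles** — Ward-linkage hierarchical clustering of a
   years-of-life-lost (YLL) matrix, ANOVA/Kruskal–Wallis-routed
   between-cluster tests with Bonferroni correction, Newick dendrogram
   export.
7. **Synthetic data generator** — produces region tables, station records
   and YLL matrices with known ground truth, so every stage of the pipeline
   is testable end to end without any external data.

## The model

For region *i* with life expectancy *Y<sub>i</sub>* and covariate row
**x**<sub>i</sub>:

```
Y_i = α + x_i' β + u_i + v_i
v_i ~ N(0, σ_v²)                           (unstructured noise)
u   ~ intrinsic CAR:  p(u | τ_u) ∝ exp( −τ_u/2 · u' (D − W) u )
```

`W` is the symmetric inverse-distance weight matrix between region centroids
(great-circle distances, `w_ij = 1/d_ij`) and `D = diag(rowSums(W))`, so the
conditional mean of `u_i` is the weighted average of its neighbours' effects
and the conditional precision grows with total neighbour weight. The IID
alternative drops `u`. Priors are Gamma on all precisions —
Gamma(1, 0.1) for the intercept and coefficient precisions, Gamma(1, 0.05)
for τ<sub>u</sub> and τ<sub>v</sub> — and every full conditional is
conjugate, so the sampler is a pure Gibbs scheme: a Gaussian block for
(α, β), a Gaussian block for `u` sampled in the eigenbasis of `D − W`
(with the sum-to-zero constraint applied by centering), and Gamma blocks for
the precisions. Convergence is monitored with split-R̂; intervals are
equal-tailed 95% credible intervals.

The Moran gate permutes values by default; when applied to regression
residuals the pipeline re-projects every permuted vector through the
residual-maker matrix (the Freedman–Lane scheme), which keeps the test at
its nominal size when covariates are themselves spatially structured.

## Worked example

Everything below is driven by the built-in generator, so it runs anywhere:

```r
library(oxylife)

cfg   <- synthetic_config(seed = 42)        # 34 regions, 6 below 140 mmHg
paths <- write_synthetic_dataset(cfg, tempdir())

pcfg <- validate_config(list(
  input = list(region_csv = paths$regions, yll_csv = paths$yll),
  model = list(n_chains = 2, n_iter = 4000, n_burnin = 1000),
  seed  = 42
))
report <- run_pipeline(pcfg)
print(report)
#> oxylife pipeline report: 34 regions (34 modeled)
#> Moran's I = 0.013 (p = 0.034) -> CAR model
#> Selected covariates: gdp_per_capita, health_tech_per_1000, oxygen
#> DIC = 46.19, adjusted R2 (full) = 0.998
#> Clusters: 6/16/12
```

The descriptive table's oxygen row shows the complete separation forced by
the cut-off (one U statistic is 0, the other `n_high * n_low`):

```r
report$descriptive[report$descriptive$variable == "oxygen", ]
#>  variable n_high n_low   summary_high     summary_low u_high u_low      p_value
#>    oxygen     28     6 150.72 (±5.54) 121.68 (±12.34)    168     0 0.0001618498
```

Posterior summaries of the chosen CAR fit (true oxygen effect 0.15 per mmHg
in this generator):

```r
head(report$fit$summaries, 6)
#>                  parameter   mean     sd lower_95 upper_95 rhat
#>                      alpha 57.363 2.7998   52.288   63.132 1.01
#>        beta_gdp_per_capita  0.793 0.1857    0.425    1.144 1.02
#>  beta_health_tech_per_1000  0.670 0.1606    0.362    0.998 1.01
#>                beta_oxygen  0.103 0.0166    0.069    0.134 1.01
#>                        u_1  0.303 0.6662   -1.094    1.538 1.01
#>                        u_2  1.122 0.4006    0.250    1.846 1.00

adjusted_r2(report$fit)                          # 0.998 (fixed + spatial)
adjusted_r2(report$fit, include_spatial = FALSE) # 0.729 (fixed effects only)
```

The YLL clustering recovers the planted three-group structure
(`Clusters: 6/16/12`), with the low-oxygen cluster showing elevated YLL for
the hypoxia-linked causes and depressed lung-cancer YLL
(`report$cluster$tests`).

Lower-level entry points (`oxygen_from_pressure()`, `compare_oxygen_groups()`,
`inverse_distance_weights()`, `morans_i()`, `screen_covariates()`,
`fit_car()` / `fit_iid()`, `ward_cluster()`, `compare_clusters()`) are all
exported and documented; `inst/cli/oxylife.R` is a thin command-line wrapper
with `simulate` and `run` subcommands.

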