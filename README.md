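# mpanis

Do coastal marine protected areas carry fewer non-indigenous species?
`mpanis` is an R package for answering that question quantitatively from
site-level survey data. It was built around a 30-site mollusc survey of two
very different Pacific islands — Moorea (French Polynesia) and Vancouver
Island (Canada) — whose scored site table ships with the package, and every
stage of the analysis is exposed as a reusable, tested function that works
on any dataset with the same schema (including synthetic ones the package
can generate).

## What it computes

For sites indexed by scored covariates and a community response, the
package implements:

* **Protection scoring** — a four-tier protection level (5 / 3 / 2 / 1 from
  marine protected area to unprotected), and a length-weighted coastal
  score over a window of coast,

  `PS = Σᵢ PLᵢ · tᵢ · kmᵢ / window`

  with protection level `PL`, duration `t` (decades) and segment length
  `km` (duration optional; without it the score is the length-weighted mean
  level, bounded in [1, 5]).
* **Aquaculture vector scoring** — `AqV = Σᵢ Xᵢ · Farmᵢ` over cultivated
  species within 10 km, with `X` = 1 / 2 / 3 for native / exotic /
  recognized-invader species, then max-anchored rescaling to a 0–5 band.
* **Diversity summaries** — Margalef richness `(S − 1)/ln N`, Simpson's
  index (bias-corrected or plug-in), and NIS proportions per species and
  per individual.
* **Inference** — Pearson screening with Bonferroni and permutation tests;
  correlation-matrix PCA with bootstrap eigenvalue limits; gap-rule outlier
  screening; multiple linear regression with the overall ANOVA F
  `(SSR/k)/(SSE/(n−k−1))`; bivariate normal-family GLMs (identity and log
  links) with likelihood-ratio G tests; Durbin-Watson (permutation null)
  and Breusch-Pagan diagnostics; and regional subset re-analysis.
* **Synthetic data** — a seeded two-region site generator with known
  effect sizes, for parameter-recovery and error-rate validation of the
  whole pipeline.

## Worked example

```r
library(mpanis)

d <- packaged_table1()          # the 30-site two-island reference table
fit <- nis_analysis(d, n_perm = 999, n_boot = 1000, seed = 1)
fit
#> NIS ~ protection analysis: 30 sites screened, 28 modelled
#>   outliers removed (dist_port_km): V-CB, V-LB
#>   screen significant after Bonferroni: status_local, aquaculture
#>   PCA: first four components carry 65.0% of the variance
#>   MLR: R = 0.913, F(12, 15) = 6.298, p = 0.0006
#>   GLM slopes significant at 0.05: status_local, aquaculture
```

Reading the output: two sites whose distance to the nearest port is
discontinuous with the rest (China Beach and Long Beach) are flagged by the
gap rule and excluded from the model stages; on the remaining 28 sites the
12-predictor regression explains 83% of the variance in NIS proportion
(multiple R = 0.913, F(12, 15) = 6.298, p = 0.0006), and both the screen
and the bivariate GLMs single out the same two drivers — local protective
status (negative) and aquaculture (positive).

Individual pieces are available on their own:

```r
pearson_cor(d$aquaculture, d$nis_prop, n_perm = 999, seed = 1)
#> Pearson correlation: r = 0.6728 (df = 28), t = 4.812, p = 4.6e-05
#>   permutation p = 0.0010 (999 shuffles)

sapply(run_subsets(d), function(s) coef(s$mlr)["status_local"])
#> VancouverW+Moorea  VancouverE+Moorea  Vancouver  Moorea
#>            -0.091             -0.076     -0.223  -0.084
```

The protection coefficient is negative in all four regional subsets — the
association is not an artifact of pooling two very different islands.

Synthetic validation with known truth:

```r
sim <- simulate_sites(synthetic_config(), seed = 42)
m <- fit_mlr(sim$dataset, "nis_prop", c("status_local", "aquaculture", "substrate"))
coef(m)[2:3]; unlist(sim$truth[c("beta_ps", "beta_aq")])
```

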