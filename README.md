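# paeval

Evaluate the effectiveness of protected-area (PA) designations —
SSSI (national), SPA (EU, birds) and SAC (EU, habitats) — for a national
avifauna, from the three data streams that large citizen-science schemes
produce: two-period atlas presence on tetrads, annual two-visit counts on
1-km squares, and constant-effort ringing totals. The package is aimed at
quantitative ecologists who want to estimate per-species PA associations
for population **state** (occurrence, abundance), **change** (colonization,
persistence, abundance trend), **demography** (productivity and its trend)
and **community structure**, while controlling for the non-random placement
of PAs in uplands far from human habitation.

Because the real scheme data are access-restricted, `paeval` ships a
first-class synthetic-data generator with known ground-truth effects and a
confounded landscape; every estimator is validated by parameter recovery
against that truth.

## The model at the core

For species *s*, square *i* (year *t* where relevant), the response —
binomial/logit for binary and events–trials metrics, negative-binomial/log
for counts — has linear predictor

    eta = b0 + sum_k gamma_k lc_ik            # 9 land-cover proportions (arable dropped)
             + d1 h_i + d2 h_i^2              # standardized log human density
             + f(easting, northing, elevation)  # tensor-product smooth (ridge penalty)
             + beta_PA * p_i                  # focal PA coverage fraction in [0,1]
             [+ t + t^2 + beta_tr * p_i * t   # year curve and PA-by-year trend
              + u_t                           # year random intercept
              + log(offset_i)]                # 1-or-2-square transect effort

`beta_PA` (and `beta_tr` for trends) is the quantity of interest. Fits are
penalized likelihood via mgcv with Wald SEs; per-species coefficients are
then aggregated by exact sign tests and t-tests, related to species traits
by phylogenetic GLS (error covariance `s2p*C + s2e*I + diag(se^2)`, REML)
or an MCMC engine, cross-checked by a Mahalanobis-matched counterfactual
(treated: coverage > 10%; controls: zero coverage; 1:1, no replacement, no
calipers) with standardized-mean-difference balance diagnostics, and
summarized at the community level (richness, Hill's N2, evenness, CSI,
CTI on detectability-corrected densities).

## Worked example

```r
library(paeval)

run <- run_pipeline(run_config(
  sim_config(n_squares = 1000, n_species = 15, n_years = 10, seed = 42)))

dplyr::select(run$summary, metric, n_pos_sig, n_neg_sig, n_total,
              mean_effect, se, t_p)
#>   metric     n_pos_sig n_neg_sig n_total mean_effect      se     t_p
#> 1 occurrence         5         0      13     0.773   0.146   1.91e-4
#> 2 colonizat…         4         1      13     0.776   0.534   1.72e-1
#> 3 persisten…         1         0      13     0.362   0.420   4.05e-1
#> 4 abundance          7         3      15     0.116   0.168   4.99e-1
#> 5 abundance…         5         2      15     0.00730 0.00601 2.45e-1
#> 6 productiv…         3         3      12     0.0169  0.169   9.23e-1
#> 7 productiv…         1         1      12    -0.00524 0.00689 4.63e-1
```

Reading this: 5 of 13 usable species are significantly *more* likely to
occur where PA coverage is higher (none significantly less), and the mean
occurrence association across species is 0.773 ± 0.146 on the logit scale
per unit coverage — a strongly positive state association, echoed more
weakly in colonization and persistence, while the trend metrics sit near
zero, as their generating means do. The matched counterfactual for the same
run pairs 300 treated squares with zero-coverage controls and reduces the
elevation imbalance (SMD 1.59 → 1.09 here; scarce controls keep residual
imbalance, which is why the matched re-analysis keeps covariate
adjustment):

```r
glance(run$matched$ALL)
autoplot(run$matched$ALL)        # love plot of SMDs before/after
```

The trait stage regresses per-species coefficients on traits under
phylogenetic correlation; in this run the colonization effect declines with
log population size (−1.32, 95% CI −2.16 to −0.48): rarer species benefit
most, which is the generator's built-in linkage being recovered.

```r
dplyr::filter(run$trait_models, model_id == "ecological", term == "log_pop")
autoplot(run$summary)            # headline bars + means figure
```

All stage outputs (CSV tables, newick tree, markdown report) are written
to `out_dir` when set, and reruns with the same seed are byte-identical.

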