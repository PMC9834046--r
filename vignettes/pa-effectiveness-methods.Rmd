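---
title: "Methods: evaluating protected-area effectiveness from citizen-science monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating protected-area effectiveness from citizen-science monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paeval)
```

## The scientific problem

Statutory protected areas (PAs) — nationally designated SSSIs and the
European SPA (birds) and SAC (habitats) networks — are a central policy
instrument against biodiversity loss, but their placement is anything but
random: in the UK they sit disproportionately in upland areas far from human
habitation. Any association between PA coverage and bird populations is
therefore confounded with elevation, land cover and human pressure.
`paeval` implements a full analysis chain for separating PA associations
from that confounding, using the three data streams that national
citizen-science schemes provide:

* **two-period atlas presence** on 2-km tetrads (occurrence, colonization,
  persistence);
* **annual two-visit counts** on 1-km squares (abundance and its trend),
  with the visit maximum as the abundance measure;
* **constant-effort ringing totals** (productivity: the juvenile share of
  captures, and its trend).

Because the real scheme data are access-restricted, the package is built
around a synthetic-data generator with known ground truth. The generator is
a first-class, tested module: every estimator in the package is validated by
parameter recovery against the truth it writes.

## The estimation model

For each species and metric, the response in square $i$ (and year $t$ where
relevant) is modelled on its natural scale — binomial/logit for the binary
and events–trials metrics, negative binomial/log for counts — with linear
predictor

$$
\eta_{it} = \beta_0
  + \underbrace{\textstyle\sum_k \gamma_k \, \mathrm{lc}_{ik}}_{\text{9 land-cover proportions}}
  + \delta_1 h_i + \delta_2 h_i^2
  + f(e_i, n_i, z_i)
  + \beta_{\mathrm{PA}} \, p_i
  \;[+\; \tau_1 t + \tau_2 t^2 + \beta_{\mathrm{tr}}\, p_i t + u_t
  \;+\; \log o_i],
$$

where $\mathrm{lc}_{ik}$ are land-cover proportions (arable omitted: the ten
proportions sum to one, so one class must be dropped for identifiability),
$h_i$ is standardized log human density, $f$ is a low-rank tensor-product
smooth of easting, northing and elevation, $p_i \in [0,1]$ is the focal
PA coverage fraction for one designation, $u_t$ is a year random intercept
(a weather proxy, shared shrinkage via ridge-penalized dummies), and
$\log o_i$ is the effort offset (1 or 2 transect squares). The quantity of
interest is always $\beta_{\mathrm{PA}}$ — and for the trend metrics the
interaction $\beta_{\mathrm{tr}}$ with linear year. Because $p_i$ enters
untransformed on $[0,1]$, coefficients read as full-coverage contrasts.

Fitting is penalized likelihood via `mgcv` (`gam`, switching to
`bam(discrete = TRUE)` above 5,000 rows for speed): the smooth and
year-factor blocks carry ridge penalties chosen by REML/fREML, all other
terms are unpenalized, and the reported SE is the Wald standard error from
the penalized information matrix. On designs with no penalized block the fit
reduces exactly to `glm` maximum likelihood; the test suite asserts this
equivalence against `glm`/`MASS::glm.nb` oracles. The negative-binomial size
is estimated by the family's outer optimization; `variance = mu + mu^2/size`.

Exclusion rules mirror standard practice for mass-produced per-species fits:
`n_lt_k` (fewer units than coefficients), `fit_failure` (separation,
$|\beta| > 15$ on the logit scale, or optimizer failure), `overdispersed`
(Pearson $\chi^2/\mathrm{df} > 2$ on binary/binomial fits, or an NB size
below $10^{-3}$), a parametric-bootstrap zero-inflation check (observed
zeros above the 99th percentile of 200 simulated replicates), and a
cross-species outlier rule (beta further than 5 IQR from the metric's
median). The 5-IQR multiplier is our choice; "extreme outlier" has no
standard quantitative definition, and in practice the rule only removes
estimates that are also flagged on other grounds.

Two-sided Wald $p < 0.05$ defines a "significant association" throughout;
no source we follow states a different $\alpha$.

## The synthetic-data generator

The generator's defaults are the package's reference study conditions and
are not tuning knobs.

**Landscape.** Covariates are smooth Gaussian-kernel random fields on a
planar 1-km grid (default range 6 km; the spatial correlation structure of
real covariates is unknown, so the field parameters are explicit free
choices). Elevation, log human density and ten softmax land-cover
proportions (anchored at the UK aggregate-class shares) are mutually
dependent; later fields are residualized on earlier ones so the confounding
loadings are exact in-sample rather than left to chance. PA coverage is a
thresholded logistic transform of a latent field whose loadings give
`cor(pa, elevation) ≈ +confounding_strength` and
`cor(pa, log human density) ≈ −confounding_strength` (default 0.6), with
30% of squares forced to exactly zero coverage so a matched design has true
controls. The PA-specific placement component uses half the covariate field
range: site selection varies locally, and this finer scale is also what
keeps coverage identifiable after spatial adjustment — with a coverage
surface as smooth as the landscape fields, the tensor smooth would absorb
nearly all PA variation and per-species SEs would roughly double.
Designation-specific fractions are `pa_all` times a logistic share field,
which enforces the nesting invariant exactly.

**Species.** An ultrametric coalescent tree; traits evolve as Brownian
motion plus independent noise (mass, population sizes, population change,
SSI, STI, habitat class, conservation listings, detectability). True PA
slopes per metric are `mean + linkage_pop * std log population size
[+ linkage_change * std log population change] + noise`. Defaults put the
cross-species mean slopes at the values reported for the UK avifauna
(occurrence 0.49, colonization 0.27, persistence 0.23, abundance 0.25,
abundance trend 0) with SDs (0.9, 0.8, 0.8, 0.6, 0.03) chosen so that the
mean's standard error at realistic species counts matches the reported
±0.07/±0.08/±0.09/±0.05 values; rarer species get larger true effects
(`linkage_pop = −0.3`) and declining species more positive trend effects
(`linkage_change = −0.015`), the directions reported for the real avifauna.
Productivity defaults are mean −0.2 (the reported overall association is
negative) with trend mean 0 (no overall value is reported).

**Outcome streams.** Species-level covariate effects are built only from
terms the fitted models can absorb — linear land cover, nonlinear elevation,
quadratic log human density and a mesoscale shared spatial field (0.4 of the
domain extent) — because the generator's role is to emulate the statistical
structure the analysis assumes; what passing recovery tests therefore show
is that the estimator works when its covariate model is adequate, not that
it is robust to unmodelled fine-scale habitat structure in real data. The
mean species elevation effect is negative (−0.5 per SD): most species are
lowland, which is exactly what makes upland-biased PA placement a genuine
confounder. Counts are negative binomial (size = `overdispersion`, default
1.5) with a shared year random intercept (SD 0.15); the recorded visit
maximum equals the drawn count and the second visit is a binomial thinning.
Ringing totals are Poisson with binomial juvenile splits, and early/late
visit counts are drawn so the completeness filter bites occasionally.

One subtlety is calibrated rather than assumed: the *occurrence* outcome is
presence in **either** atlas period, so its logit-PA slope mixes the
period-1 and colonization models and would otherwise be attenuated by about
30%. The generator solves, per species, for the period-1 slope that makes
the either-period outcome carry exactly the species' true occurrence slope
at its realized baseline rates. Colonization and persistence slopes enter
their conditional models directly.

**Evidence codes.** Given true presence, codes are multinomial
(possible 0.2 / probable 0.3 / confirmed 0.5); truly absent surveyed tetrads
record a spurious "possible" at rate 0.02. This exercises the 10-km
breeding-evidence filter non-trivially: lone "possible" records with no
probable/confirmed sighting of the species in their 10-km parent square are
demoted to absence, per period (whether the filter pools periods is not
documented for the source analysis; per-period is our assumption and is
flagged as such).

## Occupancy classification

Transitions use only tetrads surveyed in both periods: colonization is
defined where the species was absent in period 1, persistence (the
complement of extinction) where it was present; a tetrad never has both
defined, and the two defined sets partition the surveyed-both tetrads.
Occurrence uses all surveyed tetrads, including single-period ones.
Species enter the atlas analysis only if native and occupying at least 20
tetrads. The abundance screen — an average of at least 100 recorded squares
per year in the real scheme — is applied proportionally (≥5% of squares per
year) so it scales to synthetic landscapes of any size.

## Matched counterfactual

Squares with coverage strictly above 10% are treated; squares with exactly
zero coverage are controls; the thin sliver in between is excluded. Matching
is greedy 1:1 nearest-neighbour on Mahalanobis distance (pooled
treated+control covariance; ridge-stabilized only if singular, which also
preserves the metric's affine invariance), without replacement and without
calipers, so treated units are simply left unmatched when controls run out
(partial matching). Processing order is a genuine design choice: with ample
controls we process hardest-first (largest nearest-distance), which protects
hard-to-match units; with scarce controls — the usual regime here, since
treated squares outnumber zero-coverage squares — hardest-first would retain
precisely the least-comparable treated units and *worsen* balance, so the
order flips to easiest-first and the matched sample becomes the overlap
population. Balance is reported as standardized mean differences
(difference over the pooled full-sample SD) before and after matching, with
|SMD| ≥ 0.25 flagged.

The matched re-analysis replaces the coverage fraction with a binary
treated/control indicator while keeping covariate adjustment, because
residual imbalance remains. Two adjustment variants exist: the default
reuses the full model structure including the tensor smooth; the
`spatial_linear` design term substitutes a linear/quadratic elevation plus
linear easting/northing block. The latter matters because on a matched
subsample a spatially clustered binary treatment is close to collinear with
a free-form spatial smooth (the smooth's unpenalized null space contains
exactly the linear trend surfaces the treatment indicator resembles), and
the smooth then absorbs part of the treatment contrast. The de-biasing
property checks use `spatial_linear` for this reason. Note also what the
matched estimand is: under partial matching it is the treatment effect in
the overlap population, and with heterogeneous coverage among treated
squares the binary contrast targets a coverage-weighted average effect, not
the full-coverage slope.

## Cross-species summaries

Per metric and designation: counts of species with significantly positive
versus negative PA coefficients, compared with an exact two-sided binomial
test against 0.5 (the continuity-uncorrected chi-square statistic is
reported alongside, since that is how such counts are often summarized, but
the exact test is authoritative); the across-species mean effect with a
one-sample two-sided t-test (df = n−1); and paired t-tests of SPA versus
SAC effects within species. Species are unweighted in these t-tests
(weights belong to the traits analysis only — the source methods are
explicit about weighting only there); excluded species never enter counts
or means. Degenerate cases are reported, not hidden: no significant species
gives a missing sign-test p, a zero-SE sample is flagged.

## Traits analysis under phylogenetic correlation

The species-level coefficients $\hat\beta_s$ with sampling variances
$v_s = \mathrm{SE}_s^2$ are regressed on traits with error covariance

$$ \Sigma = \sigma_p^2 \, C + \sigma_e^2 I + \mathrm{diag}(v_s), $$

where $C$ is the Brownian correlation matrix of the phylogeny (shared
root-to-MRCA path length over tree depth; star tree ⇒ identity; non-ultrametric
trees are normalized per-tip with a warning). The two variance components
are estimated by REML on a 2-parameter log-scale profile; with a star tree
and equal weights the estimator collapses to OLS exactly, which is tested
to 1e-8, and the weighted fit is cross-checked against
`metafor::rma.mv` as an independent implementation of the same model.

Four model sets run per metric and designation: three conservation-listing
models (BoCC, Schedule 1, Annex 1 — each with log population size, because
commoner species have more precise estimates) and an ecological model (log
mass, log population size, log population change, SSI, STI, habitat class)
with inverse-variance weights. Whether the listing models should also be
weighted is ambiguous in the source description; they are unweighted by
default with a `weight_listing` switch. Metrics with fewer than 10
usable species are skipped, as are listing models without contrast.
Productivity metrics are excluded from the traits analysis (too few species
in the ringing scheme).

A single-chain Gibbs sampler provides the MCMC engine for fidelity with the
original workflow: the univariate inverse-Wishart priors reduce to inverse
gammas (residual V = 1, ν = 0.002; phylogenetic V = 1, ν = 1), flat priors
on coefficients, 50,000 iterations with 5,000 burn-in and thinning 25, with
the known $v_s$ as a fixed measurement-error layer. Sampling the
phylogenetic effect uses the eigenbasis of $C$, where its full conditional
precision is diagonal, so the chain is fast and exact. Effective sample
sizes are computed from the initial-positive-sequence autocorrelation sum
and flagged below 200. The deterministic GLS engine is the default —
posterior means agree with GLS within Monte-Carlo error, and deterministic
estimates make recovery properties testable — with MCMC available via
`method = "mcmc"`.

## Community structure

Counts are converted to densities by dividing by the species' detection
probability (taken as an input; estimating detectability is out of scope).
Per square-year: richness, Hill's $N_2 = 1/\sum p_i^2$ (inverse Simpson),
evenness $N_2/\text{richness}$, and the density-weighted means of SSI (CSI)
and STI (CTI). SSI itself is the coefficient of variation of a species'
density across habitat classes using the population (divide-by-n) SD —
the convention is not documented for the source index, so the sample-SD
variant is available by flag (it changes the 1-of-12 specialist from
$\sqrt{11}$ to $\sqrt{12}$). All five metrics are scale-invariant in the
densities except richness, and $1 \le N_2 \le$ richness with equality only
for perfectly even communities; these invariants are property-tested.
Species densities are pooled over years when computing SSI from data.

Each metric is regressed on the same covariate structure plus PA and
PA-by-year: negative binomial/log for richness, Gaussian/identity for the
continuous metrics. Metric trends are read from the PA-by-year interaction
rather than per-square slope regressions, mirroring the model form used
for species trends.

## Pipeline, reproducibility and problem sizes

`run_pipeline()` executes simulate → classify → fit → summarize → match →
traits → community with per-stage child seeds derived from one master seed
by fixed offsets, so outputs are byte-identical across reruns and disabling
a downstream stage cannot change upstream results (both are tested by
hashing). All artifacts are plain text (CSV, newick, markdown report); the
report carries the seed and a configuration hash (output paths excluded
from the hash, since where files land must not change what they contain).

Problem sizes used by the shipped checks are chosen to make the properties
sharp at desk scale: parameter recovery at 2,000 squares × 20 species × 15
years with CI coverage over 100 single-species replicates; null calibration
over 550 species fits (500-square landscapes) and 200 replicates of the
cross-species t-test (300-square landscapes, coarser smooth); matching
properties over 50 seeds; the demo pipeline at 150 squares × 6 species × 6
years. The binarized-coverage variant used in the de-biasing check fixes
the treated contrast at a single known effect size, removing the
coverage-weighting ambiguity described above.

## Known limitations

* The generator emulates the structure the models assume; it does not
  emulate observer heterogeneity, detection error within atlas periods,
  fine-scale habitat selection, or spatially autocorrelated residuals.
  Recovery results say nothing about those failure modes.
* Designation dates are ignored (all PAs treated as designated throughout),
  as in the source design.
* The matched analysis answers a different question (binary contrast in the
  overlap population) than the regression analysis (full-coverage slope);
  the package reports both and does not attempt to reconcile the estimands.
* Real-data ingestion (shapefiles, rasters, scheme databases) is out of
  scope; the readers accept plain delimited text in the documented column
  layout.

```{r example, eval = FALSE}
run <- run_pipeline(run_config(
  sim_config(n_squares = 500, n_species = 15, n_years = 10, seed = 1),
  designations = "ALL"))
run$summary
autoplot(run$summary)
```
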