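---
title: "Methods: long-term bird population trends from heterogeneous point counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: long-term bird population trends from heterogeneous point counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avitrend)
```

## The problem

Long-running breeding-bird datasets are often stitched together from several
projects with different spatial designs. Pooling them buys a long time series
at the price of three statistical hazards:

* **environmental bias** — the covariate distribution of the surveyed sites
  drifts across project epochs, so a naive year effect confounds habitat
  shifts in the *sample* with population change;
* **overdispersion** — count variance exceeding the Poisson mean;
* **zero inflation** — excess zeros beyond what the count distribution
  predicts, e.g. from sites structurally outside a species' range.

`avitrend` implements a pipeline that addresses all three: per-species count
regressions with environmental-bias covariates under four candidate error
structures, AIC selection among them, parametric-bootstrap yearly population
indices at standardized covariates, confidence-interval-weighted trend tests,
and functional-group models linking trends to species traits.

## From field records to modelled counts

Counts of detected individuals are converted to breeding pairs with integer
species conversion factors, `pairs = ceiling(individuals / CF)`: gregarious
species are detected as family groups, and e.g. a CF of 11 maps 1–11
individuals to one pair and 12–22 to two. Species are retained when their
share of point counts with presence strictly exceeds 2% (presence/absence,
so the filter is CF-invariant). Within-year site spacing below 500 m is
reported as a warning, not an error: real pooled tables are imperfect and the
analysis should still run.

## The four candidate count models

For each species the pairs at all site-years are modelled with log link under
Poisson (P), NB2 negative binomial (NB, variance $\mu + \mu^2/k$),
zero-inflated Poisson (ZIP) and zero-inflated negative binomial (ZINB)
errors. The linear predictor of the count mean contains

* survey year as a treatment-coded factor (first surveyed year as reference —
  unsampled years simply have no level and no index);
* spline smooths of the 17 land-cover fractions (250 m buffer) and of
  elevation and slope;
* aspect sine and cosine as linear terms;
* a tensor product of two df-3 marginal bases in the planar coordinates, as
  a spatial trend.

For the ZI families, the structural-zero probability gets a logit linear
predictor with smooths of elevation and of urban and forest cover in a
2500 m buffer — covariates that describe whether a site is in the species'
range at all rather than how many pairs it holds.

**Fixed-df bases instead of penalized smoothers.** Every smooth is an
unpenalized cubic B-spline basis with at most 4 degrees of freedom and
interior knots at covariate quantiles. With fixed bases the models are plain
maximum likelihood: the AIC parameter count, the likelihood-ratio geometry
and the coefficient covariance (inverse observed information) are all exact,
with no smoothing-parameter selection entangled in the comparison of the four
families. The df-4 cap keeps each effect at most as flexible as a cubic with
one knot; a df-4 basis reproduces any global cubic exactly, which the tests
exploit as an oracle. Knot placement is a documented package choice — the
basis type behind the original analyses is not recoverable from the published
material.

**Fitting.** P is fitted by IRLS and NB by `MASS::glm.nb`. The ZI families
are maximized directly with analytic gradients (BFGS, relative tolerance
1e-10, max 500 iterations), initialized from the corresponding non-inflated
fit plus a zero-part intercept matched to the empirical excess-zero fraction.
Log-likelihoods include all normalizing constants so AIC is comparable across
families; ties go to the simpler family in the order P < NB < ZIP < ZINB.
Non-converged fits (including a non-invertible information matrix) are
flagged and excluded from selection. Aliased design columns are dropped by
pivoted QR and recorded, so bootstrap-time prediction uses exactly the
reduced design.

**Explained deviance.** For P/NB this is the usual $1 - D/D_0$ against an
intercept-only null. The mixture families have no standard decomposition;
the package reports complete-data analogues: each zero gets its posterior
structural-zero probability under the fitted mixture, the count component is
the posterior-weighted family deviance against a weighted intercept-only
null, and the zero component is the binomial deviance of the fitted zero
probabilities against the posterior indicators relative to an intercept-only
zero part. These reduce to the standard quantities when the zero part
vanishes.

## Yearly indices

The population index of year $t$ is the model's unconditional expected pairs
per site, $(1-\pi)\mu$, at a standardized covariate profile:

* each land-cover class is fitted as a smooth of year over the snapshot-map
  years (df = min(4, snapshots − 1)) and evaluated at the survey years,
  clamped to [0, 1]; extrapolation beyond 5 years of the snapshot range is
  refused;
* topography and the 2500 m covariates are fixed at their mean over the
  sites, and the coordinates at the area centroid;
* for species whose minimum convex hull of presence points covers less than
  80% of the region, means, centroid and snapshot averages are taken within
  the hull, so a montane species is not standardized to lowland covariates.

Uncertainty comes from a parametric bootstrap: 1000 draws of the coefficient
vector from the asymptotic multivariate normal at the estimates. The yearly
index is summarized by the median of the draws and a 95% percentile interval
(type-7 quantiles). Re-simulating response data instead would require
refitting the model per draw; resampling coefficients is the variant
compatible with 1000 replicates per species at this model scale. The NB/ZINB
dispersion never enters the mean, so it is held at its estimate. A mildly
indefinite covariance (numerical Hessian noise) is repaired to the nearest
positive semidefinite matrix with a warning; a relative repair distance above
5% aborts instead of silently sampling from a different model. One open
reading was whether prediction should average over a site grid rather than a
single standardized profile; the single-profile reading is implemented, and
the synthetic truth is defined at the same profile so recovery is measured
against the estimand the pipeline actually targets.

## Trend assessment

The long-term trend is a weighted least squares regression of the yearly
median index on calendar year, with weights $1/\mathrm{CI\ width}$. A year
with zero bootstrap width would otherwise dominate with infinite weight; its
weight is capped at ten times the largest finite weight (all-zero widths fall
back to OLS with a warning). Significance uses the two-sided $t$ test with
$n-2$ df at $\alpha = 0.05$, boundary inclusive (non-significance is
$p > 0.05$). The overall change
$T\% = (I_{\mathrm{last}} - I_{\mathrm{first}})/I_{\mathrm{first}} \times 100$
is computed from the WLS *fitted* endpoint values — raw endpoint medians
would contradict the regression the classification rests on for noisy series
— with each species using its own first surveyed year. Adjusted $R^2$ is
floored at zero. A significant decline below −50% is flagged as steep.
Yearly indices are serially dependent, which this regression ignores; for a
long-term linear signal that mainly affects the nominal coverage of the
trend test, a limitation shared with the approach the package implements.

The packaged fixture table of published per-species results is transcribed
verbatim, including typographic oddities (a slope printed with the wrong
sign relative to its t statistic, one bolded T% whose printed p-value is
non-significant). Summaries therefore trust the p-value and T% columns only,
and `"<0.001"` entries are parsed as their upper bound — any value at or
below it classifies identically at $\alpha = 0.05$.

## Traits and functional groups

Eight categorical traits are derived per species: migration strategy;
dispersal ratio (wing length / cube root of body mass); annual fecundity
(clutch size × broods per year, with brood parasites forced to one brood);
incubation period; diet by the 70% dominance rule (scavenging counts toward
vertebrates); nest type reclassified to elevated/ground/hole nesters;
landscape type by the strict 50% median-cover rule (urban or wetland
dominance has no named class and falls to "several"); and the overall
specialization index. Numeric traits are categorized by type-7 quartiles
with inclusive boundaries (≤ Q1 low, ≥ Q3 high).

The single-axis specialization index is computed as the coefficient of
variation (population SD over mean) of the species' binary usage vector
across an axis's resource categories — 0 for a complete generalist,
$\sqrt{K-1}$ for a single-category user — and the overall SI is the mean of
the five axis indices. The source material names the index family but not
its arithmetic on presence/absence data; the CV form is the natural
restriction and is isolated in one function should a different convention be
preferred.

Trait association is screened pairwise with Cramér's V
($\sqrt{\chi^2/(n\,(\min(r,c)-1))}$, uncorrected $\chi^2$), with Fisher's
exact test replacing the $\chi^2$ test when any expected cell is below 5.
Traits in a significant association with V ≥ 0.5 are flagged; the default
drop rule (higher mean V across all pairs) is a heuristic and a configured
drop list takes precedence.

For each trait, species index series are normalized (all quantiles divided
by the species' own first-year median, so every series starts at 1 and
weights remain comparable) and pooled into one weighted fixed-effects model,
`index ~ group + year + year:group`, weighted by the reciprocal normalized
CI width. Group slopes (year coefficient plus interaction) and their
pairwise equality are tested with finite-sample F statistics via
`car::linearHypothesis`; single-constraint F equals the matching $t^2$
exactly. No species-level random effects are used — fidelity to the pooled
fixed-effects formulation was preferred over model sophistication, and the
repeated-measures dependence within species is a known limitation. Whether
group models should use only years observed for every species was open; all
available species-years enter, which the weights handle naturally.

## The synthetic-data generator

The generator emulates the structure the pipeline assumes, with recorded
ground truth:

* sites placed with 500 m minimum within-year spacing (with a
  packing-capacity feasibility check) in a planar region;
* spatially autocorrelated covariates from low-rank Gaussian random fields
  (sums of Gaussian bumps with random weights; correlation length
  configurable, default 5 km); the 17 land-cover fractions come from a
  logistic-normal construction so they lie in [0, 1] and sum below 1 —
  percentage-cover semantics without inventing rasters;
* design bias as per-epoch acceptance weights on a named covariate, so the
  surveyed covariate distribution drifts across epochs like a change of
  project;
* counts from any of the four families with log-linear year trends, and
  structural zeros driven by the standardized 2500 m covariates;
* gregarious species emit individuals as `(pairs − 1) · CF + u`, `u` uniform
  on 1..CF, so ceiling division recovers pairs exactly — the distribution of
  individuals per detected group is not documented anywhere, and this
  bounded-noise choice is a stand-in that makes the conversion exactly
  invertible;
* trait tables carried on the species specifications, with group structure
  encoded as shared trend components.

Default scales are modest (a 20–40 km square, 50–200 sites per year, 8–12
species) — large enough for the asymptotics the pipeline relies on, small
enough that the whole validation suite runs on a laptop; the default survey
calendar mirrors a 1992–2019 program with four missing years. What the
generator does **not** emulate: detection probability (single-visit counts
are taken as relative abundance, as in the source design), within-season
revisits, temporal autocorrelation of site environments, and real GIS
land-cover maps. Passing tests therefore validate the estimators under the
model's own assumptions, not robustness to detection artifacts.

## Validation summary

The test suite checks, among others: exact reproduction of the published
summary counts from the packaged fixture; WLS estimates against an
independent centered normal-equations oracle at 1e-10; the $F = t^2$
identity and a contrast-formula oracle for group hypotheses; closed-form
specialization indices; the ZIP likelihood collapsing to Poisson when the
zero mass is forced to zero; AIC identity from stored log-likelihood and
parameter count; type-I error of the trend test within [0.03, 0.07] under a
flat-truth null (1000 series); AIC selecting a well-separated ZINB truth in
at least 80% of 100 replicates at n = 5000; bootstrap interval coverage of
the true yearly index within [0.90, 0.98] over 200 replicate surveys
(B = 200 at test scale); group-slope recovery within 3 SE; and
trend-sign recovery for at least 90% of species with |log-slope| ≥ 0.02 in
an unbiased full-pipeline run (12 species, 200 sites/year, B = 1000).
`scripts/acceptance.R` recomputes the headline quantities from scratch.

```{r example, eval = FALSE}
reg <- region_spec(0, 20000, 0, 20000, survey_years = seq(1992, 2010, 2),
                   snapshot_years = c(1992, 2000, 2010))
sites <- generate_sites(reg, n_per_year = 120, seed = 11)
sim <- simulate_counts(sites, default_species_specs(6), seed = 12)
res <- assess_trends(sim$counts[c("site_id", "year", "species_id", "individuals")],
                     sites, snapshots = generate_snapshots(sites, reg),
                     smooth_terms = c("broadleaved", "arable", "elevation"),
                     B = 1000, seed = 5)
res$trends
summarize_results(res$trends)
```
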