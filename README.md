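# avitrend

Long-term breeding-bird population trends from heterogeneous point-count
surveys.

## What it does, and for whom

Regional bird-monitoring datasets are often pooled from several projects
with different sampling designs. `avitrend` is for ecologists who want
defensible long-term trends from such data, where three hazards bite at
once: **environmental bias** (the covariate distribution of surveyed sites
drifts across project epochs), **overdispersion** and **zero inflation** in
the counts.

The pipeline, per species:

1. **Preprocess** — detected individuals become breeding pairs via integer
   conversion factors, `pairs = ceiling(individuals / CF)` (a Common
   Starling flock of 22 at CF = 11 is 2 pairs); species present at more than
   2% of point counts are retained.
2. **Count models** — four candidate regressions of pairs on fixed-df
   spline smooths of land-cover, topography and a spatial tensor trend, plus
   a survey-year factor: Poisson, NB2 (variance μ + μ²/k), zero-inflated
   Poisson and zero-inflated negative binomial, the last two with a logit
   structural-zero model on broader-scale covariates. Maximum likelihood
   throughout; the best family is picked by AIC.
3. **Yearly indices** — the expected pairs per site, (1 − π)·μ, at
   standardized covariates (land cover smoothed over snapshot-map years,
   topography at its mean, coordinates at the centroid, all restricted to
   the species' minimum convex hull when it covers < 80% of the region),
   with a 95% percentile interval from a 1000-draw parametric bootstrap of
   the coefficients.
4. **Trend test** — weighted least squares of the median index on year,
   weights = 1 / CI width; the change `T% = (I_last − I_first) / I_first ×
   100` comes from the fitted endpoints; significant declines below −50%
   are flagged as steep.
5. **Functional groups** — series normalized to a first-year median of 1
   are pooled into weighted `index ~ group + year + year:group` models per
   trait (migration, dispersal ratio, fecundity, incubation, diet, nest
   type, landscape type, specialization), with finite-sample F tests of
   each group slope and of pairwise slope equality.

A synthetic-survey generator with recorded ground truth (spatially
autocorrelated covariates, configurable design bias, all four count
families, conversion-factor noise, trait tables) supports end-to-end
validation; a packaged transcription of the published 76-species results
table supports exact summary checks.

## Worked example

```r
library(avitrend)

reg   <- region_spec(0, 20000, 0, 20000, survey_years = seq(1992, 2010, 2),
                     snapshot_years = c(1992, 2000, 2010))
sites <- generate_sites(reg, n_per_year = 120, seed = 11)
sim   <- simulate_counts(sites, default_species_specs(6), seed = 12)
res   <- assess_trends(sim$counts[c("site_id", "year", "species_id", "individuals")],
                       sites, snapshots = generate_snapshots(sites, reg),
                       smooth_terms = c("broadleaved", "arable", "elevation"),
                       B = 1000, seed = 5)
res$trends[c("species_id", "wls_model", "slope", "p_value", "t_pct", "trend_class")]
```

```
  species_id  wls_model    slope  p_value  t_pct          trend_class
1       sp01    C-P-GAM -0.04055 1.17e-06 -53.97  significant decline
2       sp02   C-NB-GAM -0.01685 4.75e-03 -33.76  significant decline
3       sp03  C-ZIP-GAM -0.00612 4.47e-01  -7.55      non-significant
4       sp04 C-ZINB-GAM  0.03891 2.13e-04  70.67 significant increase
5       sp05    C-P-GAM  0.10674 4.78e-07 131.73 significant increase
6       sp06   C-NB-GAM -0.04832 3.71e-06 -54.92  significant decline
```

The six species were generated with log-linear trends −0.04, −0.02, 0,
0.02, 0.04 and −0.04 per year from the P, NB, ZIP, ZINB, P and NB families
in turn: the selected model matches the generating family for every
species, every nonzero trend is recovered with the right sign and
significance, the flat species is correctly non-significant, and the two
−0.04 species (true change exp(−0.04 · 18) − 1 ≈ −51% over the 18-year
span) are flagged as steep declines.
`summarize_results(res$trends)` then tabulates families and trend classes
the same way the package summarizes the published results fixture
(`table1_fixture()`).

## Further reading

The methods vignette (`vignettes/avitrend-methods.Rmd`) documents the model
assumptions, the fixed-df basis choice, the bootstrap variant, numerical
tolerances and tie-breaks, what the synthetic generator does and does not
emulate, and known limitations.
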