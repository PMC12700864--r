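# socioclock

Do social bonds slow biological ageing? In long-lived social mammals —
the motivating system is the Shark Bay population of Indo-Pacific
bottlenose dolphins, where males maintain decades-long alliances — this
question can be asked quantitatively by combining three ingredients that
this package implements end to end:

1. **Social network metrics from field surveys.** Dyadic association is
   measured by the Simple Ratio Index, `SRI = x / (x + y_a + y_b)`, the
   proportion of surveys involving either animal in which both were
   present. A male's *cumulative social bond strength* is his node
   strength `S_i = Σ_j SRI_ij`, normalized by the maximum node strength
   over all males seen ≥ 15 times in the same time window, so it lies in
   [0, 1]. The package also computes the coefficient of variation of a
   male's SRI values and his mean male group size, applying the field
   filters (drop foraging surveys, drop resightings of the same group
   within 2 h, accumulate from a male's first sighting through 31 December
   of the year he was biopsied — once per sampling point for repeatedly
   sampled males).
2. **A species-specific epigenetic clock.** Elastic-net regression
   (`α = 0.5`) of chronological age on CpG methylation beta values,
   restricted to genome-mapped probes, evaluated by
   leave-one-individual-out cross-validation (LOIOCV) so that repeated
   samples of one animal never straddle the train/test split. Reported
   metrics are the median absolute error (years) and Pearson *r*; *age
   acceleration* (AgeAccel) is the residual of regressing epigenetic age
   on chronological age.
3. **Crossed-random-effect inference.** A linear mixed model
   `epigenetic age ~ bond strength + group size + chronological age +
   (1 | individual) + (1 | year)` fitted by direct ML/REML (profiled
   likelihood over log variance ratios, dense covariance), with two-step
   AIC model selection (random structure, then a nested fixed-effect
   sequence), standardized coefficients, Satterthwaite p-values, partial
   residuals, robustness subsets, collinearity diagnostics, and a
   quasi-Bayesian mediation analysis (ACME / ADE, total = ACME + ADE).

A synthetic-cohort generator with known ground truth (alliance-clustered
surveys via a stochastic block model, linear-with-clipping probe
trajectories, a biological-age offset that depends negatively on bond
strength and positively on group size with crossed individual/year random
intercepts) makes every stage testable without any external data.

## Worked example

```r
library(socioclock)

cohort <- simulate_cohort(n_individuals = 30, n_samples = 40, n_repeat = 8,
                          n_probes = 1000, n_clock_probes = 200,
                          surveys_per_year = 50, study_span_years = 30,
                          rules = filter_rules(min_sightings = 10), seed = 42)

metrics <- compute_social_metrics(cohort$samples, cohort$surveys,
                                  cohort$individuals,
                                  filter_rules(min_sightings = 10))

X <- mask_probes(cohort$methylation)
clock <- loiocv_predict(X, cohort$samples$chronological_age,
                        cohort$samples$individual_id, alpha = 0.5, seed = 42)
clock
#> Epigenetic clock (LOIOCV, alpha = 0.50): n = 40 samples, 30 individuals
#>   median absolute error = 1.97 years, Pearson r = 0.950
```

The clock recovers age to within ~2 years out of fold. Merging the
eligible males' social metrics with their clock predictions and fitting
the mixed model (note: select columns before merging so the two
`individual_id` columns do not collide):

```r
accel <- age_accel(clock$predictions$epigenetic_age,
                   clock$predictions$chronological_age,
                   clock$predictions$sample_id)
pred <- cbind(clock$predictions[, c("sample_id", "chronological_age",
                                    "epigenetic_age")],
              age_accel = accel$age_accel)
d <- merge(metrics[metrics$eligible, ], pred, by = "sample_id")

fit <- fit_lmm(d$epigenetic_age,
               cbind("(Intercept)" = 1,
                     bond_strength_norm = d$bond_strength_norm,
                     mean_male_group_size = d$mean_male_group_size,
                     chronological_age = d$chronological_age),
               list(individual = d$individual_id, year = d$window_end_year),
               method = "REML")
fixed_effect_pvalues(fit, "satterthwaite")
#>                   term estimate     se   df  p_value
#> 1          (Intercept)    9.139 1.8902 4.59 0.005916
#> 2   bond_strength_norm  -12.518 4.0412 9.03 0.012718
#> 3 mean_male_group_size   -0.119 2.3284 8.11 0.960416
#> 4    chronological_age    0.745 0.0841 5.44 0.000196
```

The generator injected a bond-strength slope of −9.75 years per unit of
normalized strength; at this toy size (14 analysable samples) the fit
recovers −12.5 ± 4.0 with p = 0.013 — epigenetically *younger* for
stronger bonds — and a chronological-age slope of 0.745. At the
acceptance scale (n = 200, 50 replicates) the recovered means are within
1% of truth (see below).

The whole pipeline (simulate → social metrics → clock → inference →
mediation → report) also runs as one call from a YAML config:

```r
cfg <- validate_config("config.yaml")
run_all(cfg)     # writes social_metrics.csv, clock_predictions.csv,
                 # model_selection.csv, final_model.json, mediation.json,
                 # partial_residuals.csv, run_report.json
```

or from the shell via `Rscript inst/cli/socioclock.R all --config config.yaml`.

## Package layout

- `R/cohort.R` — synthetic cohort generator (individuals, surveys,
  samples, offsets, methylation)
- `R/social.R` — survey filters, SRI, node strength, CV, group size
- `R/clock.R` — probe masking, elastic net, penalty selection, LOIOCV,
  evaluation, AgeAccel
- `R/lmm.R` — crossed-random-intercept ML/REML, p-values, standardized
  coefficients, partial residuals, VIFs
- `R/selection.R`, `R/mediation.R` — two-step AIC selection, robustness
  subsets, quasi-Bayesian mediation
- `R/pipeline.R`, `inst/cli/socioclock.R` — config validation,
  orchestration, run reports, command-line entry point
- `vignettes/socioclock-methods.Rmd` — the model, its assumptions, and
  every numerical design choice
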