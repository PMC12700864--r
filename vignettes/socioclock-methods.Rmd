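---
title: "Methods: social bonds, epigenetic clocks, and mixed-model inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: social bonds, epigenetic clocks, and mixed-model inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and of every
numerical decision that was genuinely open. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## 1. The scientific question and the modelling chain

Individuals of the same chronological age can differ in *biological* age.
In social mammals, the strength of social bonds predicts survival, so it
plausibly also predicts the pace of biological ageing. The package
operationalizes this with a three-stage chain:

*Surveys → social predictors.* Group-encounter surveys (an animal is a
group member if present in the first five minutes; "gambit of the group")
yield dyadic Simple Ratio Indices
$\mathrm{SRI}_{ab} = x / (x + y_a + y_b)$, where $x$ counts surveys with
both animals and $y_a, y_b$ surveys with exactly one. A focal male's
cumulative bond strength is his node strength $S_i = \sum_j \mathrm{SRI}_{ij}$,
normalized by the maximum over *eligible* males (≥ 15 sightings) in the
same window so the predictor lies in [0, 1] for analysed animals. Group
size is the mean count of other males across the focal's sightings; the
CV of a male's SRI values summarizes whether he spreads or concentrates
his bonds.

*Methylation → epigenetic age.* An elastic net
($\alpha = 0.5$; penalty $\lambda\,[\alpha\lVert\beta\rVert_1 +
(1-\alpha)\lVert\beta\rVert_2^2/2]$) regresses chronological age on
beta values of genome-mapped CpG probes. Because some animals contribute
several samples, cross-validation leaves out *individuals*, not samples
(LOIOCV): a prediction for any sample is made by a clock that never saw
any sample of that animal. AgeAccel is the residual of an OLS regression
of epigenetic age on chronological age; by construction it has mean zero
and zero correlation with chronological age.

*Predictors → inference.* The headline model is a Gaussian linear mixed
model
$$y_{s} = \beta_0 + \beta_1 z_s + \beta_2 g_s + \beta_3 a_s +
u_{\mathrm{id}(s)} + v_{\mathrm{yr}(s)} + \varepsilon_s,$$
with $y$ epigenetic age (years), $z$ normalized bond strength, $g$ mean
male group size, $a$ chronological age, and crossed random intercepts for
individual and sampling year. Two-step AIC selection first compares the
four random structures {none, ID, year, ID+year} (ML, full fixed design),
then six nested fixed-effect models adding bond strength, group size,
chronological age, CV of bond strength, and the bond × group interaction
in that order. The selected model is refit by REML for reporting.

## 2. Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `min_sightings` | 15 | surveys | reliability threshold for a male's network metrics; also gates the normalization maximum |
| `resight_window_hours` | 2 | hours | a repeated encounter of the *same group* within this window is pseudo-replication, not new association data |
| `exclude_forage` | TRUE | — | foraging aggregations are co-location, not association |
| `alpha` | 0.5 | — | equal lasso/ridge mixing, the mammalian-clock convention |
| `k_folds` (inner CV) | 10 | folds | penalty selection inside each LOIOCV training set, grouped by individual |
| `nlambda` (inner path) | 50 | — | log-spaced penalty grid; 50 points is ample resolution at n ≈ 90 and halves runtime vs 100 |
| `df_method` | satterthwaite | — | the field's mixed-model convention; `normal` available |
| `adult_age_min` | 14 | years | adult-male robustness subset (alliances are established by this age) |
| `accuracy_max` | 0.5 | years | high-accuracy-birth-date robustness subset |
| `n_sims` (mediation) | 1000 | draws | quasi-Bayesian simulation size |

## 3. What the synthetic generator emulates — and what it does not

`simulate_cohort()` produces ~68 individuals over a 40-year study, ~90
tissue samples (a subset of 18 individuals sampled at 2–3 distinct ages),
alliance-clustered male association via a stochastic block model
(`within_p = 0.55` vs `between_p = 0.02` over 6 clusters), foraging
surveys (20%) and identical-membership resight twins (10%) to exercise
the filters, and ~30k probes of which a minority (default 1500) track
age.

The biological-age offset of each sample is
$\Delta_s = \beta_z (z_s - \bar z) + \beta_g (g_s - \bar g) + u_{id} +
v_{yr} + \varepsilon_s$ with defaults $\beta_z = -9.75$, $\beta_g = 0.90$
(the published coefficients, used as ground truth), and methylation
follows `clip01(intercept + slope × biological_age + noise)` with signed
slopes (probes both gain and lose methylation), magnitudes 0.004–0.012
per year, and clock-probe noise τ = 0.01.

Social fixed effects enter the offset **only for eligible males**. This
mirrors the analysis population, and it is also a correctness matter: the
normalized strength of a male below the sighting threshold is divided by
a maximum taken over *other* (eligible) males and is therefore not
bounded by 1 — early versions fed such values into the offset model and
produced physically absurd offsets (one seed reached z ≈ 12.7, i.e. a
−114-year offset). Females and ineligible males receive only the random
components.

**Noise calibration (chosen once, before any acceptance measurement was
frozen):** σ_id = 1.5 y, σ_year = 0.5 y, σ_resid = 1.5 y. Together with
the fixed-effect contributions for eligible males this puts the SD of
biological−chronological offsets near 2.2–2.5 y, which is what a clock
with a ~2-year median absolute error implies. Bond strength draws use a
Beta(2.9, 4.4) (SD ≈ 0.17, the published predictor SD) and group size a
Gamma(7.7, scale 0.52) (SD ≈ 1.44) in the direct-simulation helpers;
the full generator produces both empirically from the survey process.
Survey group-size distributions are not empirically constrained by any
published table, so they are an exposed configuration, not a claim of
realism.

What the generator does **not** emulate: array technical structure
(detection p-values, batch effects, normalization artefacts), spatial or
home-range structure, female reproductive histories, age-dependent
sociality trends, mortality/dropout. A green test therefore establishes
that the *pipeline machinery* is correct and well-calibrated under the
assumed data-generating process — not that the biological conclusions of
any particular field dataset are robust to violations of that process.

## 4. Numerical choices

**Mixed-model estimation.** The marginal covariance
$V = \sigma^2_e I + \sum_m \sigma^2_m Z_m Z_m^\top$ is formed densely
(the target regime is n of a few hundred; the motivating analysis has
n = 50). The residual variance is profiled out and the optimizer works
on log variance *ratios* $\log\gamma_m = \log(\sigma^2_m/\sigma^2_e)$,
bounded in $[\log 10^{-10}, \log 10^{6}]$ — the lower bound is the
boundary floor; hits are flagged in `$boundary`. `nlminb` runs from
three starts (moderate, large, near-zero ratios) and the best optimum
wins; each likelihood evaluation is one Cholesky of V plus a GLS solve,
with the fixed effects profiled. ML and REML use the standard criteria
(REML adds $\log|X^\top V^{-1} X|$); both were verified against lme4 to
~1e-7 in coefficients, likelihoods, and variance components (see
`test-lmm.R`).

**AIC.** $2k - 2\ell$ with k = fixed effects + all variance components
*including* the residual. Both selection steps use ML fits throughout:
REML criteria are not comparable across fixed structures. The final model
is refit by REML because REML variance components are less biased at
small n.

**Satterthwaite df.** $\nu_j = 2\,[\mathrm{Var}\hat\beta_j]^2 /
(g_j^\top A\, g_j)$, with $g_j$ the central-difference gradient of
$[X^\top V(\theta)^{-1}X]^{-1}_{jj}$ in the variance components θ and A
the inverse negative numerical Hessian of the (RE)ML log-likelihood in θ.
If that Hessian is not invertible (typically at variance boundaries) the
method falls back to the normal approximation with a warning. Known
limitation: Wald-type p-values in crossed designs are mildly
anti-conservative at modest sizes — our calibration simulations at
n = 200 measure type-I rates in the 0.04–0.08 range across seed blocks
around the nominal 0.05, matching lme4's Wald behaviour exactly (SEs
agree to 1e-5); this is a property of the method, not of the
implementation.

**Penalty selection.** The inner grouped k-fold CV reimplements the
cv.glmnet algorithm directly (master penalty path from the training data,
per-fold path fits, pooled squared error) because the wrapper's
per-lambda bookkeeping dominated runtime at these sizes. Inner selection
fits use a relaxed coordinate-descent tolerance (1e-5); the model
actually used is refit at full precision. Single-λ models are obtained
from a short decreasing warm-start path ending exactly at λ — the stable
way to get one elastic-net solution. Ties on the CV curve resolve to the
first (largest-λ) minimizer via `which.min`.

**Degenerate inputs.** SRI of a never-observed dyad is 0 (not NaN); a CV
with fewer than two SRI values or zero mean is NA (recorded, not
dropped); a window with no focal sightings is a per-record error that
marks the record ineligible with a note; constant responses give an
intercept-only clock with a warning; zero-variance vectors make Pearson r
NA; negative predicted ages are reported as-is (AgeAccel is
translation-robust, and clamping would bias the regression).

**Missing betas.** Median imputation per probe, parameters computed on
the training fold only and applied to the held-out fold — never the
reverse. (The generator produces complete matrices; the imputation path
is exercised by the unit tests.)

## 5. Open design decisions and their rationale

- **Resight criterion**: "same group" = identical member set within 2 h,
  because `filter_surveys()` deliberately has no access to sexes; a
  Jaccard overlap-fraction alternative (`overlap_theta`) is provided.
  The first encounter is always retained; a resight of a *dropped*
  (foraging) survey is itself retained, since the dropped survey
  contributed no association data.
- **Window**: first sighting of the focal through 31 December of the
  sampling year — calendar-year granularity for the window end, and the
  window applies to all dyads' counts, not only the focal's.
- **CV partner policy**: nonzero SRIs only, by default. Including the
  zeros of every never-met male would make the CV an increasing function
  of population size rather than a property of the focal's bonds. The
  all-males policy is available (`partner_policy = "all_males"`) and the
  choice is recorded in the output attributes.
- **Eligibility semantics**: SRIs to males below the sighting threshold
  *do* count toward node-strength sums and group size; the threshold
  gates only which focals are analysed and whose maximum normalizes. The
  focal himself is included in the eligible-maximum, so the top male
  scores exactly 1.
- **No age transformation** in the clock: the response is untransformed
  chronological age. A log-linear hook would be easy to add but is off;
  this matters mainly for age-0 calves.
- **Penalty re-selection per LOIOCV fold** (inner grouped 10-fold CV):
  anything else leaks the held-out individual into λ.
- **Mediation structure**: treatment = group size, mediator = bond
  strength, outcome = AgeAccel, covariate = chronological age, OLS
  component models, quasi-Bayesian draws from the asymptotic normals of
  both coefficient vectors, ACME = a·b per draw, percentile intervals.
  With linear models and no treatment × mediator interaction,
  total = ACME + ADE holds exactly per draw (the tests assert it to
  1e-12). The covariate set is configurable; the default is a documented
  choice, not a claim about any published supplement.
- **Config format**: YAML with explicit key/type validation (unknown keys
  rejected by name); all stage seeds derive deterministically from one
  master seed, so a rerun is byte-identical.

## 6. Known limitations

- Dense-covariance likelihoods are O(n³) per evaluation; beyond a few
  thousand observations a sparse mixed-model backend would be needed.
- Wald/Satterthwaite inference is mildly anti-conservative at small n
  (see §4); at n = 50 — the motivating analysis size — p-values near
  0.05 should be read with that in mind. Kenward–Roger or parametric
  bootstrap would be the heavier remedies.
- The clock's accuracy ceiling against *chronological* age is set by the
  generator's biological-age offsets: with the published coefficients as
  truth, eligible males carry ~2.1 y of offset SD from the social terms
  alone, so seed-level median absolute errors straddle 2 y exactly as a
  real clock with MAE ≈ 2.0 would. Recovery tests therefore measure the
  machinery plus the assumed biology, not the machinery alone.
- The generator's survey process is a stochastic block model with
  stationary membership probabilities; real alliance formation is
  developmental and age-structured.
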