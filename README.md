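# healthspan

Multi-state life tables for disability-free life expectancy (DFLE) in ageing
cohorts.

## The problem

Longitudinal surveys of older adults — the motivating design is the China
Longitudinal Healthy Longevity Survey (CLHLS), with waves every two to three
years, disability items at each wave and exactly dated deaths — are routinely
used to ask how many remaining years of life are lived *free of disability*,
and how that differs between groups: people following favourable versus
unfavourable healthy-lifestyle trajectories, or higher versus lower
socioeconomic status (SES). `healthspan` implements the whole estimation
chain for epidemiologists and health-policy analysts:

* rule-based scoring of six healthy-lifestyle factors (smoking, drinking,
  exercise, diet, cognitive activity, sleep), five disability definitions
  (BADL, mobility, vision, hearing, MMSE-based cognition) and the
  socioeconomic vulnerability index (SEVI);
* chained-equations multiple imputation of missing covariates (predictive
  mean matching for continuous, logistic draws for binary variables);
* latent class growth analysis (`lcga()`) to identify trajectory groups,
  with BIC and posterior-classification model selection;
* a three-state illness–death model with recovery, whose four transition
  intensities (nondisabled→disabled, nondisabled→dead, disabled→nondisabled,
  disabled→dead) are Gompertz proportional hazards on age,

  `q_r(a, x) = λ_r exp(γ_r (a − 65)) exp(β_r' x)`,

  estimated from interval-censored wave panels either by midpoint episode
  splitting (fast, sequential) or by the exact interval likelihood;
* weighted group-specific rates `q_g = HR_g · q / Σ_g π_g HR_g` (π_g the
  person-years share of group g in the transition's risk set), so the group
  mixture reproduces the overall rate at every age;
* multi-state life tables over ages 65–115 (exact per-band matrix
  exponential, trapezoid person-years) giving total LE, DFLE, disabled years
  and %DFLE with contrasts against a reference group;
* percentile bootstrap confidence intervals over subjects;
* a synthetic-cohort generator with known ground truth and an independent
  microsimulation oracle (`truth_le()`, `microsim_le()`), so every stage is
  testable without restricted survey data.

## Worked example

A complete run on a synthetic cohort of 3,000 subjects (4 waves ~3 years
apart, entry ages 65–95):

```r
library(healthspan)
run <- dfle_pipeline(scenario = sim_scenario(n_subjects = 3000),
                     config = dfle_config(seed = 3))
run
#> Disability-free life expectancy pipeline run
#>   3000 subjects, 8580 subject-waves | definition: any_of_five | grouping: lifestyle (episode fits)
#>   life-table contrasts at 65:
#>     unfavourable           total LE  12.211 (diff +0.000) | DFLE   6.473 (diff +0.000) | %DFLE 53.01
#>     favourable             total LE  16.238 (diff +4.027) | DFLE   9.042 (diff +2.568) | %DFLE 55.68
```

Reading the output: subjects assigned to the favourable lifestyle-trajectory
group have an estimated 16.24 years of remaining life at age 65 — 4.03 years
more than the unfavourable group — of which 9.04 years (55.7%) are expected
to be lived free of any of the five disabilities. `run$estimate` holds the
fitted transition models, hazard ratios, group proportions, weighted rate
schedules and the per-group `mslt` life tables; `write_dfle_run(run, dir)`
writes the summary tables at reporting precision (3 decimals for years, 2
for percentages).

The contrast arithmetic itself is a one-liner. With published group levels
(total LE 12.828 / DFLE 7.279 years unfavourable; 17.187 / 10.243
favourable):

```r
le_contrasts(data.frame(group = c("unfavourable", "favourable"),
                        total_le = c(12.828, 17.187),
                        dfle = c(7.279, 10.243)))
#>          group total_le total_diff   dfle dfle_diff   dle pct_dfle
#> 1 unfavourable   12.828      0.000  7.279     0.000 5.549 56.74306
#> 2   favourable   17.187      4.359 10.243     2.964 6.944 59.59737
```

Confidence intervals come from `bootstrap_dfle()` (percentile, resampling
subjects and re-running the whole chain per replicate), and
`gompertz_msm(..., method = "interval")` provides the exact
interval-likelihood estimator when the transition intensities themselves are
of interest.

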