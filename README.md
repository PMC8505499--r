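# ntramed

Trimodal radiodensity modelling of mid-thigh CT and multiple-mediator
analysis of physical activity on lower-extremity function.

## The problem

Sarcopenia — age-related loss of muscle strength, function and mass — shows
up in computed tomography as a characteristic shift of soft-tissue
radiodensity: muscle peaks become lower, wider, more skewed and drift toward
0 HU as lean tissue is infiltrated by fat. A mid-thigh CT cross-section
yields, per subject, a distribution of Hounsfield-unit (HU) values over the
soft-tissue range −200 to 200 HU. `ntramed` models that distribution as a
quasi-probability density summing three skew-Gaussian tissue components —
fat, loose connective/water-equivalent tissue, and lean muscle:

```
sum_{i=1}^{3}  N_i / (sigma_i * sqrt(2*pi)) * exp(-(x - mu_i)^2 / (2 sigma_i^2))
             * erfc( alpha_i * (x - mu_i) / (sigma_i * sqrt(2)) )
```

Each component has amplitude `N` (total integrated mass, tracking voxel
count and hence tissue quantity), location `mu` (HU), width `sigma` (HU) and
skewness `alpha`; the central connective component is structurally
symmetric (`alpha = 0`), giving **eleven** subject-specific parameters.
Fitting is bounded nonlinear least squares on bin heights with a
moment-based start and jittered multistarts.

On top of the fit, the package implements a four-step covariate-adjusted
mediation pipeline asking whether these radiodensity parameters *mediate*
the longitudinal relationship between self-reported physical activity (PA,
a five-level score) and four lower-extremity-function (LEF) tasks: fast and
normal gait speed, isometric leg strength, and timed up-and-go.

1. Total effect: `LEF_followup ~ PA + age + sex + BMI + LEF_baseline`.
2. Mediator screen: each of the 11 parameters `~ PA + age + sex + BMI`,
   Holm–Bonferroni across the family of 11 activity p-values.
3. Outcome models: `LEF_followup ~ mediators + covariates + baseline`.
4. Full models: `LEF_followup ~ PA + mediators + covariates + baseline`,
   reporting the attenuation `100 * (beta_full - beta_prior) / beta_prior`
   of the standardized PA coefficient.

Indirect effects are products of coefficients (`a_j * b_j`), with percentile
bootstrap confidence intervals over subject resamples.

Because the individual-level cohort data that motivated this design are
access-restricted, a synthetic-data module generates voxel samples from
known trimodal parameters and longitudinal cohorts with *planted* mediation
paths, so every stage is testable against ground truth. Its defaults
reproduce the published cohort marginals (age 74.9 ± 4.8 y, 58% women,
BMI 27.3 ± 4.2, the five-level activity frequencies, and the published LEF
and radiodensity-parameter moments).

## Worked example

Fit the trimodal model to a synthetic subject sampled at the reference
cohort-mean parameters:

```r
library(ntramed)
p <- ntra_reference_params("baseline")
v <- sample_voxels(p, 1e5, seed = 42)       # voxel HU values
h <- bin_voxels(v)                          # 1-HU histogram over [-200, 200)
fit <- ntra_fit(h, scale = 181.6)           # scale = known total mass
fit
#> Trimodal radiodensity fit
#>   bins: 400   scale: 181.6   converged: TRUE
#>   SSE: 0.321333   R-squared: 0.9993
#> Trimodal radiodensity parameters (HU):
#>              N        mu   sigma   alpha
#> fat    61.7970 -117.7946  8.1282 -2.4720
#> conn   41.9328  -24.0326 24.9570  0.0000
#> muscle 77.5134   61.5257  8.6249  2.8699
```

The generating values (fat 62.0/−117.8/8.2/−2.5; connective
41.6/−24.1/25.1; muscle 78.0/61.5/8.6/2.8) are recovered to within a few
percent from 10^5 voxels; `coef()`, `predict()`, `plot()`, `residuals()`
and `simulate()` methods are available. Run the mediation pipeline on a
cohort with mediation planted through muscle amplitude and location:

```r
gen <- generate_cohort(muscle_mediation_scenario(3000, seed = 42))
rep <- ntra_mediation(gen$cohort, B = 1000, seed = 42)
rep
#> Multiple-mediator analysis of physical activity on LEF
#>   n = 3000 subjects, alpha = 0.05, B = 1000
#>   Step 1 activity effect significant for: gsf, gsn, str, tug
#>   Selected mediators: muscle_N, muscle_mu
#>   Attenuation of the activity coefficient (% change):
#>     gsf    0.1558 ->   0.1170  (-24.9%)
#>     gsn    0.1508 ->   0.1173  (-22.3%)
#>     str    0.0881 ->   0.0543  (-38.3%)
#>     tug   -0.1541 ->  -0.1273  (-17.4%)
rep$bootstrap$str$effects
#>               effect estimate ci_lower ci_upper significant
#> 1  indirect_muscle_N   1.8771   1.2750   2.5035        TRUE
#> 2 indirect_muscle_mu   0.6149   0.3432   0.9553        TRUE
#> 3     indirect_total   2.4920   1.8533   3.1483        TRUE
#> 4             direct   4.0116   2.2804   5.7026        TRUE
```

The screen selects exactly the two planted mediators, every activity
coefficient is attenuated (partial mediation), and all bootstrap intervals
exclude zero — strength (STR) effects are in Newtons, gait effects in m/s,
up-and-go in seconds (negative: more activity, faster completion).
`mediation_tables()` renders the report as five delimited tables;
`mediate_files()` / `simulate_study_files()` and the dispatcher in
`inst/scripts/ntramed.R` provide the file-level workflow.

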