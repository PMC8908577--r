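# octcomp

Compensation of circumpapillary retinal nerve fiber layer (cpRNFL)
thickness for ocular anatomical factors, and evaluation of whether the
compensated measurement discriminates cognitive impairment better than
the raw one.

## Who this is for

OCT cpRNFL thickness is a candidate biomarker of neurodegeneration (mild
cognitive impairment, Alzheimer's disease), but the raw measurement mixes
the axonal signal with nuisance anatomy: optic disc size/shape/tilt,
fovea position, embedded retinal vessels, refractive error, age,
ethnicity and scan quality. `octcomp` is for researchers who want to
remove those contributions sector by sector and quantify the diagnostic
gain with proper paired and cluster-aware inference.

## The model

For each of the 256 circumpapillary sectors *s*, measured thickness in
**control eyes** is regressed on candidate covariates
(age, ethnicity, refractive error, signal strength, disc area/ratio/
orientation, fovea distance/angle, and the sector's own vessel density),
with the covariate subset chosen per sector by minimizing the Gaussian
AIC over all subsets:

    AIC = n log(RSS/n) + 2(k + 1)

Compensation subtracts the selected centered effects, which preserves the
training-population mean:

    compensated(s) = measured(s) − Σ_k β̂_k(s) (x_k − x̄_k(s))

Around the model sit the pieces needed to use it end to end:

* feature extraction from en-face images — disc ellipse morphometry by
  second moments, fovea distance/angle, annular 256-sector vessel density
  (area fraction over a 3.28–3.64 mm band), ETDRS macular composites
  (mGCC, mGC-IPL);
* a diagnostic comparison framework — logistic score models,
  Mann–Whitney AUC, sensitivity at 80% specificity, paired DeLong tests,
  subject-clustered bootstrap confidence intervals, two-sample post-hoc
  power;
* a synthetic cohort and image generator emulating the covariate
  distributions, two-eyes-per-subject clustering, group effects and
  vessel-density confounding of a memory-clinic OCT study, used by all
  shipped checks (no patient data are included).

## Worked example

```r
library(octcomp)

cohort <- generate_cohort(cohort_config(seed = 1))   # 55/108/62 subjects
cohort <- quality_filter(cohort)$kept                # signal strength >= 6
model  <- fit_compensation(cohort)                   # controls, AIC-exhaustive
summary(model)
#> Compensation model summary
#>   training eyes: 76, mean AIC: 339.5, mean model size: 5.01
#>   selection frequency across sectors:
#>              age        ethnicity refractive_error  signal_strength
#>            0.512            0.570            1.000            0.395
#>        disc_area       disc_ratio disc_orientation   fovea_distance
#>            0.695            0.137            0.062            0.562
#>      fovea_angle   vessel_density
#>            0.113            0.961
```

Vessel density is selected in 96% of sectors — the generator couples
vessels into the measured thickness, and the model finds it. Compensation
removes that confound:

```r
dc <- decorrelation_check(cohort, model)
#> r(vessel density, measured)    =  0.193
#> r(vessel density, compensated) =  0.009
```

and the diagnostic comparison (MCI and AD cases vs controls, in-sample
AUC, subject-clustered bootstrap CI, DeLong p vs the measured reference):

```r
build_comparison(cohort, model, contrast = "cases_vs_control",
                 B = 500, seed = 2)
#> Diagnostic comparison: cases_vs_control
#>   1. Measured cpRNFL thickness                        AUC 0.69 (0.63-0.77)  sens@80%spec 50.2  Ref
#>   2. Retinal vessel density                           AUC 0.68 (0.62-0.77)  sens@80%spec 41.2  p=0.935
#>   3. Macular layers (mRNFL, mGCL and mIPL)            AUC 0.82 (0.82-0.92)  sens@80%spec 68.8  p=0.001
#>   4. Compensated cpRNFL thickness and ocular factors  AUC 0.78 (0.73-0.86)  sens@80%spec 58.4  p=0.011
#>   5. Combined (compensated + mGCC)                    AUC 0.87 (0.84-0.93)  sens@80%spec 81.0  p=0.000
```

Measured cpRNFL discriminates modestly (AUC 0.69); compensated thickness
does significantly better (0.78, p = 0.011 vs measured), and adding the
macular ganglion cell complex raises it further (0.87). The two-sample
post-hoc power helper reproduces a standard normal-approximation
calculation:

```r
posthoc_power(33, 4, 170, 36, 5, 55, alpha = 0.05)
#> [1] 98.16983
```

The full pipeline (cohort → quality filter → fit → compensate → report)
runs from one configuration object or YAML file:

```r
run_pipeline(run_config(seed = 1), "out/")   # CSV + JSON + Markdown report
```

A thin command-line wrapper with `simulate | run | fit | apply | compare`
subcommands is installed at `inst/scripts/octcomp.R`.

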