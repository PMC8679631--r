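# fltpet

Quantitative analysis of dynamic ¹⁸F-fluorothymidine (FLT) PET in
hepatocellular carcinoma (HCC) treated with transarterial chemoembolization
(TACE) — for imaging scientists who need the full chain from 4D volumes to
response statistics in one tested, scriptable package.

HCC is hard to monitor after TACE on contrast CT/MRI, and FLT PET, which
images proliferation via thymidine-kinase-1 trapping, is an attractive
response biomarker — if the high physiologic FLT uptake of cirrhotic liver
can be handled. `fltpet` implements:

- **SUV quantification**: late-window summed images, body-weight SUV
  (`SUV = C / (A·1000/W)`), ROI statistics, tumor-to-liver ratios.
- **Image-derived input function**: hottest-voxel blood-pool extraction and
  sigmoid metabolite correction to plasma-parent concentration.
- **Two-tissue compartment kinetics**: the reversible model
  `dC1/dt = K1·Cp − (k2+k3)·C1 + k4·C2`, `dC2/dt = k3·C1 − k4·C2`,
  `C_T = (1−Vb)(C1+C2) + Vb·Cb`, solved by exact bi-exponential convolution;
  bounded multistart Levenberg–Marquardt fitting; the net influx constant
  `Ki = K1·k3/(k2+k3)`.
- **Kinetic spatial filtering (KSF)**: voxel TAC-shape classification against
  tissue templates, majority-relabel spatial regularization, and liver-voxel
  exclusion with signal-suppression metrics.
- **Response statistics**: the inclusive −20% SUV60_mean response rule,
  mRECIST dichotomization, Cohen κ concordance (Fleiss large-sample CI),
  Wilcoxon and χ² tests, cohort aggregates.
- **Seeded simulators**: a 4D digital liver phantom (liver + blood pool +
  spherical tumors, count-scaled Gaussian frame noise) and a synthetic lesion
  cohort generator, so every stage is testable without patient data.

The clinical study's two printed tables (26 lesions / 16 patients; 14
baseline kinetic fits) ship as plain-text fixtures and are reproduced by the
test suite.

## Worked example

Cohort-level response analysis from the packaged lesion table:

```r
library(fltpet)
library(dplyr)

t1 <- load_table1()
cohort_summary(t1) |>
  select(n_lesions, mean_suv60_mean_pre, mean_suv60_max_pre,
         mean_pct_change_mean, pet_responders, mrecist_responders)
#> # A tibble: 1 × 6
#>   n_lesions mean_suv60_mean_pre mean_suv60_max_pre mean_pct_change_mean
#>       <int>               <dbl>              <dbl>                <dbl>
#> 1        26                6.48               9.68                -29.5
#>   pet_responders mrecist_responders
#>            <int>              <int>
#> 1             15                 14

response_concordance(t1)
#> Cohen kappa = 0.657 (95% CI 0.351-0.963), p = 0.0013, n = 24
```

Baseline lesion SUV60_mean averages 6.5 and SUV60_max 9.7; SUV60_mean falls
by 29.5% on average after TACE; 15 of 25 evaluable lesions respond by the
−20% PET rule and 14 of 24 by mRECIST, with good concordance (κ = 0.66,
rounding of 0.657).

Fitting the compartment model to a simulated lesion with the cohort's
patient-3 kinetics recovers the generating parameters and its
Ki = 0.31·0.24/0.64 = 0.116 mL/min/g:

```r
aif_sim <- metabolite_correct(feng_aif(aif_params(), seq(0, 59, by = 0.05)))
truth   <- two_tissue_params(0.31, 0.40, 0.24, 0.04, 0.019)
sched   <- default_frame_schedule()
lesion  <- frame_average(model_tac(truth, aif_sim, seq(0, 59, 0.05)), sched)

fit_2tcm(lesion, aif_sim, sched, fit_config(n_starts = 8))
#> Two-tissue compartment fit
#> <2TCM> K1=0.31 mL/min/g k2=0.4 k3=0.24 k4=0.04 /min Vb=0.019 (Ki=0.116)
#>   weighted RSS 7.502e-24 over 33 frames (9 restarts)
```

Fitted objects support `tidy()`, `glance()` and `autoplot()`; an end-to-end
simulated subject (phantom → SUV → fit → response call, checked against the
simulator's own ground truth) is one call to `phantom_response_pipeline()`.

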