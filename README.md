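# icgperf

Quantitative perfusion analysis of indocyanine green (ICG) fluorescence
angiography for intraoperative bowel assessment, anchored to hyperspectral
tissue oxygen saturation (StO₂).

During laparoscopic colorectal surgery, an ICG bolus is injected and the
fluorescence of the bowel wall is recorded for about two minutes. The
time–fluorescence intensity curve of a region of interest is summarized by
five kinetic quantities:

* **T_MAX** — time from the first fluorescence increase (onset) to the
  maximal intensity (s);
* **T_1/2MAX** — time from onset to half of the maximal intensity (s);
* **perfusion TR** — the time ratio T_1/2MAX / T_MAX, in (0, 1];
* **F_MAX** — maximal intensity above baseline (arbitrary units, AU);
* **slope** — ΔF/ΔT = F_MAX / T_MAX (AU/s).

Safe ranges of these parameters are derived by regressing each parameter on
HSI-measured StO₂ over many colonic assessment points and inverting the fit
at the safe-oxygenation criterion StO₂ ≥ 60% (e.g. T_1/2MAX = 26.351 −
0.267·StO₂ gives 10.3 s at StO₂ = 60%, rounded clinically to ≤ 10 s). The
package implements the full pipeline: curve kinetics (including ROI
extraction from TIFF frame stacks), cutoff regression with confidence
intervals of the mean response, descriptive coverage-interval cutoffs for
irregular parameters, diagnostic evaluation (exact CIs, association tests,
DeLong ROC), the two-stage intraoperative decision protocol and stepwise
StO₂ prediction, Spearman correlation networks, and a seeded synthetic-data
module (cohorts, gamma-variate bolus curves, frame stacks) emulating a
68-patient × 5-point study. See the methods vignette
(`vignettes/icg-perfusion-quantification.Rmd`) for the model details and
design choices.

## Worked example

```r
library(icgperf)

## a synthetic cohort with the study's structure: 68 patients x 5 points
pts <- generate_cohort(cohort_config(), seed = 7)

## regression-based cutoff derivation
fit <- fit_parameter_regression(pts, "t_half_s")
fit
#> <icg_regression_fit> t_half_s (linear, n = 340): t_half_s = 32.678 -0.340 x StO2, R^2 = 0.248
cutoff_schedule(fit, c(60, 70, 80))
#>   sto2_level mean_value    ci_low   ci_high
#> 1         60  12.274520 10.777557 13.771483
#> 2         70   8.873859  7.901794  9.845925
#> 3         80   5.473199  4.799990  6.146407

## diagnostic evaluation of the published safe cutoff (T_1/2MAX <= 10 s)
tab <- dichotomize(pts, "t_half_s", cutoff = 10, direction = "le")
diagnostic_metrics(tab)
#>        metric numerator denominator estimate_pct ci_low_pct ci_high_pct
#> 1 sensitivity       272         329     82.67477  78.143649    86.60596
#> 2 specificity        10          11     90.90909  58.722008    99.77010
#> 3         ppv       272         273     99.63370  97.976112    99.99073
#> 4         npv        10          67     14.92537   7.396468    25.74025
#> 5    accuracy       282         340     82.94118  78.512986    86.78429

r <- roc_analysis(pts, "t_half_s")
sprintf("AUC %.3f (95%% CI %.3f-%.3f)", r$auc, r$ci_low, r$ci_high)
#> "AUC 0.947 (95% CI 0.907-0.988)"

## intraoperative decisions at three assessment points
intraoperative_protocol(sto2_pct = c(65, 45, 55), t_half_s = c(8, 30, 15))
#>                  category                action
#> 1                    good   proceed_anastomosis
#> 2                    poor move_transection_line
#> 3 acceptable_intermediate        surgeon_review
```

Read the fit line as: on this synthetic cohort each percentage point of
tissue oxygenation shortens T_1/2MAX by ~0.34 s, and the safe T_1/2MAX at
the 60% oxygenation criterion is ~12 s (95% CI of the mean 10.8–13.8) — the
cohort-specific analogue of the published ≤ 10 s safe value. The diagnostic
table shows the familiar pattern of a high-sensitivity, high-PPV screen
with weak NPV, and the AUC quantifies the parameter's overall
discrimination of adequate oxygenation.

A thin command-line wrapper over the same functions is installed at
`inst/cli/icgperf.R` (`extract`, `cutoffs`, `diagnose`, `simulate`
subcommands).

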