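# sca1vol

Longitudinal volumetric biomarker analysis for spinocerebellar ataxia
type 1 (SCA1), for imaging statisticians and ataxia researchers who need
to evaluate regional brain volumes as progression markers: which regions
atrophy faster in patients than in controls, whether that change is
measurable within patients alone, how soon it becomes statistically
detectable, and whether it predicts clinical decline on the SARA ataxia
scale (0–40 points).

## What it computes

Given a tidy longitudinal table (one row per subject-visit with group,
gender, age, intracranial volume and 34 regional volumes in mm³) the
pipeline runs:

1. **ICV power-proportion adjustment** — per region, fit
   `VOI = α·ICV^β` by nonlinear least squares, divide by `ICV^β`, and
   rescale to natural units (raw mean and SD). After adjustment the
   volumes carry essentially no ICV signal (|r| < 0.05).
2. **Mixed-effects screens** — per region,
   `ΔVOI ~ group × time + baseline age + gender + (1 | subject)` by REML
   with Satterthwaite df (the group-by-time interaction tests
   differential atrophy), and the affected-only analogue (elapsed-time
   effect), both Bonferroni-corrected with m = 34. A baseline
   cross-sectional comparison with standardized coefficients is included.
3. **Detectability horizon** — the earliest elapsed time at which the
   99% CI of the predicted within-affected cumulative change
   `ĉ(t) = β₀ + β_t·t`, with variance from the fixed-effect covariance,
   excludes zero (bisection to 1e-4 yr, with a closed-form oracle).
4. **Penalized mixed-model selection** — an LME-LASSO over ΔSARA with
   the screened ΔVOIs and their time interactions penalized
   (`max logLik − λΣ|β|`, coordinate descent + profile-ML variance
   updates), λ chosen on the integer grid 1–100 by BIC over relaxed
   refits, with subject-grouped cross-validation alongside.
5. **Label-fusion core (desk scale)** — the morphologically matched
   multi-atlas procedure downstream of registration: exemplar selection
   by Pearson correlation of (log) Jacobian-determinant fields within the
   brain mask, similarity-weighted majority-vote fusion of 10 exemplars ×
   5 label sets, and regional volume extraction (volumes sum exactly to
   ICV).

A synthetic-cohort generator (`sim_config()` / `simulate_cohort()` /
`simulate_sara()` / `simulate_atlas_stack()`) reproduces the study
conditions — 13 affected / 20 unaffected, visits near 0/1.5/3 years with
dropout, published ICV distributions, published atrophy slopes, noise
calibrated to the published standard errors — with full ground truth for
parameter-recovery and calibration studies.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on a
synthetic study-condition cohort and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_icv_adjust.R
Rscript analysis/03_lme_screens.R
Rscript analysis/04_detectability.R
Rscript analysis/05_sara_selection.R
Rscript analysis/06_atlas_fusion.R
```

`02_icv_adjust.R` prints

```
fitted scaling exponents:  0.68 to 1.26
ICV correlation before adjustment:  0.543 to 0.844
ICV correlation after adjustment:   -0.0152 to 0.0123
```

i.e. the allometric exponents straddle 1 (sub-linear for subcortical
structures) and the adjustment removes the head-size signal, mirroring
the published post-adjustment range (−0.0375 to 0.0234). `03_lme_screens.R`
flags the cerebellar, striatal and pontine regions whose planted
interaction slopes are large relative to their calibrated noise
(`regions passing both longitudinal screens: voi_cerebellum
voi_cbl_lobule_6 voi_cbl_wm_deep_nuclei voi_caudate voi_putamen
voi_pallidum voi_pons`), and `04_detectability.R` prints the fastest
horizons:

```
fastest detectable regions (99% confidence):
                    voi t_detect_years group_significant
               voi_pons      0.3190263              TRUE
           voi_thalamus      0.4230658             FALSE
            voi_putamen      0.5503862              TRUE
            voi_caudate      0.6098483              TRUE
 voi_cbl_wm_deep_nuclei      0.6403044              TRUE
           voi_pallidum      0.7399166              TRUE
```

— fractions of a year, the same order and scale as the published 0.49 to
0.99-year horizons. `05_sara_selection.R` selects the penalty by BIC
(`BIC-optimal lambda: 16` on this cohort) and reports the surviving
predictors of SARA change with naive post-selection Wald statistics; the
two dominant terms are the generative truth, putamen change
(β = −1.71e-03 points/mm³, z = −5.84) and pontine change
(β = −1.03e-03 points/mm³, z = −3.81), with a handful of weak extras —
at 59 follow-up rows the BIC curve is shallow and weak terms come and go
between replicates. `06_atlas_fusion.R` labels a 32³ synthetic target
from 10 exemplars × 5 label sets, prints the exemplar similarity ladder
(0.95 down to 0.10, matching the generated correlations), perfect
labelling accuracy against the generating parcellation at the default
10% label-corruption rate, and the extracted volumes (ICV 8552 mm³ on
the desk-scale grid).

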