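# batkin — quantitative PET/MRI analysis of brown adipose tissue

Human brown adipose tissue (BAT) burns lipids and glucose to produce heat.
Whether the fat fraction (FF) measured with water-fat MRI in the
cervical-supraclavicular fat depot (sBAT) tracks the tissue's cold-induced
glucose metabolism — and whether cold-induced FF decreases reflect lipid
consumption rather than perfusion and blood-volume changes — is the kind of
question a combined cooling–reheating PET/MRI protocol answers. `batkin`
implements the full quantitative chain for such studies, for imaging
scientists who have dynamic PET and multi-echo MRI volumes plus region
masks, and want parameter estimates and cohort statistics out the other
end.

## What it computes

* **Perfusion, distribution volume, arterial blood volume, input delay**
  from dynamic [15O]water PET by weighted nonlinear regression of the
  single-tissue compartment operational equation

  C(t) = V_A′·C_A(t−Δ) + (1−V_A′)·F′·∫₀ᵗ C_A(s−Δ)·e^{−(F′/V_T′)(t−s)} ds

  fitted to the first three minutes, frame-averaged (not mid-time sampled),
  with a delay multistart (−10…+30 s), asymptotic per-parameter CVs and a
  CV ≤ 100 % quality-control rule. Residual [18F]FDG during a reheated
  water scan is removed from two bracketing 60 s frames under a constant,
  linear or exponential background model.
* **Net FDG uptake rate K_i and the metabolic rate of glucose** by the
  basis-function implementation of the irreversible two-tissue compartment
  model (one irreversible basis plus 50 log-spaced clearance-rate bases on
  [0.02, 1.0] min⁻¹), voxelwise or per region, with
  MR_glu = C̄ᴾ_glu · K_i / LC (LC = 1).
* **Fat-fraction maps** from 15-echo gradient-echo trains
  (TE₁/ΔTE = 1.70/0.65 ms) by VARPRO-style multi-peak water-fat separation
  with field-map and R2* estimation; FF = 100·|F|/(|W|+|F|), with the
  3.9 pp pilot-sequence correction.
* **Region splitting and statistics**: metabolic HI/LO subregions at
  MR_glu > 11 µmol/100 cm³/min (strict), exact Wilcoxon signed-rank and
  Spearman permutation tests with tie and zero handling, Pearson
  correlations, repeatability CVs, and the condition-change report tables.
* **A synthetic-data generator** producing input functions, dynamic PET,
  multi-echo MRI and whole 12-subject cohorts with known ground truth, so
  every stage is verifiable at desk scale.

## Worked example

```r
library(batkin)

# a ground-truth-known subject: dynamic water PET on the printed framing
sched <- parseFrameSchedule("1x10,8x5,4x10,2x15,3x20,2x30,6x60")
input <- genInputWater(sched)                    # arterial bolus, 0.5 s grid
tac   <- model1tcm(F = 18.3, VT = 70, VA = 7.3, delay = 5, input, sched)
fit   <- fit1tcm(tac, input, window = 180)
fit
#> WaterFitResult: F=18.30 (CV 0.0%), VT=70.0, VA=7.30 (CV 0.0%), delay=5.0 s
```

The noiseless fit returns the generating parameters: perfusion in
ml/100 cm³/min, V_T and V_A in ml/100 cm³, delay in seconds, with CVs at
zero because there is no residual. A full synthetic cohort runs the same
machinery end to end:

```r
cohort <- genCohort(generatorConfig(gridDim = c(16, 16, 8)), seed = 1)
report <- buildReport(analyzeCohort(cohort)$table)
subset(report$changes, region == "sBAT" & contrast == "cold1-baseline",
       c(metric, delta, sd, p, n))
#>       metric     delta       sd           p  n
#> 1         FF -2.545324 2.837744 0.009765625 12
#> 25 perfusion  5.043236 6.203027 0.008300781 11
#> 28        VA  4.706656 2.303711 0.001953125 11
```

Cold exposure lowers sBAT fat fraction by ~2.5 percentage points and
raises perfusion and arterial blood volume, each with its exact paired
Wilcoxon p-value and the per-contrast n after missing-data and QC
exclusions. `report$correlations` holds the FF-vs-MR_glu Spearman/Pearson
table (strongly negative at every temperature condition).

A command-line front end covers the per-file operations:

```sh
inst/scripts/batkin tac  --image dyn.nii.gz --frames frames.json \
                         --mask sbat.nii.gz --out tac.csv
inst/scripts/batkin idif --image dyn.nii.gz --frames frames.json \
                         --mask aorta.nii.gz --plasma-ratio 1.1 --out plasma.csv
inst/scripts/batkin fit-water --tac tac.csv --input plasma.csv --out fit.json
```

## Package layout

| file | contents |
|---|---|
| `R/AllClasses.R` | S4 containers (FrameSchedule, BloodCurve, RegionTAC, DynamicImage, BasisSet, …) |
| `R/io.R`, `R/frame-schedule.R` | NIfTI / JSON / CSV / YAML readers and writers, VOI extraction, image-derived input |
| `R/water.R` | 1TCM forward model, fitting, background subtraction, QC |
| `R/fdg.R` | basis construction, K_i fitting, MR_glu |
| `R/waterfat.R` | multi-peak water-fat separation, pilot correction |
| `R/regions.R`, `R/cohort.R` | HI/LO splitting, exact statistics, report assembly |
| `R/simulate.R`, `R/pipeline.R` | synthetic-data generator and end-to-end cohort analysis |
| `vignettes/bat-quantification.Rmd` | the methods vignette: models, assumptions, numerical choices |
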