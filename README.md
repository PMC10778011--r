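# breslowmsi

Preoperative staging of primary cutaneous melanoma by Breslow thickness —
the depth of invasion in millimetres that drives staging and surgical
margins — from two non-invasive modalities: multispectral imaging (MSI)
and high-frequency ultrasound (HFUS). The package is aimed at researchers
evaluating non-invasive staging algorithms: it implements the image-based
classifier and its feature extraction, simulates the ultrasound
measurement, scores both methods with a full diagnostic-accuracy battery,
and ships a calibrated synthetic-cohort generator so every stage is
reproducible offline.

## What it computes

**Features** (per lesion, from a four-channel image and an ROI mask):
mean gray value of the G/R/IR channels, and the ImageJ-style shape
descriptors

- circularity = 4πA / P²,
- solidity = A / A_hull,
- roundness = 4A / (π · major_axis²),

with a carefully specified sub-pixel perimeter estimator (smoothed
iso-contour with sharp-corner restoration; digital disks measure within
~1% of 2πr and squares within 0.1% of their true perimeter).

**Classifier** — a three-threshold decision tree over the clinical groups
`<1mm`, `1-2mm`, `>2mm`:

```
circularity < 0.75 ?
├── yes: mean G >= 8.0   → <1mm       mean G < 8.0    → 1-2mm
└── no:  mean IR < 113.7 → >2mm       mean IR >= 113.7 → 1-2mm
```

**Evaluation** — 3×3 confusion matrices, one-vs-rest
sensitivity/specificity/PPV/NPV, micro-averaged totals, Cohen's κ with
asymptotic (Fleiss–Cohen–Everitt) confidence intervals, per-category MSE,
and a reconstruction utility that re-derives a published accuracy table's
totals (micro metrics and κ) exactly from its per-class rows.

**Synthetic cohort** — log-normal thickness (moment-matched to mean
1.61 mm, SD 1.69 mm, clipped to 0.135–8.12 mm), clinical subtype/site
frequencies, heteroscedastic ultrasound noise calibrated to
r(measured, true) = 0.943, rendered lesion images whose IR intensity
declines with depth (r = −0.659) and whose boundary irregularity encodes
the category. At zero noise both staging methods recover every lesion's
true category (κ = 1), which is the pipeline's self-consistency check.

## Worked example

```r
library(breslowmsi)

params <- sim_params(n = 101, seed = 42)   # defaults encode the study conditions
run <- run_pipeline(params)
print(run$hfus)
```

```
Breslow staging accuracy (n = 101)
Confusion matrix (rows = truth, cols = predicted):
       predicted
true    <1mm 1-2mm >2mm
  <1mm    40     6    0
  1-2mm    9    19    2
  >2mm     0     2   23
 category  n sensitivity specificity   ppv   npv kappa       ci_95
     <1mm 46       87.0%       83.6% 81.6% 88.5% 0.702 0.563-0.841
    1-2mm 30       63.3%       88.7% 70.4% 85.1% 0.536 0.353-0.719
     >2mm 25       92.0%       97.4% 92.0% 97.4% 0.894 0.792-0.996
Micro: sens 81.2%, spec 90.6% | kappa 0.705 (0.586-0.825)
```

The ultrasound stages 82 of 101 synthetic lesions correctly
(micro sensitivity 81.2%, substantial agreement κ = 0.705). The
image-based classifier on the same lesions is noticeably weaker, and the
multivariate thickness model correlates strongly with truth:

```r
glance(run$msi)    # micro sens 69.3%, spec 84.7%, kappa 0.526
glance(run$model)  # r = 0.912, F = 118, p = 3.5e-36
autoplot(run$hfus) # confusion heatmap; autoplot(run$model) for fit-vs-truth
```

Reconstructing a published accuracy table's totals from its per-class
rows:

```r
reported_accuracy("hfus") |> reconstruct_totals()
#>      n sensitivity specificity   ppv   npv kappa
#> 1   98       0.918       0.959 0.918 0.959 0.858
```

A thin command-line wrapper over the same functions lives at
`inst/cli/breslowmsi.R` (subcommands `simulate`, `extract-features`,
`classify`, `regress`, `evaluate`, `reproduce-tables`, `run-all`).

## Package layout

- `R/cohort.R`, `R/render.R` — synthetic cohort and lesion rendering
- `R/features.R` — descriptors and the perimeter estimator
- `R/classify.R` — the threshold decision tree; `R/categories.R` binning
- `R/regression.R` — multivariate OLS with broom-style methods
- `R/evaluate.R`, `R/reconstruct.R` — accuracy engine and table
  reconstruction
- `R/pipeline.R`, `R/io.R`, `R/plots.R` — orchestration, CSV/PNG/TIFF/JSON
  IO, ggplot methods
- `vignettes/breslow-staging.Rmd` — the methods vignette (model,
  assumptions, calibration, limitations)
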