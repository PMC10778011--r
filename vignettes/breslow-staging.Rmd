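---
title: "Methods: non-invasive Breslow thickness staging and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-invasive Breslow thickness staging and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Breslow thickness — the histological depth of melanoma invasion in
millimetres — drives staging and the choice of surgical margin, but it is
only available after excision. Two non-invasive candidates for estimating
it preoperatively are high-frequency ultrasound (HFUS, direct depth
measurement on a skin cross-section) and multispectral imaging (MSI,
diffuse-reflectance images at a few wavelengths, here green, red and
infrared bands plus an unused autofluorescence channel). `breslowmsi`
implements the MSI feature extraction and threshold classifier, a
simulated HFUS measurement, the statistical battery that scores both
methods against histology, and a synthetic-cohort generator so that the
whole pipeline is testable without clinical data.

The staging target is ordinal with three groups: `<1mm`, `1-2mm`
(both boundaries inclusive — the middle interval is read as closed, which
keeps the three clinical groups exhaustive and sends boundary cases to the
intermediate-risk group) and `>2mm`.

## Image descriptors

For a manually outlined region of interest (ROI), the feature extractor
computes the ImageJ-style quantities:

* **mean gray value** — integrated density / area, per channel;
* **circularity** — $4\pi A / P^2$;
* **solidity** — $A / A_{\mathrm{hull}}$, hull taken over pixel centres,
  hull area by the shoelace formula;
* **roundness** — $4A / (\pi \ell_{\mathrm{major}}^2)$, where
  $\ell_{\mathrm{major}}$ is the major-axis length of the ellipse with the
  same second central moments as the region (the per-pixel $1/12$ variance
  term is added, the standard "Fit Ellipse" convention).

Circularity, solidity and roundness are capped at 1.0: digitisation can
push the raw ratios slightly above 1 (a pixel-centre hull slightly
understates the area of a convex digital region, and a digital disk's
perimeter can measure marginally short), and the cap mirrors how
image-analysis tools report these quantities.

### The perimeter estimator

No published convention pins down the perimeter of a binary mask, yet
circularity depends on it quadratically, so the estimator is specified
exactly and frozen by tests. Naive crack (pixel-edge) boundaries
overestimate a disk's circumference by ~27%; chain-code counts
underestimate squares. `measure_perimeter()` therefore uses a
**binomially smoothed sub-pixel iso-contour with sharp-corner
restoration**:

1. the 0/1 mask is zero-padded and convolved with the separable
   $(1,2,1)^{\otimes 2}/16$ kernel;
2. the 0.5 iso-contour of the smoothed field is traced (marching squares
   with linear interpolation) and its polyline length summed — for a
   straight edge at *any* orientation this contour is exactly straight, so
   staircase bias vanishes; digital disks of radius 10–50 measure within
   ~1.7% of $2\pi r$;
3. smoothing shaves a constant ~0.655 px off each genuinely sharp corner,
   so corners are detected on the *raw* contour (two straight runs of
   length ≥ 2 px meeting across a gap of ≤ 2 px at more than 60°) and
   0.655 px per right-angle-equivalent of turning is added back. The 60°
   floor keeps the ubiquitous 45° axial/diagonal staircase transitions of
   smooth digital boundaries from scoring. A 10×10 square then measures
   40.0; an axis-aligned square of any size has circularity
   $\pi/4 \approx 0.785$ to three decimals.

Degenerate regions whose smoothed field never reaches 0.5 (single pixels,
thin lines) fall back to the raw contour, which keeps the perimeter
strictly positive. The corner-restoration constant is calibrated for
right-angle corners and scaled linearly in the turning angle; very acute
corners are under-restored, a documented approximation that is irrelevant
for lesion-like shapes. Masks whose foreground is not a single
8-connected component are rejected rather than silently merged — the
analysis is defined for one lesion at a time.

## The threshold decision tree

The classifier consumes three features and three thresholds
(`threshold_config()`, defaults 0.75 / 8.0 A.U. / 113.7 A.U. on the 8-bit
0–255 scale):

```
circularity < 0.75 ?
├── yes: mean G >= 8.0  -> <1mm        (irregular, bright green)
│        mean G <  8.0  -> 1-2mm      (irregular, dark green)
└── no:  mean IR < 113.7 -> >2mm      (regular, dark infrared)
         mean IR >= 113.7 -> 1-2mm    (regular, bright infrared)
```

Tie handling is fixed as: "over/higher" branches are closed (`>=`),
"under/lower" branches open (`<`), making the tree a total function.
Solidity, roundness and the R channel are measured and stored but
deliberately unused by the tree; they belong to an earlier variant of the
algorithm whose first stage is out of scope here, and guessing their role
would change the published operating points. The intensity thresholds are
kept configurable because the arbitrary-unit scale of the original device
is not fully specified; 8-bit values are assumed throughout.

## Diagnostic evaluation

`evaluate_classification()` scores a 3×3 confusion matrix (rows = truth,
columns = prediction):

* per category, the one-vs-rest collapse gives TP/FN/FP/TN and from them
  sensitivity, specificity, PPV, NPV and a binary Cohen's κ;
* the totals row micro-averages by pooling the collapsed counts; for
  single-label data this makes micro sensitivity = micro PPV = accuracy
  and micro specificity = micro NPV (an algebraic identity the test suite
  checks and which published total rows display);
* overall agreement is the multi-class κ = $(p_o - p_e)/(1 - p_e)$, which
  depends only on the diagonal and the marginals;
* κ intervals use the large-sample Fleiss–Cohen–Everitt variance with a
  normal quantile, clipped to $[-1, 1]$. The CI procedure of the original
  report is not named, so the asymptotic choice is cross-checked in the
  tests against a 10,000-resample bootstrap (they agree to well under
  25% on the reference matrix) and is exact in the zero-variance limit;
* mean squared error of a continuous estimate is averaged within each
  *true* category; empty categories are reported as absent, not zero.

For the ultrasound method the continuous estimate is the measurement
itself. For MSI no continuous estimate is defined by the published
algorithm, so the pipeline uses the multivariate model's fitted thickness;
this is a design choice of this package and is flagged here prominently —
MSI per-category MSE values are not comparable to any published MSE column
beyond order of magnitude.

### Reconstructing published accuracy tables

`confusion_from_class_metrics()` inverts per-class table rows
(n, sensitivity, specificity) into the confusion matrix's diagonal and
marginals: diagonal$_k$ = round(sens$_k \cdot n_k$), FP$_k$ =
$(N - n_k)$ − round(spec$_k \cdot (N - n_k)$). Rounding must be globally
consistent (ΣFP = ΣFN); if it is not, the function reports the
discrepancy rather than adjusting anything. Since κ and all micro metrics
are functions of diagonal + marginals, a published table's "Total" row can
be recomputed exactly from its per-class rows — this is what the
acceptance checks do. The off-diagonal cells are *not* identified by this
inversion; the one test that needs a full matrix (the bootstrap CI
cross-check) uses a hand-derived consistent completion and says so.

## The regression module

`fit_breslow_lm()` is ordinary least squares of thickness on mean G, R,
IR and circularity with an intercept (the intercept is not stated in the
source description but a no-intercept model on arbitrary-unit intensities
would be meaningless). The headline statistic is the Pearson correlation
between fitted and observed thickness, equal to $\sqrt{R^2}$; overall
significance comes from the regression F-test. No variable selection or
regularisation is applied. Rank-deficient designs abort with the
collinear terms named.

## The synthetic cohort generator

The generator's defaults encode the clinical study conditions:

| quantity | default | origin |
|---|---|---|
| cohort size `n` | 101 | enrolled cohort |
| thickness law | log-normal, moment-matched to mean 1.61 mm, SD 1.69 mm | reported moments; the law itself is a package choice — strictly positive and right-skewed like the observed 0.135–8.12 mm range |
| thickness clip | [0.135, 8.12] mm | observed range |
| subtype probabilities | SSM 69/101, NM 8/101, … | reported subtype table |
| site probabilities | trunk 60/101, extremities 32/101, … | reported site counts |
| HFUS noise | SD = 0.08 + 0.211·t mm | calibrated by root search so that r(measured, true) = 0.943 at n = 10,000 |
| IR model | mean IR = 129.5 − 8·t A.U., lesion scatter SD 13.3 | slope/scatter calibrated to r(IR, t) = −0.659; the intercept is *pinned* to 113.5 − 2·slope so the noise-free, 8-bit-quantised IR value crosses the 113.7 A.U. classifier threshold exactly at 2 mm (113.5 is the rounding midpoint below the smallest integer that passes the threshold — pinning the continuous line at 113.7 itself would let quantisation flip lesions just above 2 mm) |
| G means | 10 / 6 / 6 A.U. by category, scatter SD 4 | chosen once so the simulated MSI classifier lands in the reported performance ballpark (κ ≈ 0.5) while staying perfectly separable at zero noise |
| boundary irregularity | amplitude 0.25 / 0.18 / 0.02 by category | calibrated so circularity ranges (≈0.52–0.59, 0.65–0.72, 0.96–0.98) are strictly separated from the 0.75 threshold |
| grid / radius | 96 px, radius 14–24 px | resolution/speed compromise; descriptors are scale-stable (tested at 2× and 4×) |

Lesion masks are star-convex radial-Fourier perturbations of a disk
(harmonics 2–8, fixed per-category amplitude, random phases): one
irregularity knob controls circularity continuously, and star-convexity
guarantees a single connected component. Clipping the thickness law pulls
the realised cohort mean to ≈1.575 mm, still well within the ±0.1 mm
calibration band around 1.61.

The intercept pinning plus the strictly separated circularity bands give
the generator a useful structural property: with every noise term at zero
(`noiseless_params()`), both the ultrasound binning and the decision tree
recover the true category for *every* lesion, so both methods reach
κ = 1 end-to-end — the pipeline's self-consistency check. Notably, even a
1–2 mm lesion that happens to render with high circularity is still
classified correctly at zero noise, because its noise-free IR value lies
at or above the 113.7 A.U. threshold by construction.

Randomness is organised as named streams (cohort, ultrasound, shapes,
intensity, pixel noise) all derived from one integer seed, so
regenerating one stage never perturbs another and identical
(parameters, seed) pairs give bit-identical output.

### What the generator does not emulate

No optics: LED spectra, autofluorescence physics, speckle, shading and
camera response are absent — channels are flat fields plus Gaussian pixel
noise. No intra-lesion texture or pigment-network structure. ROIs are the
generator's own masks, so the manual-outlining variability of real
practice is absent. Subtype and site are sampled independently of
thickness, although they correlate clinically. Consequently, passing
tests demonstrate that the algorithms are implemented correctly and
behave as specified under the reported cohort statistics — they do not
validate clinical performance on real lesions, and the real-cohort
correlations the generator is calibrated against cannot be independently
reproduced without the original data.

## Numerical choices and degenerate inputs

* Intensities are 8-bit; channel values are clamped to [0, 255] after
  rounding.
* Ultrasound measurements are floored at 0 mm; a floored reading is
  binned as `<1mm`.
* A thickness of exactly 1 or 2 mm bins to `1-2mm`; non-positive
  thickness is a domain error.
* Empty masks, sub-5-pixel regions and multi-component masks are domain
  errors; 16-bit image input is rejected, never truncated.
* κ is undefined (error) when the expected agreement is 1; the asymptotic
  CI requires n ≥ 10.
* All caps, tie conventions and the corner-restoration constant are
  frozen by tests.

## Problem sizes used by the test suite

The stochastic checks run at the sizes the package documents as its
standard verification conditions: cohort moments and ultrasound
correlation at n = 10,000; the rendered IR/thickness correlation at
n = 5,000 lesions; regression coverage with 200 replicates of n = 5,000;
pipeline-level comparisons at the clinical cohort size n = 101 across 20
seeds. All are fixed-seed and deterministic.

## Known limitations

* The perimeter estimator's corner restoration is calibrated for
  right-angle corners; acute corners are slightly under-measured.
* The asymptotic κ interval is a large-sample approximation; for very
  small strata the per-class intervals are wide and approximate.
* The G-channel operating point (threshold 8.0 A.U.) is surprisingly low
  for 8-bit data; lacking a definitive intensity-scale specification, the
  generator simply places its G means around that published threshold and
  the thresholds remain user-configurable.
* Table reconstruction recovers diagonal and marginals only; statements
  that need off-diagonal cells (like CIs) require a completion and are
  labelled as such.
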