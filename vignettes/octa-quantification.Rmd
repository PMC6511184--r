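---
title: "Quantifying OCT-A perfusion density: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying OCT-A perfusion density: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octaperf)
```

## The measurement model

OCT angiography renders retinal blood flow as en-face grayscale images at
selectable depths. `octaperf` implements the quantification chain used in
small clinical OCT-A studies of the vitreoretinal interface:

1. **Slab definition.** The device supplies two surfaces per eye — the
   internal limiting membrane (ILM) and the retinal pigment epithelium (RPE)
   — as per-A-scan depths in μm (depth increases from vitreous to choroid).
   The outer plexiform layer is estimated at a fixed offset,
   `z_OPL = z_RPE − 110`, the inner plexiform layer at 70% of the ILM→OPL
   thickness, `z_IPL = z_ILM + 0.7 (z_OPL − z_ILM)`, and the choriocapillaris
   as the fixed band `[z_RPE + 29, z_RPE + 49)` μm. The superficial (SCP) and
   deep (DCP) capillary plexus slabs are the half-open intervals
   `[z_ILM, z_IPL)` and `[z_IPL, z_OPL)`, so they tile the inner retina
   without double-counting the IPL plane.
2. **Binarization.** The en-face image is reduced to its red channel (the
   reference channel of the RGB export; a gray export is unchanged), a single
   global threshold is set at the arithmetic image mean, and pixels strictly
   above it become "perfused". Strictness is the tie-break: a constant image
   has zero vessels.
3. **FAZ exclusion.** The foveal avascular zone, delineated as a polygon on
   the SCP (vertex coordinates in mm), is rasterized by the pixel-centre rule
   and excluded from analysis in *all three* plexuses — the retinal plexuses
   merge at the FAZ edge, and measuring the FAZ per-slab mostly adds
   variability. Its area is the absolute shoelace area of the polygon.
4. **Perfusion density** is the mean of the binarized slab over the
   non-excluded pixels: foreground inside the FAZ counts in neither numerator
   nor denominator. It is dimensionless in [0, 1] and is a *peri-FAZ*
   density.
5. **Cohort statistics.** Paired changes use the Wilcoxon signed rank test,
   group contrasts the Mann-Whitney test, correlations Spearman's rank — all
   two-sided at α = 0.05, with no multiplicity correction (the report records
   how many tests it ran). Sample-size arithmetic uses the two-sided
   noncentral-*t* power for a two-sample comparison, the only reading under
   which the published sizing statements (power 0.85 at d = 1.1 with 16 per
   group; power 0.8 at a 30%-reduced effect with 32 per group) reproduce.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| scan extent | 3 or 6 | mm | device acquisition presets |
| grid | 245 / 350 | px | AngioPlex-like export sizes; the source studies never state pixel counts, so these are explicit assumptions and any `n_px` is accepted |
| OPL offset | 110 | μm | slab formula above |
| IPL fraction | 0.70 | — | slab formula above |
| CC band | +29 … +49 | μm | slab formula above |
| threshold | image mean | intensity | the macro's "average fix threshold"; computed *before* FAZ painting, over all pixels |
| FAZ rule | pixel centre | — | unbiased, standard, convergent |
| α | 0.05 | — | the study convention |

The threshold function is pluggable (`binarize(img, threshold = ...)`)
because macro descriptions of this workflow do not always distinguish
ImageJ's "Mean" from its IsoData default; the mean reading is implemented and
tested.

## Exact small-sample tests

With 16 eyes per arm, asymptotic p-values are not defensible. The Wilcoxon
signed rank statistic's null distribution is computed exactly (dynamic
programming over all `2^n` sign assignments on a doubled-rank lattice, so
mid-ranks from ties stay exact) for up to 25 nonzero differences; zero
differences are dropped first (the classic convention; a Pratt option
exists). Mann-Whitney uses full rank-split enumeration for combined n ≤ 12
without ties; Spearman enumerates all permutations for n ≤ 7. Above those
sizes the standard normal/t approximations with tie corrections take over.
The test suite checks every exact path bit-for-bit against independent
brute-force enumeration oracles.

## What the synthetic generator emulates — and what it does not

Because the patient scans behind studies of this design are not public, the
package ships a generator whose outputs have *known* ground truth:

* **Vasculature**: connected branching random walks (capillary widths 1-3 px,
  segment lengths scaled to the grid), densified until the foreground
  fraction outside the FAZ hits the target density; the achieved fraction is
  recorded exactly in the ledger. Defaults target the 6×6 mm magnitudes
  (SCP 0.427, DCP 0.434, CC 0.472, between-eye SD 0.027).
* **FAZ**: a jittered 12-gon rescaled to its target area exactly —
  ~0.103 mm² for traction eyes, ~0.198 mm² for controls — strictly avascular
  in the truth image.
* **Anatomy**: smooth ILM/RPE maps with a Gaussian foveal pit and, for
  traction eyes, a raised-cosine anterior ILM displacement confined to an
  adhesion disk (< 1500 μm diameter, the treatment-eligibility bound).
* **Longitudinal effect**: study eyes get an additive SCP shift (default
  −0.014, the published 6×6 mm change) plus per-eye change noise
  (SD 0.015, chosen so a 16-eye paired Wilcoxon lands in the reported
  significance range); controls get zero shift. Control ages are matched
  within ±1 year.
* **Rendering**: truth × 255, Gaussian blur, additive Gaussian noise, clipped
  to [0, 255]. Blur is specified in μm (default 17 μm ≈ 1 px at 6 mm/350 px,
  the transverse PSF scale), so scaled-down simulation grids are not
  over-blurred relative to the preset world.

It does **not** model OCT speckle physics, decorrelation flow signal,
projection artifacts between plexuses, motion artifacts, or JPEG compression
(deliberately: the workflow's historical JPEG step is a reproducibility
hazard, and the package requires lossless input, accepting JPEG only under a
warning). A green test therefore establishes that the *quantification chain*
is correct and calibrated, not that the generator is a physical scan
simulator.

## Numerical behaviour of the mean threshold

One property deserves emphasis. On a blurred rendering of a binary network
whose density is below 0.5, the mean threshold sits *below* the half-height
of a blurred edge (mean ≈ density × 255 < 127.5), so the recovered vessel
mask is slightly dilated: at the 6×6/350 preset with 17 μm blur the measured
density exceeds the truth by roughly +0.02, and more at coarser grids. This
is a faithful property of mean-threshold binarization, not a bug; it is
one-sided, nearly identical at both timepoints, and therefore cancels in the
paired contrasts the method exists to measure. The acceptance suite
demonstrates exactly this: per-image density is biased upward, while the
−0.014 paired SCP shift is recovered without material bias (grand mean
within one within-cohort standard error over 100 simulated cohorts) and the
null rejection rate stays α-calibrated. Noiseless renderings round-trip
exactly, which is how ledger consistency is asserted.

## Degenerate inputs and edge policies

* Boundaries are *always* computed, even for anatomically impossible
  surfaces; `validate_segmentation()` returns a per-A-scan violation mask
  and the exclusion decision is left to the cohort layer, because such
  studies exclude whole eyes, not pixels.
* A polygon with fewer than 3 vertices has area 0 (with a warning);
  self-intersection is an error, not a silent absolute value.
* An exclusion mask covering the whole image raises
  `"empty region of interest"` rather than returning 0/0.
* All-zero paired differences give p = 1 with an annotated method string.
* Every generator is a pure function of `(parameters, seed)`; the cohort
  ledger stores achieved (pixel-exact), not target, densities.

## Design choices that were genuinely open

* **"T_ILM-OPL"** in the slab formula is read as `z_OPL − z_ILM`, the only
  reading consistent with the published slab diagram.
* **En-face projection** from volumes is exposed as `max` (default) and
  `mean`; the device's internal rule is unpublished.
* **Acceptance magnitude tolerance**: "recovered within ±1 SE" is
  interpreted against the within-cohort standard error of the mean change
  (~0.004 density units) — a bias bound of about a third of the effect —
  rather than the standard error of the 100-seed grand mean, which would
  fail ~1/3 of the time for a perfectly unbiased estimator by construction.
* **Simulation scale in tests**: Monte-Carlo acceptance runs use 64-100 px
  grids instead of 350 px to stay inside the CI time budget; density targets,
  effect sizes, physical blur and sample sizes are unchanged by this, and the
  per-image density-targeting tolerance is tested per grid size.

## Known limitations

Surface maps are inputs — there is no boundary detection from raw OCT
volumes. The FAZ is supplied as a polygon (no automatic FAZ segmentation,
matching the manual delineation workflow). Only global mean thresholding is
provided (no Frangi/adaptive enhancement). The generator's noise model is
deliberately minimal; effect recovery results should be read as validating
the pipeline, not as simulated clinical evidence.
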