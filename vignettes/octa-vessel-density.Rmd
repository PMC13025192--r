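---
title: "Parafoveal vessel density from OCTA: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parafoveal vessel density from OCTA: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Optical coherence tomography angiography (OCTA) produces en face images of
retinal blood flow in which vessels appear bright on a dark, speckled
background. A widely used summary of microvascular health is *vessel
density* (VD): the percentage of analyzed pixels classified as vessel in a
binarized angiogram. VD in the parafovea — the ETDRS grid's inner ring
around the foveal avascular zone (FAZ) — drops as diabetic retinopathy
(DR) progresses, but the number obtained depends heavily on how the image
is binarized. `octavd` implements a complete parafoveal VD protocol for
the superficial capillary plexus and a synthetic-cohort experiment that
probes how five binarization strategies — three local (Phansalkar,
sliding-window Otsu, adaptive mean) and two global (global mean, global
Otsu) — differ in their ability to discriminate disease stages.

## Pipeline

Each subject contributes one en face angiogram (nominally 320 × 320 px
covering 4.5 × 4.5 mm, so 0.0140625 mm/px), a binary FAZ mask, and an eye
laterality (OD/OS). The stages are:

1. **ROI construction.** A 3 mm diameter circle is centered on the FAZ
   centroid; the FAZ itself is excluded. "Cropping" is implemented as
   masking: all operators run on the full grid and ignore invalid pixels,
   which avoids coordinate remapping. FAZ and out-of-ROI intensities are
   excluded from *everything* downstream — threshold statistics, the
   Frangi convolution input (invalid pixels are zeroed first), and
   density denominators — so tampering with FAZ intensities can never
   change a result.
2. **Vesselness enhancement.** A 2-D multiscale Frangi filter with scales
   σ ∈ {1, 2} px (from min 1, max 2, ratio 2), blobness sensitivity
   β₁ = 0.5 and structureness sensitivity β₂ = 15. Per scale, the
   γ = 2-normalized Hessian eigenvalues (|λ₁| ≤ |λ₂|) give
   R_B = λ₁/λ₂ and S = √(λ₁² + λ₂²), and

   v_σ = exp(−R_B²/2β₁²) · (1 − exp(−S²/2β₂²)),  zero unless λ₂ < 0,

   with the final response the pixelwise maximum over scales. The map is
   min–max rescaled over the valid pixels and then inverted
   (v′ = 1 − v), so vessels become the dark class.
3. **Binarization.** Five methods, all with the strict dark-vessel rule
   vessel ⇔ intensity < T:
   * Phansalkar: T = m(1 + p·e^(−q·m) + k(s/R − 1)) with a 15 × 15
     window, k = 0.25, p = 2, q = 10, R = 1; m, s are the valid-pixel
     window mean and population standard deviation.
   * Sliding-window Otsu: the inverted map is quantized to 8 bits
     (half-up), and each valid pixel gets the 256-bin between-class
     variance maximizer of its 15 × 15 window.
   * Adaptive mean: T = m + (0.5 − sensitivity); at the default
     sensitivity 0.5 this is pure local-mean thresholding.
   * Global mean: T is the mean of all valid pixels.
   * Global Otsu: one 256-bin Otsu cut over all valid pixels.
4. **ETDRS quadrants.** The parafoveal annulus (radii 0.5–1.5 mm under
   the default diameter convention) is split at 45°/135°/225°/315° into
   superior, inferior, nasal and temporal sectors; which horizontal
   sector is nasal follows eye laterality (for OD, image left under the
   standard en face export orientation).
5. **Densities.** Per quadrant, VD = 100 · vessel px / quadrant px; the
   ring value is the unweighted mean of the four quadrant values (not
   the pooled ratio — the two differ when FAZ masking leaves unequal
   quadrant areas).
6. **Statistics.** A mixed-design repeated-measures ANOVA
   (between-subject factor: diagnostic group; within-subject factor:
   binarization method on the ring density, or quadrant within each
   method), Greenhouse–Geisser-corrected, with Tukey (studentized-range)
   post hoc comparisons run only when the omnibus main effect has
   p < 0.05.

```{r example}
library(octavd)
ph <- make_phantom(phantom_spec(seed = 7))
run_subject(ph$image, ph$faz)
```

## Numerical choices

* **Gaussian derivative kernels** are truncated at 4σ with reflective
  boundary handling, and moment-corrected so that polynomial images give
  exact derivatives (the zeroth moment of g″ is forced to 0 and its
  second moment to 2). On I(r,c) = c² the large eigenvalue is exactly
  2σ² at interior pixels.
* **β₂ operates on 8-bit-scaled structureness**
  (`frangi_params$intensity_scale = 255`). β₂ = 15 is the classic Frangi
  constant for CT-like dynamic ranges; applied to a unit-interval
  Hessian it degenerates the structureness term to ≈ S²/450 (maximum
  vesselness ~10⁻³), which after rescaling yields a near-binary map on
  which the local thresholds collapse. The blobness ratio is scale-free
  either way.
* **Eigenvalue ties:** λ₂ = 0 fails the polarity test (and R_B is
  defined as 0 there), so v_σ = 0 without any 0/0.
* **Threshold ties go to background** (strict inequality), with a
  1e-12 guard absorbing summed-area-table round-off so constant regions
  are deterministically vessel-free.
* **Otsu ties** resolve to the smallest cut; the between-class variance
  comparison is done in exact 128-bit integer arithmetic, so the
  tie-break cannot be perturbed by floating-point noise.
* **8-bit quantization** is half-up (`floor(v·255 + 0.5)`), not R's
  round-half-even.
* **Windows clip at borders and drop invalid pixels**; a window with
  fewer than two valid pixels yields background. No padding value ever
  enters a threshold statistic.
* **Degenerate inputs:** constant images normalize to all zeros (with a
  warning) and produce zero vesselness, empty masks, and 0% densities.

## Design decisions

* **Grid convention.** The ETDRS description (1 mm central circle, inner
  ring to 3 mm) and the 3 mm ROI are coherent only if those figures are
  diameters, so the annulus spans radii 0.5–1.5 mm by default;
  `grid_spec(convention = "radius")` preserves the literal 1–3 mm radius
  alternative (it requires a ≥ 6 mm field).
* **Dark-vessel convention.** Because the vesselness map is inverted
  before thresholding, vessels are the low-intensity class and all five
  methods test intensity < T. For the symmetric criteria (global mean,
  both Otsu variants) this equals the usual bright-object pipeline — a
  property the test suite checks — while for Phansalkar and adaptive
  mean the order of operations matters and is followed literally.
* **Adaptive-mean sensitivity** maps to an additive offset that vanishes
  at 0.5. At the protocol's operating point the decision is therefore
  formula-free, and the knob is monotone: larger sensitivity thresholds
  more aggressively toward background.
* **Greenhouse–Geisser** (rather than Huynh–Feldt) is used because the
  protocol's fractional degrees of freedom imply *some* sphericity
  correction and GG is the conservative default of the commercial
  packages this analysis style comes from. ε is computed from the
  pooled within-group covariance of the repeated measures; for a
  two-level within factor ε = 1 exactly.
* **Unequal group sizes** use the Tukey–Kramer harmonic-mean form.
* **Per-quadrant comparisons** are one-way group comparisons on that
  quadrant's densities with the between-subjects error term of that
  column. Whether such quadrant-level contrasts should instead use a
  pooled error from the full mixed model is ambiguous in this analysis
  tradition; the one-way reading is the conservative, self-contained
  interpretation.

## What the synthetic generator does and does not emulate

`make_phantom` draws 2–4 px wide arteriolar trees as branching random
walks from the image border toward the fovea, fills a capillary mesh of
1–2 px segments until a target vessel fraction (default 0.30 outside the
FAZ) is reached, deletes a group-specific fraction of capillary segments
(dropout: the DR analogue of capillary nonperfusion, default profile
0 / 0.05 / 0.15 / 0.35 for control / noDR / NPDR / PDR), and renders

    image = clip((b + (1 − b) · blur(vessels)) · (1 + speckle), 0, 1)

with a σ = 0.7 px blur, multiplicative zero-mean Gaussian speckle
(default scale 0.15) and a background signal floor b = 0.10. The floor
represents the OCTA decorrelation noise floor: real angiogram
backgrounds are never black, and without it no noise would reach the
background at all, removing the very mechanism (background-noise
inclusion) by which non-adaptive global thresholds overestimate density.
Capillary segments are rejection-sampled to stay space-filling (a
candidate mostly covering existing vessels is redrawn), so deleting a
fraction of segments deletes a comparable fraction of capillary pixels.
`make_cohort` derives one deterministic seed per subject, alternates
laterality, and draws each subject's capillary density from
Normal(0.30, 0.04): without between-subject variability every group
difference, however small, would eventually become significant, which no
real cohort behaves like. The 0.04 figure corresponds to the 3–5
percentage-point between-subject spread reported for parafoveal VD in
healthy eyes.

The generator does **not** model projection or motion artifacts,
segmentation error, the deep plexus, vessel caliber changes, or the
spatial correlation of OCTA decorrelation noise. Passing the synthetic
experiment therefore shows that the *pipeline* ranks and separates
groups as expected when capillary loss is the only signal — it does not
certify performance on clinical images.

## Problem sizes and calibration

The discrimination experiment uses n = 15 subjects per group at the full
320 px geometry (60 angiograms, about a minute of compute). The type-I
calibration of the group main effect runs 200 replicate null cohorts
(equal dropout in all groups, n = 10 per group) at 64 px phantoms — the
calibration concerns the ANOVA's behavior under exchangeable group
labels, which does not depend on image size, and the smaller geometry
keeps 8,000 phantom analyses to a few minutes. The observed rejection
rate is required to fall in [0.03, 0.08] at α = 0.05.

## Known limitations

* On the synthetic cohort the five methods' *mean* densities sit within
  a few percentage points of each other, and the finer ranking between
  them is decided by sub-point margins: adaptive mean and global mean in
  particular are nearly tied, and Phansalkar — not local Otsu — tends to
  produce the lowest values. The group-separation structure (PDR
  separable from control and noDR by every local method; control vs
  NPDR not separable) is stable, but the full method ranking reported on
  clinical data depends on image statistics (speckle texture, plexus
  density) that the synthetic model reproduces only coarsely.
* Densities are reported at full float precision and only rounded for
  display; two runs with the same configuration and seed are
  byte-identical.
* The laterality-to-image-side mapping assumes the standard en face
  export orientation (superior up, OD nasal on the image left); both
  assumptions are configurable (`od_nasal_side`).
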