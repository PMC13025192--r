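# octavd — parafoveal vessel density from OCT angiography

`octavd` quantifies parafoveal vessel density (VD) in en face optical
coherence tomography angiography (OCTA) images of the superficial
capillary plexus, and asks a methodological question: how much does the
choice of binarization method — three local adaptive strategies
(Phansalkar, sliding-window Otsu, adaptive mean) versus two global ones
(global mean, global Otsu) — change the ability to discriminate diabetic
retinopathy (DR) stages? It is aimed at retinal-imaging researchers who
process their own angiogram exports and want a transparent, tested
alternative to opaque device metrics.

## The protocol

For each eye (a grayscale angiogram, a binary foveal-avascular-zone mask,
and a laterality OD/OS):

1. A 3 mm diameter region of interest is centered on the FAZ centroid;
   the FAZ is excluded from every downstream statistic.
2. Vessels are enhanced with a multiscale 2-D Frangi filter (scales
   σ ∈ {1, 2} px, β₁ = 0.5, β₂ = 15). With |λ₁| ≤ |λ₂| the
   γ-normalized Hessian eigenvalues, R_B = λ₁/λ₂ and
   S = √(λ₁² + λ₂²):

       v_σ = exp(−R_B² / 2β₁²) · (1 − exp(−S² / 2β₂²)),   λ₂ < 0,

   maximized over scales, rescaled over the analyzed region, then
   inverted so vessels are the dark class.
3. The inverted map is binarized five ways (vessel ⇔ intensity < T):
   Phansalkar `T = m(1 + 2e^(−10m) + 0.25(s − 1))` in 15 × 15 windows,
   sliding-window Otsu on the 8-bit quantized map, adaptive local mean,
   global mean, and global Otsu.
4. An ETDRS-style parafoveal annulus (radii 0.5–1.5 mm) is split into
   superior / inferior / nasal / temporal quadrants, with the
   nasal–temporal assignment following eye laterality.
5. VD = 100 · vessel pixels / quadrant pixels, and the ring value is the
   mean of the four quadrants.
6. Group differences are tested with mixed-design repeated-measures
   ANOVA (Greenhouse–Geisser corrected) and Tukey post hoc comparisons,
   gated on significant omnibus effects.

Because no clinical images ship with the package, a synthetic angiogram
generator (`make_phantom` / `make_cohort`) produces OCTA-like phantoms —
branching arteriolar trees plus a capillary mesh, circular FAZ,
multiplicative speckle, and group-wise capillary dropout — with known
ground truth, so the whole discrimination experiment is reproducible on a
desktop.

## Worked example

```r
library(octavd)

ph <- make_phantom(phantom_spec(seed = 7))   # 320 px / 4.5 mm phantom
run_subject(ph$image, ph$faz)
```

```
         method vd_superior vd_inferior vd_nasal vd_temporal  vd_ring
1    phansalkar    37.34576    28.14153 38.03828    26.00101 32.38164
2    local_otsu    40.46840    28.22967 39.04558    26.17729 33.48023
3 adaptive_mean    44.73684    31.91891 41.56384    29.96726 37.04671
4   global_mean    44.38429    30.79829 43.11257    28.00302 36.57454
5   global_otsu    38.70562    27.82674 39.08335    24.98111 32.64921
```

Each row is one binarization method; the columns are quadrant densities
in percent and their ring mean. On this phantom the two most liberal
methods (adaptive mean, global mean) sit about four percentage points
above the more conservative ones, and densities differ by quadrant — the
kind of method- and region-dependence the package is built to expose.

The cohort-level experiment simulates 15 subjects per group with dropout
0 / 0.05 / 0.15 / 0.35 (control / noDR / NPDR / PDR), processes all 60
phantoms with the five methods, and fits the statistics:

```r
ex <- run_experiment(seed = 1)
ex$study_method$anova
#> Repeated-measures ANOVA: between = group, within = method (GG epsilon = 0.4187)
#>   group                        F(3.000, 56.0) = 6.954, p = 0.0004645
#>   method                       F(1.675, 93.8) = 1521, p = 4.981e-69
#>   group:method                 F(5.024, 93.8) = 1.994, p = 0.08635
```

Every local method separates PDR from both control and noDR (Tukey
p adj < 0.05) while control vs NPDR stays non-significant — the
qualitative signature of local adaptive thresholding being sensitive to
advanced but not early capillary loss.

A command-line front end with `simulate` / `process` / `stats` /
`experiment` subcommands is provided in `inst/scripts/octavd.R`.

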