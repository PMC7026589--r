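---
title: "The repair-trapping comet model: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The repair-trapping comet model: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cometscreen)
library(dplyr)
```

`cometscreen` is an in-silico counterpart of a microwell-array ("CometChip")
genotoxicity platform in which nucleotide excision repair (NER) is
chemically trapped to make bulky DNA adducts visible in the alkaline comet
assay. This vignette documents the model, its parameters and where they come
from, the synthetic image generator, the quantification algorithm, and the
numerical decisions and limitations a user should know about.

## 1. The biology being modelled

The alkaline comet assay measures DNA strand breaks as the fraction of
fluorescence migrating into the "tail" of an electrophoresed nucleoid
(percent tail DNA). Bulky adducts -- UV photoproducts, aflatoxin B1 or
benzo[a]pyrene adducts -- are themselves invisible: they only break the
strand transiently, while NER excises them. The platform's trick is to add
hydroxyurea plus cytosine arabinoside (HU/AraC), which inhibit the repair
*synthesis* step. Incision still happens, but the single-strand-break (SSB)
intermediate can no longer be filled and ligated, so intermediates
accumulate and the comet assay suddenly sees the bulky damage.

## 2. Damage and trapping kinetics

Lesions enter a linear two-compartment system: a lesion pool incised at rate
$k_\mathrm{inc}$ feeding an SSB-intermediate pool resolved at rate
$k_\mathrm{res}$. For an acute pulse of $N$ lesions the trapped
intermediates at time $t$ are the closed form

$$S(t) = N\,\frac{k_\mathrm{inc}}{k_\mathrm{res}-k_\mathrm{inc}}
  \left(e^{-k_\mathrm{inc}t}-e^{-k_\mathrm{res}t}\right),$$

with the $k_\mathrm{res}\to k_\mathrm{inc}$ and $k_\mathrm{res}\to 0$ limits
handled explicitly (`pulse_intermediates()`). For chemicals incubated
continuously, lesions arrive as a constant flux $\phi$ and the intermediate
pool sits at the steady state $\phi/k_\mathrm{res}$
(`flux_intermediates()`). HU/AraC multiplies $k_\mathrm{res}$ by
$f_\mathrm{inhib}=0.03$, so a continuous exposure is amplified by exactly
$1/f_\mathrm{inhib} \approx 33\times$ in trapped intermediates -- which the
saturating tail transform compresses into the observed $\sim$4x rise in
percent tail DNA.

Genotypes modulate the rates: incision-null mutants (`XPG_null`,
`XPA_null`) set $k_\mathrm{inc}=0$ (no intermediates, with or without
inhibitors); the catalytically dead `XPG_E791A` incises but cannot complete
repair, so $k_\mathrm{res}=0$ and intermediates accumulate even without
HU/AraC. Base-excision-repair substrates (e.g. NDMA methylation damage) use
a slower intrinsic resolution rate and are partly comet-visible untrapped,
which is why NDMA is the one screen chemical positive without inhibitors.

## 3. From SSBs to percent tail DNA

Strand breaks map to percent tail DNA through a saturating exponential,

$$\%T = T_\mathrm{bg} + (T_\mathrm{max}-T_\mathrm{bg})
  \left(1-e^{-S/n_0}\right)\,e^{-X/X_0},$$

with background $T_\mathrm{bg}=10$, ceiling $T_\mathrm{max}=75$ (alkaline
comets saturate well below 100 because some DNA always stays in the head),
response scale $n_0$ per cell model, and a crosslink retention factor
$e^{-X/X_0}$: interstrand crosslinks (cisplatin) anchor DNA and *suppress*
migration, which is why a crosslinker is legitimately negative in a
breakage assay.

Parameter provenance, in one place:

* $T_\mathrm{bg}=10$, $T_\mathrm{max}=75$: the platform's printed basal and
  plateau percent tail DNA.
* UV yield 8000 photoproducts per J/m$^2$ and $n_0$ (fibroblast): solved
  jointly so that 5 J/m$^2$ UV-C at 1 h reads 20 %T untrapped -- the
  published benchmark; with trapping the same pulse then lands at 74.8 %T,
  inside the published 73--78 window. $f_\mathrm{inhib}=0.03$ was chosen
  (before any test was run) to centre that window.
* 1 Gy of gamma radiation induces 1000 SSBs -- the calibration constant the
  standard curve is built on.
* Hepatic cell models carry CYP450 activity scalars (the hepatoma line is
  set 100-fold lower in CYP3A4 and 10-fold lower in CYP1A2 than the
  differentiated hepatic line, matching the published activity gap), and
  inhibitors act on those scalars (ketoconazole, alpha-naphthoflavone).
* The nine screen chemicals' lesion-yield coefficients are *free
  parameters*: they were fixed a priori by a power analysis so the
  simulated screen reproduces the published call table under the default
  noise model. They are scenario definitions, not measured biology.

```{r}
model_tail_percent(scenario_preset("vehicle_wt"))
model_tail_percent(scenario_preset("uv_1h"))
model_tail_percent(scenario_preset("uv_1h_huarac"))
```

## 4. Synthetic image generation

`render_field()` draws each comet as a circular Gaussian head (sigma = one
quarter of the 45 um well diameter) plus a half-Gaussian tail starting two
head sigmas downstream, on an 8x8 lattice of 240 um pitch at 1.6 um/px.
Pixel values are *integrals* of these densities (differences of normal
CDFs), not point samples, so the photon budget is conserved to rounding:
a comet's head/tail split in the rendered image equals the requested
`tail_frac` by construction, which is what makes the segmentation oracle
test meaningful. Poisson noise is applied to signal plus a flat background
of 100 counts, and intensities are clipped to the 16-bit range. Fields
round-trip through ordinary grayscale TIFF plus a CSV ground-truth manifest
and a YAML geometry sidecar.

Realism limitations, deliberately accepted: no optical vignetting or PSF
blur beyond the head/tail widths themselves, no gel autofluorescence
texture, no comet-shape irregularity, and tails are always horizontal
(electrophoresis axis = raster x). These keep the generator's truth exactly
known; the quantifier never uses any of that knowledge except through its
declared geometry defaults.

## 5. Quantification

`register_grid()` finds head peaks (blurred local maxima, greedy
de-duplication, sub-pixel centroids) and estimates rotation and pitch from
nearest-neighbour displacement vectors folded modulo the lattice's
90-degree symmetry; phase offsets come from a circular mean. It recovers
the 240 um pitch to ~0.02% and injected rotations to ~0.03 degrees on
default fields, and raises a classed `cometscreen_no_grid_error` on blank
input.

Each lattice node gets one measurement window spanning one pitch
transversely; along the electrophoresis axis it runs from just ahead of the
head to just before the next *occupied* node (or 1.5 pitches when the
downstream well is empty). Occupancy is decided from the blurred intensity
at the node, not from peak detection -- high-tail comets have faint heads
that peak detection can miss, and extending a window across an occupied
neighbour silently absorbs it (a bug the property suite caught).

Segmentation uses the head-reflection rule on the background-subtracted
column-sum profile: the head is the peak bin plus twice the leading
(anti-tail) mass, the tail is the remainder, so head + tail = total exactly.
The discrete rule is extremely sensitive to peak localisation (one pixel
moves the head by twice the peak bin, ~9 %T at defaults), so the peak is
refined to sub-pixel precision by an iterated centroid over a +/- one-sigma
window -- a region guaranteed tail-free because the rendered tail starts two
sigmas downstream -- and the reflected mass is split linearly at the
boundary column. With the centre on a pixel centre this reduces exactly to
the textbook rule (the worked profile `c(0,10,20,10,5,3,2)` still yields
20 %T). On noiseless single-comet renders the error is below 0.7 %T across
tail fractions 0--0.9; in fully occupied lattices, tails longer than one
pitch are truncated by the tiling and comets above ~80 %T read a few points
low. Records carry QC flags (`edge`, `empty_well`, `low_signal`,
`saturated`, `overlap`) and `qc_filter()` enforces the 100-clean-comet
per-condition gate.

## 6. Statistics

The biological replicate is the well: all inference runs on well medians.
`dunnett_vs_control()` implements many-to-one comparisons with the
classical equicorrelated multivariate-t tail probability (via
`mvtnorm::pmvt`); its adjusted p-values are tested against `multcomp::glht`
as an independent oracle, and a seeded max-|t| permutation route is
available when normality is doubtful. A 2000-replicate null simulation
keeps the familywise error at the nominal 0.05. Dose-series calls gate on
the omnibus ANOVA and count only significant *increases*; there is no
viability cut-off by default (mirroring standard comet scoring), but a
threshold can be applied, and calls report how many doses fall below 50%
viability. Two-factor designs use `aov` + `emmeans` cell contrasts with a
manual Bonferroni over the whole contrast family, and
`paired_t_wells()` handles the degenerate zero-variance edge cases
explicitly.

## 7. Calibration

`fit_standard_curve()` regresses induced SSBs (1000 per Gy) on the rise in
percent tail DNA above the 0 Gy baseline, forced through the origin;
points within 2 %T of the ceiling are excluded as saturated, fewer than
three usable doses or a non-positive slope raise classed errors, and
`estimate_ssb()` clamps below-baseline conditions to zero with a
`no_change` flag rather than reporting negative break counts. Because the
tail transform is mildly saturating, the fitted secant slope exceeds the
tangent $n_0/(T_\mathrm{max}-T_\mathrm{bg})$ and mid-range burdens
round-trip within ~15%; curves refuse to convert across cell models, whose
$n_0$ differ.

## 8. Reproducibility

Every stochastic entry point takes a seed and uses one RNG stream;
`simulate_screen(4207)` deterministically reproduces the published
nine-chemical call pattern (seven positives with HU/AraC, NDMA alone
without, the non-genotoxin and the crosslinker negative). `run_experiment()`
records the seed and a configuration hash alongside its CSV outputs.
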