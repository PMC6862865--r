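---
title: "Methods: quantification models and design choices in mitoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantification models and design choices in mitoquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoquant)
```

mitoquant implements the quantification layer of cell-based studies of
mitochondrial dynamics and autophagy: the arithmetic that turns raw
extracellular-flux traces, fluorescence images, cytometry event lists and
blot densitometry into the per-group numbers a statistics layer then
compares. Every analysis module is paired with a seeded synthetic-data
generator whose hidden parameters are known, so each procedure is validated
by parameter recovery rather than by eye. This vignette documents the
models, the tunable parameters and their defaults, the numerical choices,
and what the synthetic validation does and does not establish.

## Extracellular-flux bioenergetics

A mito-stress-test run measures the oxygen consumption rate (OCR, pmol
O2/min) and extracellular acidification rate (ECAR, mpH/min) of each well
over a sequence of measurement cycles (30 s mixing + 3 min acquisition):
four basal cycles, then three after each sequential injection of oligomycin
(ATP-synthase block), FCCP (uncoupling, maximal respiration) and
rotenone/antimycin A (electron-transport shutdown). `summarize_phases()`
collapses each phase to the mean of its cycles (a last-cycle-only option is
provided for plateau readings) and derives the standard partition:

- mitochondrial respiration `OCR_mito = OCR_basal - OCR_rot/AA`,
- coupled (ATP-linked) respiration `OCR_coupled = OCR_basal - OCR_oligo`,
- proton leak `OCR_leak = OCR_oligo - OCR_rot/AA`,
- spare respiratory capacity `SRC% = OCR_max / OCR_basal x 100`.

`OCR_coupled + OCR_leak = OCR_mito` holds exactly by construction. "Coupled"
is defined as the oligomycin-sensitive portion of basal respiration — the
conventional reading, and the only one consistent with the injection order.
Maximal respiration is taken as the post-FCCP value *even if it falls below
basal*, so SRC below 100% (uncoupler-unresponsive cells) is representable
rather than silently clamped.

ATP production is partitioned between oxidative phosphorylation and
glycolysis following the standard flux-to-ATP stoichiometry. Total
extracellular acidification mixes lactate export (glycolysis) with CO2
hydration (TCA cycle); the glycolytic proton production rate removes the
respiratory component,

$$PPR_{glyc} = ECAR_{tot}/BP - OCR_{mito}\cdot \max H^+/O_2 \cdot
\frac{10^{pH-pK_1}}{1+10^{pH-pK_1}},$$

and the ATP rates are

$$ATP_{ox} = OCR_{coupled}\cdot 2P/O_{oxphos} + OCR_{mito}\cdot 2P/O_{TCA},
\qquad
ATP_{glyc} = PPR_{glyc}\cdot ATP/lactate + OCR_{mito}\cdot 2P/O_{glyc},$$

with total ATP their exact sum (the factor 2 converts O2 to O atoms; P/O is
ATP per O atom). None of the constants are measured by the instrument:
`bioenergetic_constants()` ships them as explicit, overridable
configuration (pH 7.4, pK1 6.093 at 37 °C, max H+/O2 = 1 for glucose,
P/O 2.486 / 0.121 / 0.242, ATP/lactate 1) and every result records the
constants used. The default buffering power (0.1 mpH per pmol H+) is a
placeholder of the right order for a 96-well flux plate; absolute glycolytic
rates on real data require the measured value for the actual medium and
volume. A negative `PPR_glyc` is returned *unclamped* with a warning:
clamping would silently mask a mis-calibrated buffering power.

Per-well rates confound cell density; `normalize_by_signal()` divides each
rate by the well's nuclei-stain signal relative to the plate (or group)
mean. Whether the reference is the plate or the comparison group is an
analysis choice the instrument convention leaves open; both modes are
provided and the plate mean is the default. SRC is left untouched — it is a
ratio of rates and therefore density-invariant already.

## Mitochondrial morphometry

Fragmentation analyses score each segmented mitochondrion with two
moment-based descriptors: roundness $4A/(\pi\,\mathrm{major}^2)$ and aspect
ratio $\mathrm{major}/\mathrm{minor}$, where the axes belong to the ellipse
with the same second central moments as the particle's pixel set. Both tend
to 1 for circular (fragmented) particles; tubular networks have low
roundness and high aspect ratio, and for an ideal ellipse their product
is 1 — a useful internal consistency check, asserted in the tests within
[0.8, 1.2] to allow pixelation.

Segmentation is a global Otsu threshold followed by 8-connected labeling,
an area filter (defaults 9 px² to 10⁵ px²) and exclusion of border-touching
particles, whose axes are truncated and not clearly measurable. Two
numerical choices deserve note:

- *No pre-smoothing by default.* The half-maximum contour of a blurred thin
  ridge lies outside the true edge, so Gaussian pre-smoothing (sd 1 px)
  systematically widens the minor axis of tubular particles and biases a
  true 4:1 aspect ratio down to ~3.76 at some orientations — outside the
  ±0.2 pixelation envelope otherwise observed. With the area filter already
  suppressing noise speckle at realistic signal-to-noise, smoothing is off
  by default (`smoothing_sd = 0`) and available for very noisy data.
- *A contrast guard for blank images.* Otsu always returns a split, even of
  pure noise (class means ~1.6 sd apart). Segmentation therefore requires
  the foreground class to exceed the background mean by 4 background sd;
  otherwise the label map is empty. A blank field yields zero particles,
  not an error.

The generator plants non-overlapping ellipses (placement by bounded
rejection sampling; infeasible packings fail loudly) and renders edges with
4×4 subpixel coverage. Hard center-inside rasterization is *not* used: it
distorts thin shapes so strongly that even the true label map of a 20×5 px
ellipse measures an aspect ratio of ~4.24, whereas real microscope images
have partial-volume edges. With coverage rendering, measured values across
a full rotation sweep stay within ±0.05 of truth for circles and within
about ±0.2 (aspect ratio) and ±0.02 (roundness) for 4:1 ellipses.

Group summaries report mean ± SEM per group and flag groups below 500
particles as under-sampled, reflecting common practice of quantifying >500
mitochondria per group.

## Puncta detection and tandem-reporter autophagy flux

Puncta (LC3, p62, proteinase-K-resistant α-synuclein, tandem-reporter
vesicles) are detected by multi-scale Laplacian-of-Gaussian filtering:
scale-normalized responses over `sigma_range` (default 1–3 px, 4
geometrically spaced scales, matching diffraction-limited spots of sd
~1–2 px), local maxima in space and scale, a threshold relative to the
strongest response in the detection's cell (default 0.3), an absolute noise
floor (default 8 robust sd of the finest response map — this is what keeps
empty cells detection-free), and non-maximum suppression within
$\sqrt{2}\sigma$. Detections are assigned to cells by centroid position in
a cell map (provided mask, or the generator's rectangular tiles); orphan
detections are kept as "unassigned".

The tandem mRFP-GFP-LC3 reporter marks autophagosomes in both channels;
lysosomal acidity quenches GFP, so autolysosomes are red-only. The primary
classification is per-cell count subtraction — autophagosomes = green
count, autolysosomes = red − green — because that is the literal counting
rule such reporters are scored with. A per-vesicle mode (each green punctum
greedily paired to the nearest red within `match_radius`, default 3 px) is
reported alongside as a consistency check; the two agree exactly when
detection is perfect, since every planted green spot coincides with a red
one. Negative subtraction results (green > red, a detection asymmetry) are
clamped to zero and flagged rather than propagated: negative vesicle counts
are physically meaningless, and the flag preserves auditability.

## Cytometry gating, plate-reader and densitometry ratios

Membrane-potential readouts are gated against a biological positive
control: FCCP-collapsed cells define the threshold as their `q`-quantile
(default 0.95), and the sample is scored as the percent of events strictly
above it. The statistic is rank-based, hence invariant to detector gain or
any monotone display transform. Note the design consequence: the gate
passes $(1-q)$ of control-like events, so a mixture with 70% high events
reads $70 + 30\times5\% = 71.5\%$ in expectation — the gate quantifies
"above-control signal", not the mixing proportion itself. Event-level
location statistics (mean, median, geometric mean over positive events,
with zero counts reported) cover fluorescence readouts analyzed as
intensity shifts; both percent-positive and location statistics are
emitted, since which one a given figure used is often unstated.

Plate-reader signals normalized to a nuclei stain and densitometry bands
normalized to a loading control share one operation:
`ratio_to_normalizer()` computes per-unit ratios, group mean ± SEM, and an
optional rescaling so a named reference group's mean is 1. Ratios cancel
any common gain. Background subtraction of band intensities is upstream of
this package; inputs are integrated intensities.

## Statistics layer

Group comparisons use one-way ANOVA (delegated to `stats::aov`) followed by
Newman–Keuls step-down testing on the studentized range, the classical
companion of this assay literature. For a pair straddling $p$ ordered
means, $q = |\bar y_i - \bar y_j| / \sqrt{MS_w/\tilde n}$ with $\tilde n$
the harmonic mean of the two group sizes (the standard unequal-n
extension), compared against `qtukey(1 - alpha, p, df_w)`; no critical-value
tables are embedded. Testing proceeds from the widest span inward and every
sub-range of a non-significant range is declared non-significant untested,
so the significant set is closed under the range rule by construction.
Ties in ordered means are broken by group label, which affects traversal
order only. Degenerate inputs are resolved explicitly (all values equal:
F = 0, p = 1; separated means with zero within-variance: F = ∞, p = 0,
flagged; groups with n < 2 are excluded from post-hoc testing with a
warning). Monte-Carlo validation at the complete null (4 groups, n = 10,
2000 replicates) puts the family-wise error at ~0.05, and on random
datasets Newman–Keuls rejects every pair Tukey HSD rejects, the classical
dominance relation.

Whether "n" should be independent experiments or pooled cells/particles
varies by figure in this literature and is left to the caller; the report
records which unit each stage used (`analysis_unit` in the configuration
snapshot).

## The synthetic generators: what they emulate, and what they do not

The generators reproduce the *statistical structure* the analyses assume:
phase-mean OCR values with i.i.d. additive Gaussian cycle noise and a
log-normal cell-density factor mirrored in the normalization signal;
non-overlapping elliptical particles over Gaussian background noise;
Gaussian spots (sd 1.5 px) on rectangular cell tiles with green ⊆ red
reporter topology; two-component log-normal intensity mixtures; and
multiplicative lognormal loading/noise structure for plate and blot tables.
Well-to-well variance of real flux assays is not published for this kind of
experiment, so generator defaults are chosen for test power, not realism.

They deliberately do not emulate: injection kinetics or oxygen diffusion
into plate plastic; microscope optics beyond partial-volume edges and
Gaussian noise (no PSF tails, no uneven illumination); overlapping or
touching organelles (overlap handling is a separately degraded case, not
part of the accuracy claims); real cell shapes (per-cell aggregation needs
only a partition, so tiles suffice); or cytometry spillover/compensation.
Passing recovery tests therefore demonstrates the *arithmetic and
detection logic* are right under the stated noise model — not that
segmentation or gating choices are optimal for any particular instrument's
artifacts.

## Problem sizes and runtime

The validation suite uses sizes chosen to exercise each claim while staying
fast: 96 wells at 5% cycle noise for flux recovery; 50 images (224 px) for
the morphometry rotation sweep; 20 seeded two-channel frames (2×2 cells of
64 px tiles) for tandem recovery; 10⁴ events × 50 seeds for gating; 2000
null replicates for the family-wise error. The end-to-end
`run_pipeline()` demonstration uses 3 groups × 6 wells, 12 particles ×
2 images per group, 3×3-cell reporter frames, 4×5000-event samples and
4 lanes per group, and reruns byte-identically under a fixed seed.

## Known limitations

Morphometry is 2-D and per-particle; no network/branching analysis. The
blob detector's absolute noise floor assumes the finest-scale response map
is mostly noise — an image tiled wall-to-wall with puncta would bias the
floor upward. Count subtraction inherits any red/green detection asymmetry
(flagged, not corrected). The FCS binary format is out of scope (events are
read from CSV). Buffering power and P/O constants must be supplied for
absolute (rather than relative) ATP rates on real instruments.
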