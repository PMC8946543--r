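---
title: "Nuclear chromatin and colocalization analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nuclear chromatin and colocalization analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`nucoloc` analyses multi-channel confocal z-stacks of peripheral-nerve
Schwann-cell nuclei labelled with DAPI (chromatin), H3K4me3 (euchromatin
mark), PMP22 (peripheral myelin protein 22) and Lamin B1 (nuclear lamina).
The pipeline answers four questions per nucleus and then compares genotypes
(wild-type vs the Trembler-J PMP22-L16P mutant):

1. how many nuclei are in the field and how large is each (3D segmentation);
2. how much of each signal is nuclear (mean intensity over the nuclear mask);
3. where inside the nucleus each signal sits (peripheral vs central);
4. which signals co-occur and co-distribute (five colocalization pairings
   with a randomization significance test).

## Segmentation model

Nuclei are segmented on the DAPI channel only, because chromatin staining
delineates the full nuclear extent while the other marks are partial or
extend into the cytoplasm. A duplicate of the DAPI channel is blurred with
a 2-D Gaussian (sigma 5 px, default) applied per z-plane; voxels whose
blurred intensity lies in the inclusive band [30, 255] are foreground, and
26-connected 3-D components of at least `min_voxels` (50) voxels become
nuclei. Intensities are never measured on the blurred copy: all means are
taken on the raw channels over the final mask, giving fluorescence
intensity per nuclear area in arbitrary 8-bit units. Volume is voxel count
times the physical voxel volume `dz * dy * dx`.

Numerical conventions worth knowing:

* the blur kernel extends to +-3 sigma and treats outside-image as zero
  (fields have dark borders, so this is the physically sensible pad);
* 26-connectivity matches common 3-D analysis suites; touching nuclei are
  not split (no watershed) — a documented limitation, acceptable here
  because fields are sparse;
* the threshold band applies to the blurred image's own scale, with both
  bounds inclusive.

A useful property of this fixed protocol: for an object of roughly uniform
interior intensity `I`, the blurred profile crosses `I/2` at the true
boundary. The low threshold 30 therefore reconstructs the boundary most
faithfully when the local mean intensity near the nuclear edge is about 60;
brighter interiors dilate the mask, dimmer ones erode it. This drives the
synthetic phantom's intensity calibration below.

## Chromatin classification

Within a nuclear ROI, DAPI voxels are classified by fixed intensity bands:
heterochromatin (DAPI-dark) at [150, 255], euchromatin (DAPI-light) at
[50, 150), and voxels below 50 belong to neither class. Both comparisons
are inclusive at their printed lower bounds; the classes are disjoint by
construction, so their Manders co-occurrence is exactly 0. Total chromatin
(TC) is defined as the union of the two classes — i.e. sub-50 nuclear
voxels are excluded from TC; a different choice would silently change the
EC-vs-TC pairing, so the definition is fixed here and stated.

Signal masks for H3K4me3, PMP22 and Lamin B1 use a fixed inclusive
threshold of 50 by default (symmetric with the DAPI-light lower bound);
Otsu's method is available where per-channel adaptivity is preferred. The
original interactive per-nucleus thresholding is deliberately not
reproduced: fixed thresholds are the reproducible surrogate.

## Peripheral vs central profiles

The hand-traced line profiles of the original protocol are replaced by a
deterministic surrogate: on each z-plane of the nuclear mask, a line is
anchored at the in-plane centroid and directed along the mask's principal
axis (longitudinal) or its perpendicular (transverse), sampled at 1-px
steps within the contiguous in-mask run through the centre. Longitudinal
vectors are split into four quarters (distal two = peripheral), transverse
vectors into three thirds (distal two = peripheral). Remainder samples
under integer division are spread so no sector deviates by more than one
sample: distal quarters fill first on longitudinal vectors; a single
transverse leftover widens the central third, two go one to each side.
Planes with fewer than 8 mask pixels (ellipsoid caps) are skipped. Raw
samples — not per-plane means — are pooled across planes and both vector
kinds; per-kind summaries are also reported since pooling is a choice the
original description leaves open.

## Colocalization

Five pairings are computed per nucleus, each per z-slice and summarized by
the median across slices (consistent with the median-based reporting used
throughout): (i) euchromatin signal vs total chromatin, signal-level;
(ii) euchromatin vs heterochromatin masks; (iii) PMP22 vs euchromatin
signals; (iv) PMP22 vs heterochromatin masks; (v) PMP22 vs Lamin B1
signals. For the Manders split coefficients the denominator names the
normalizing operand: M1 normalizes by the second operand of the pairing,
M2 by the first, exactly as the protocol's printed formulas do. The
published verbal labels for M1/M2 are internally inconsistent with those
formulas in places; this package implements the formulas and keeps the
pairing table explicit so there is no ambiguity about direction.

Conventions:

* co-occurrence partner criterion is intensity strictly above 0
  (configurable partner threshold) — masks are treated as 0/1 intensities;
* signal-level pairings zero intensities at or below the chromatin
  config's signal threshold (50) before summation, mirroring thresholded
  Manders coefficients as computed by standard colocalization plugins;
  mask pairings use the raw 0/1 values;
* a zero-denominator Manders coefficient is returned as flagged `NA`,
  never 0, to avoid fabricating anticolocalization;
* Kendall tau-b uses Knight's O(n log n) algorithm with tie correction
  (the test suite cross-checks it against both `stats::cor` and an
  exhaustive O(n^2) pair-count oracle);
* the Costes randomization test tiles the ROI bounding box into
  `block_size` (3 px) squares, permutes the blocks of one channel
  uniformly (edge blocks are permuted with the rest, cycling pixels within
  short blocks), and reports the percentage of `n_scrambles` (100)
  scrambles whose correlation falls below the observed one; the
  correlation is Spearman's rho by default, consistent with the decision
  to avoid Pearson on non-normal intensities (classical Pearson is an
  option); the test runs once per pairing on the mid-slice of the mask.

## Group statistics

Every per-nucleus measure is compared between genotypes with the
two-sample Mann-Whitney U test, two-tailed. (The protocol names a
"Mann-Whitney U signed-rank test"; for independent genotype groups the
rank-sum test is the only applicable reading, and that is what is
implemented.) The p-value is exact by full enumeration when the smaller
group has at most 8 observations and there are no ties, and otherwise uses
the normal approximation with tie and continuity corrections; the two
agree to within 0.02 at the boundary, which the tests verify. Shapiro-Wilk
p-values are recorded per group but never gate the analysis — the pipeline
is nonparametric throughout. Summaries are medians with 95% bootstrap
percentile confidence intervals (10,000 seeded resamples); the original CI
construction is unstated, so the bootstrap is a declared substitute, not
an inference of the original method. No multiple-testing correction is
applied, matching the original reporting; a Bonferroni-adjusted reading is
trivial to apply to the returned p-values if wanted.

## The synthetic phantom

No imaging data are deposited for this system, so the generator is the
test bed: it must realize known ground truth under the same protocol the
real analysis uses. Nuclei are axis-aligned ellipsoids (closed-form
volumes) with semi-axis ratios 1.4 : 1.4 : 3.5 (z : y : x), elongated
in-plane as Schwann-cell nuclei are, placed on a jittered grid so overlap
is impossible by construction. Default volumes are 250 +- 38 um^3 (Wt) and
160 +- 24 um^3 (TrJ); fields hold more nuclei in TrJ (18 vs 12 per field
by default). Scenes are rendered at (0.5, 0.19, 0.19) um voxels — finer
than the panoramic acquisition grid, in line with the sub-micron z-steps
and ~0.1 um cropped-image pixels used for single-nucleus analysis — so
that voxelization error stays subordinate to segmentation behaviour.

Intensity model per nuclear voxel at normalized elliptical radius `r`:

* DAPI: euchromatic base level (55 Wt / 58 TrJ) or heterochromatic level
  (160) on blob regions occupying an exact `hc_fraction` of nuclear voxels
  (0.20 Wt / 0.30 TrJ; spheres of radius 3 voxels placed uniformly,
  trimmed to the exact count), both modulated by a parabolic central
  gradient `1 + g (1 - 2 r^2)`;
* H3K4me3: level 140 (Wt) / 100 (TrJ) on euchromatin with its own central
  gradient (g = 0.35), zero on heterochromatin;
* PMP22: level 80 (Wt) / 120 (TrJ) on a positive-voxel set; exact
  fractions of the positives are placed in euchromatin and
  heterochromatin (0.85/0.05 Wt, 0.70/0.15 TrJ), the remainder in
  DAPI-dim (<50) pockets so every ground-truth overlap fraction is exact
  at any setting; 80% of positives sit in the outer third of `r`;
* Lamin B1: level 150 (Wt) / 100 (TrJ), 85% peripheral.

Additive Gaussian read noise (sd 5 by default) is applied and clipped to
[0, 255]; identical seeds give bit-identical scenes.

Two calibration choices deserve explanation. First, the DAPI gradient
strengths (0.25 Wt, 0.38 TrJ) are set so the near-edge local mean
intensity is about 60, the level at which the fixed blur+threshold
protocol reconstructs the true boundary (see the segmentation section);
the TrJ value is larger because its bigger heterochromatin share raises
the interior mean. With these defaults, segmented volumes track the
analytic ellipsoid volumes within +-10% at default noise. Second, central
dominance of DAPI and H3K4me3 is produced by the radial gradients rather
than by placing heterochromatin centrally: H3K4me3 is zero on
heterochromatin, so a central heterochromatin core would invert the
H3K4me3 polarity, contradicting the phenotype being emulated.

What the phantom does **not** model — and what passing tests therefore do
not show about real data: optical point-spread blurring and z-attenuation,
Poisson shot noise (the additive Gaussian is a deliberate simplification
at 8-bit scale), cytoplasmic PMP22 aggresomes (scenes contain only nuclear
signal, so "clear outside" is exercised structurally, not adversarially),
touching nuclei, and the nucleus-within-animal nesting of real designs
(nuclei are simulated and analysed as independent, exactly as the original
statistics treated them).

## Problem sizes and reproducibility

The test suite runs the full chain on two 50-nuclei preset scenes for the
genotype-contrast checks, 20 nuclei across the overlap-recovery sweep
(f in {0, 0.25, 0.5, 0.75, 1}, noise-free and default noise), 50 seeded
replicates for the Costes null, and 1,000 seeded simulations for the
type-I calibration of the group test — sizes chosen to give stable
directions and rates at interactive runtimes. A single global seed fans
out to fixed per-stage child seeds (scene generation, Costes scrambles,
bootstrap), so each stage is independently reproducible and a pipeline
run is a pure function of (inputs, configuration, seed).

## Known limitations

* Touching nuclei are merged (no watershed separation).
* Vector profiles assume a roughly convex in-plane mask; strongly concave
  masks fall back to the nearest in-mask run through the centroid.
* The voxel z-size must be supplied correctly by the user for volumes to
  be physical; the acquisition description this package follows quotes two
  different z-steps, so the voxel size is an explicit, overridable
  configuration item rather than a hard-wired constant.
* Costes significance saturates at 100% for `n_scrambles` scrambles; it
  is a rank among scrambles, not a continuous p-value.
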