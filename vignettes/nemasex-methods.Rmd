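---
title: "Measuring C. elegans sex ratios from plate images: models, parameters and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring C. elegans sex ratios from plate images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(nemasex)
```

`nemasex` turns a brightfield plate scan into per-worm sex calls and a
plate-level male percentage. This vignette is the package's own account
of the method: what is modelled, which knobs matter, the numerical
conventions adopted where digital geometry forces a choice, and what the
test suite does and does not establish about real data.

## The measurement model

Adult *C. elegans* at 6-7 µm/pixel are elongated dark bodies 700-1200 µm
long and 45-80 µm wide on bright agar. Sexes differ in two ways that
survive this resolution: males are shorter and thinner, and the male
tail ends in a blunt copulatory fan while the hermaphrodite tail tapers
to a fine point. Four shape parameters capture this:

* **length** `L`: arc length of the one-pixel midline (µm),
* **thickness**: foreground area divided by `L` (µm) — a mean width,
* **R1, R2**: at each end of the worm, the ratio `D(X1)/D(X2)` of body
  diameters probed `X1 = 20` µm and `X2 = 120` µm of arc from that end;
  `R2` is the larger end's ratio, `R1` the smaller.

The probe positions are fixed at 20/120 µm (`tail_probe_config()`);
they sit inside the tail taper of an adult but well clear of tip
quantization. Which end is the anatomical tail is never decided — the
max/min construction sidesteps head/tail identity. Objects shorter than
`2 * X2 = 240` µm of midline cannot be probed at both ends and are
rejected (`too_short`) rather than classified.

Classification is nearest-class Mahalanobis: per class (hermaphrodite,
male, larva) the training table yields a mean vector and unbiased
sample covariance over the fixed feature order (length, thickness, R1,
R2); an unknown worm is assigned to the class with the smallest
`sqrt((x - mu)' (Sigma + ridge I)^(-1) (x - mu))`. Per-class (not
pooled) covariances are used: the three classes have visibly different
scatter, and the distance "to each class" reads most naturally as each
class's own second moments. A ridge is added to a class covariance only
when its condition number exceeds `1e8` (doubling from `1e-10` times the
mean variance until conditioning is restored): 4-dimensional covariances
estimated from ~20-46 animals can be near-singular, and a silent
pseudo-inverse would hide that. No distance-based reject option exists;
instead the margin (runner-up minus winner distance) is exported so a
human can review the least certain calls (`export_review()` /
`apply_corrections()`), which replaces an interactive inspection GUI in
scriptable form.

Larvae are a nuisance class: they are counted, but excluded from the
sex-ratio denominator (`male % = 100 * males / (males +
hermaphrodites)`), since the quantity of interest is the sex ratio of
the adult population and late larvae are precisely the objects most
easily confused with adults.

## Segmentation parameters

* `window_um = 300` (adaptive threshold window): about one worm-width
  scale above adult thickness, so a worm never dominates its own
  averaging window, yet small enough to track illumination gradients.
  Implemented as an integral-image box mean with replicated edges.
* `offset = 0.02` (threshold offset, fraction of the 0-1 intensity
  range): rejects low-amplitude noise while keeping the worm-agar
  contrast (~0.3) comfortably foreground. Polarity is dark-foreground
  with a flag to invert.
* Hole filling is applied before region extraction — thinning a
  perforated mask would create spurious skeleton loops.
* Size filters in physical units: area 3,000-120,000 µm², bounding-box
  diagonal 120-2,500 µm, defaults bracketing L4-to-adult animals at
  6-7 µm/px. Border-touching regions are excluded by default because
  their shape parameters would be truncated.

## Numerical conventions in the skeleton metrology

Digital geometry forces several choices; they are made once, here.

**Skeletonization.** Topology-preserving thinning (Zhang-Suen) on the
filled mask, followed by iterative removal of spurs shorter than
`spur_prune_um = 40` µm — thinning artifacts at wide worm heads are
shorter than any real anatomy at this scale. A skeleton that still
branches after pruning (clumped or coiled animals) is rejected as
`branched`; this deliberately reproduces undercounting rather than
risking misclassification of merged objects.

**Canonical orientation.** Pixel-level thinning is not equivariant
under rotations and flips (its sub-iterations treat the four compass
directions asymmetrically), which would make measured features depend
on how the plate happened to be oriented — noticeably so for the tail
ratios, whose inner probe sits three pixels from the tip. Every region
is therefore measured in a canonical orientation (the lexicographically
smallest of its eight dihedral transforms) and the skeleton mapped back
to image coordinates: all four features are exactly invariant under
90-degree rotations and flips of the input.

**Path smoothing and re-digitization.** Raw thinned pixels wiggle up to
a pixel around the true midline, inflating arc length. The ordered path
is smoothed with a short boxcar (window 5, shrinking at the ends) and
re-digitized as a minimal 8-connected chain between anchors every 2 px.

**Endpoint anchoring.** Thinning erodes blunt end caps by a highly
variable amount (one to ten pixels depending on how the cap meets the
pixel grid). The path is therefore extended along its end tangents to
the mask tips and trimmed back to arc = local inscribed-disc radius
+ 1.5 px from each tip — the medial-axis endpoint of the cap plus a
boundary-noise guard. End-shortening becomes consistent across shapes.

**Length metric.** Steps count 1 (orthogonal) and sqrt(2) (diagonal)
times µm/px. This chain metric has a known property: any 8-connected
digitization of a straight segment at angle theta measures
`cos(theta) + (sqrt(2)-1) sin(theta)` per unit length — between 0 and
+8.2% high, averaging about +5.5% over orientations. For a worm in a
natural S-posture the heading sweeps enough of that period that the bias
is nearly constant, and endpoint trimming offsets most of it: measured
lengths on synthetic adults come out within a few percent, biased
slightly long for hermaphrodites (pointed tails erode least). No
correction factor is applied — the classifier sees consistent values,
which is what matters for discrimination — but oracle comparisons
against continuous ground truth inherit this irreducible digitization
floor, which is why the generator-suite tests assert suite-level means
and high per-worm pass rates rather than demanding every random worm of
every posture beat a bound that a perfect digitizer could not.

**Diameter probes.** Probe arc positions are measured from the worm's
end (the mask tip): the trimmed skeleton is used for length, but probes
walk the full tip-to-tip path kept alongside it, so a probe 20 µm from
the end is reachable even where the endpoint trim is deeper than 20 µm
(blunt male fans). The diameter itself is measured by
casting rays along both local normals in quarter-pixel steps until they
exit the mask. A distance-transform read at the (integer) skeleton
pixel was tried first and rejected: `2*dt` overshoots a digital bar's
width by exactly one pixel, and a skeleton pixel one off the medial
ridge under-reads by that offset — together exceeding the one-pixel
error budget. Ray casting is insensitive to off-axis placement and
leaves ~0.5 px of quantization.

## The synthetic plate generator

`render_plate()` exists so every stage is testable without a
microscope. What it emulates: class-specific body sizes and tail tapers
(hermaphrodite 900-1200 µm long, half-width 30-40 µm, both ends
tapering, tail to a point; male 700-900 µm, 22-30 µm, one blunt fan
end; larva 250-600 µm, 10-20 µm); sinusoidal body posture (heading
amplitude 0.45-0.8 rad, wavelength L/1.3-L/1.8, curvature-bounded) —
the S-shapes worms settle into on agar; tip blobs of ~12 µm diameter
(7 µm larvae), since worm ends never resolve to sub-pixel points at
this magnification; bright background (0.85) with a linear illumination
ramp (default ±10%) and Gaussian noise (sd 0.02); egg-shaped
confounders (~55 x 32 µm), optionally placed capping hermaphrodite tail
ends to reproduce the known failure mode in which an egg-capped tail
reads blunt and the animal is miscalled male; debris specks; and
crowding via explicit contact clumps (`attach_prob = 0.04`: ~8% of
animals are dropped onto an already-placed one, membership independent
of class) plus dense-but-separated packing for the rest.

Rasterization stamps discs along the midline with no anti-aliasing, so
the per-animal mask truth is exact; one RNG stream per plate makes
image and truth bit-reproducible from the seed. Worm parameter ranges
were chosen to reproduce the qualitative between-class ordering of the
four features (male shorter/thinner than hermaphrodite, male R2
largest, larva smallest) — they are generator conventions, not measured
constants, and are documented as such.

What it does **not** emulate: bacterial lawn texture, body surface
shading, motion blur, partial transparency, aggregation behaviour
(clump membership here is sex-blind by construction), or the true
morphological variability of mutant strains. Consequently, passing
tests establish the pipeline's geometric and statistical correctness —
not that a classifier trained on the shipped synthetic table transfers
to real plates. For real data the training table must be rebuilt from
labeled single-worm images of the same imaging setup; recall on
synthetic held-out splits (~100%) should be read as an upper bound that
real-image noise (reported historically as 87-96% for adults and
74-79% for larvae on comparable pipelines) will reduce.

## The statistics layer

Strain count tables store (male %, n) per strain; male counts are
reconstructed by nearest-integer rounding (printed percentages round-
trip to within one animal). The him screen runs a 2x2 Pearson
chi-square (male vs non-male, strain vs wild-type reference, df = 1)
and flags at raw p < 1e-4 with no multiple-testing correction and no
Yates continuity correction: at pooled-plate sample sizes (thousands of
animals) the correction is immaterial, and the uncorrected statistic at
that conservative threshold is the conventional screen; both choices
are switchable. The agreement summary reports the Pearson correlation
of paired male percentages over all strains including the reference
(excluding it moves r by less than the reported tolerance) and the
maximum absolute discrepancy at two significant figures alongside full
precision.

`error_analysis()` implements the per-well accuracy study: manual
versus automatic male % correlation, share of wells with error under 10
points, and the error's correlation with male % (after excluding wells
with fewer than `min_animals = 10` — with two animals a single missed
worm is a 50-point error) and with total count. The package bundles a
synthetic per-well table (`synth_well_records()`) with the same schema
— log-uniform well sizes 2-350, crowding-dependent undercount beyond
150 animals, 3% sex misclassification — for structural testing; a real
supplementary raw-data table, where available as CSV, can be fed
through `read_well_records()` and the same function. The sign of the
error-versus-total correlation depends on which regime dominates
(binomial noise in tiny wells pulls it negative; crowding losses in
huge wells pull it positive), so only its existence, not its sign, is a
structural property.

## Problem sizes used in the tests

The suites run on sizes chosen to exercise every code path at
interactive speed: 100-seed generator suites per class for metrology,
a 131-worm rendered pool with twenty 50/50 splits for recall, fifty
small noiseless plates for segmentation counting, and twenty crowded
plates of 200 animals (150 hermaphrodites, 50 males) for the sex-ratio
robustness property, where every plate must undercount yet report male
% within 3 points of the rendered 25%.

## Known limitations

* Touching or coiled animals are rejected, never untangled; heavy
  crowding therefore undercounts (by design, the sex ratio survives).
* The chain-metric digitization floor (above) bounds achievable length
  accuracy against continuous truth at roughly +-2-5% per animal.
* Larvae below ~260 µm of measured midline are unprobeable and
  rejected; short larvae also concentrate the fixed endpoint trim into
  a larger fraction of their length, degrading their length accuracy
  relative to adults.
* Strains with body-shape phenotypes (dumpy, blistered, ruptured) will
  not classify correctly against a wild-type-shaped training table.
* One image is one well; multi-well plates are processed as file
  batches, and stitching is out of scope.
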