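---
title: "Phenetic leaf features: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenetic leaf features: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafmorph)
```

## The problem

Botanists identify plant species from the *phenetic* parts of a leaf: how
many lobes and sinuses the blade has, what the apex and the base look like
(acuminate, acute, rounded, cordate, ...), and how the margin is toothed
(entire, serrate, dentate, crenate and their diminutive forms). leafmorph
turns a single-leaf raster image into exactly these features and matches
them against a labelled reference set with a nearest neighbour rule.

## The shape signature

Everything starts from the **centroid contour distance computed at every
boundary point** (CCD-EBP). The mask's boundary is traced clockwise into an
ordered 8-connected contour, and for each boundary point we record its
Euclidean distance to a reference centre. Conventional centroid contour
distance samples the boundary at a fixed angular interval (36 points at
10°) and can step right over a narrow lobe tip or sinus; using every
boundary point guarantees no extremum is missed
(`ccd_sampled()` implements the conventional variant as a reference mode).

The reference centre is the **incircle centre** — the interior point
farthest from the background, computed with a Euclidean distance transform
— not the area centroid. On bent, lobed or cordate blades the area centroid
drifts toward mass concentrations (and can fall outside the blade
entirely), which injects spurious oscillations into the signature; the
incircle centre stays inside by construction.

### Peaks, valleys and the magnitude-threshold mode

Oscillations of the signature are detected by an alternating scan: while
looking for a maximum, the running maximum is declared a **peak** once the
signal has dropped more than a magnitude threshold `delta` below it, after
which the scan hunts for a minimum, and so on. Small `delta` finds every
ripple; large `delta` only major lobes. Because a single threshold is
brittle, counts are **consolidated over five thresholds** (15, 25, 35, 45,
55 pixels) by taking the mode of the per-threshold counts, with ties
resolved to the first mode encountered. The peak count is the lobe count;
valleys are the sinuses. Extremum *positions* come from the first threshold
whose peak and valley counts both match the modes (first matching the peak
mode when no threshold matches both — the joint case is not otherwise
defined).

Two numerical choices matter here:

* **Cyclic handling.** The scan is linear, so on a closed contour we rotate
  the signature to start at its global minimum and scan across the wrap,
  mapping indices back afterwards. This removes start/end artifacts without
  changing the detector.
* **Working scale.** The thresholds are in pixels, so they are only
  meaningful at a fixed scale. Masks are standardised so the longest image
  side is 512 px (configurable, `standard_size`), with a clear 2 px border.
  A config option (`normalise_dist`) instead rescales the signature to
  [0, 100] before thresholding; raw pixels are the default because the
  published constants are absolute.

An elongated but unlobed blade legitimately reports two peaks (apex and
base); a near-circular entire blade reports zero. Lobe counts of zero are a
valid result, not an error.

## Apex and base

### Vertex fan and the north/south split

Rays from the incircle centre to each detected local maximum partition the
full turn: the angle between consecutive rays is computed with the law of
cosines, the wrap-around vertex included, and the angles sum to 360°
(a conservation property the test suite asserts to 0.5°). The conservation
holds whenever consecutive maxima subtend gaps under 180° — true for any
properly lobed outline; the law-of-cosines angle saturates at 180°, so an
unlobed outline with two or three incidental maxima can sum below the full
turn, which is one reason such outlines are routed to the fallback pole
logic instead. Min–max
normalised angles above 0.5 label a vertex **north**, the rest **south**:
on an elongated leaf the maxima crowd the sides while the apex- and
base-facing gaps are wide, so large vertex angles face the poles. Both
maxima flanking a vertex inherit its region; where a maximum would sit in
both regions, the smaller region's membership is subtracted from the
larger. The **median** member of each region (two middle members for even
counts) is the pole — leaves being roughly bilaterally symmetric, the
middle maximum faces the tip.

The pole's contour segment runs between the signature minima flanking it
(sinuses). Unlobed leaves have no usable minima; the segment then falls
back to a fixed fraction (default 1/8) of the contour centred on the pole,
and the poles themselves fall back to the signature's global maximum and
the point half the contour away. Two robustness guards are ours: the
vertex-fan poles are only accepted when roughly antipodal (cyclic
separation at least a quarter of the contour), and pole regions are clamped
to 4–35% of the contour — the fan degenerates on quasi-unlobed outlines
whose few maxima are rasterisation accidents.

### Which end is the apex?

The north/south split does not say which pole is the apex. The mid-vein
decides: it is wider where it met the petiole (base) and tapers toward the
apex. Square windows with side equal to the incircle radius are centred a
quarter of the pole-to-pole axis inward from each pole; within a window,
vein pixels are found by discretised hue (24 bins; the blade colour
dominates the histogram and the vein occupies clearly different bins) or,
on grayscale input, by intensity deviation from the blade median. The width
is the mean cross-axis run of vein pixels; the wider end is the base. When
no vein is measurable the package falls back to tip sharpness (smaller
flank opening angle = apex) rather than failing, since many archival
scans are binary.

### Curvature description: CCG

The **Centroid Contour Gradient** samples one boundary point of the tip
region per interval angle θ in {0, θ, …, 90°} about the region centroid
(the midpoint of the region's end chord) on the right side of the tip axis
— tips being near-symmetric, the left side would duplicate the information.
With θ = 15° that is 7 points and 6 gradients, each the absolute slope
between consecutive sampled points in the local frame (x along the chord,
y toward the tip). Sampling uses polar angles with a nearest-point
tolerance of θ/2 rather than solving the tangent form directly, which is
singular at 90°; a vertical chord's gradient is capped at `g_max` (1000) so
monotone comparisons survive.

### Type labels

The botanical vocabulary is operationalised from flank geometry. Each
region is split at the tip and a total-least-squares line is fitted to
each flank; the intersection angle and per-flank straightness (rms residual
over flank length, "straight" below `straight_tol` = 0.02) drive the rules:

* apex: < 45° → acuminate; 45–90° straight → acute; > 90° straight →
  obtuse (truncate beyond 150°); curved flanks → rounded, unless the
  terminal gradient jumps abruptly (cuspidate).
* base: a central notch in the region's (smoothed) distance profile →
  cordate; < 45° → attenuate; 45–90° straight → cuneate; > 90° straight →
  obtuse; otherwise rounded.

The 45° and 90° breakpoints are the published ones; the straightness
threshold, the notch depth (6 px after running-mean smoothing over 1/8 of
the region, which wipes out tooth ripples but not the wide cordate dip) and
the obtuse/truncate/cuspidate rules are this package's operationalisation
of the verbal taxonomy, all exposed in `leaf_config()`.

## The margin

Teeth are ripples too small for the lobe thresholds: the same extremum scan
at a **small threshold of 2 px** finds them (1 px admits rasterisation
zig-zags; larger misses fine teeth). Small-threshold extrema that coincide
with large-threshold extrema — lobe tips, sinuses, apex, base — are removed
by a set difference with a proximity tolerance of 1% of the contour length;
consequently the tooth riding each lobe tip is never counted (a five-lobed
leaf with 40 generated teeth yields 35). Teeth inside the apex/base pole
regions are also excluded: near the poles the midrib distance vanishes and
tooth ratios there are meaningless.

The **ripples ratio** — area changed by smoothing the silhouette with a
disk filter (morphological opening then closing, radius incircle/8 by
default) over leaf area — separates entire margins (near zero; threshold
0.005) from toothed ones.

Each tooth is the contour segment between its flanking small-threshold
valleys. The raw signature peak drifts off the tooth's geometric centre
wherever the underlying outline has a radial gradient, so the peak is
re-centred to the segment point farthest from the valley–valley chord
before measuring: flank chords A and B, enclosed area against the chord,
the peak/valleys triangle area, the perpendicular tooth height, and the
chord midpoint's distance to the midrib (pole-to-pole) axis. Teeth whose
valley span exceeds 1.75× the leaf's median are dropped — they are two
teeth merged across a missed valley and distort every aggregate.

The class decision:

* height/midrib ratio < 1/16 → diminutive; > 1/8 → lobe-scale, not a tooth;
* |A/B − 1| beyond `equal_tol` → saw-like (type 1), else triangularity
  (tooth area over triangle area) ≤ 1 → shark-tooth (type 2), > 1 →
  rounded (type 3);
* type 1 → serrate / serrulate, or **doubly serrate** when at least two
  teeth stand 1.55× above the median height and the big group's median
  exceeds the small group's 1.8-fold; type 2 → dentate / denticulate;
  type 3 → crenate / crenulate.

Aggregation uses the **median tooth** (median A/B, median triangularity,
median ratio) rather than per-tooth majority votes: the chords involved are
10–30 px, so individual votes carry ±20% pixel noise, while the median is
the majority tooth whenever the margin is single-typed. `equal_tol`
defaults to 0.3 for the same reason. Margins with fewer than five usable
teeth are entire — sporadic rasterisation extrema are not a toothed margin.
Ciliate (trichome) margins are out of scope: hairs are below raster
resolution and such leaves classify as entire.

## The synthetic generator

`generate_leaf()` rasterises the polar model
$r(\varphi) = R\,E(\varphi)\,(1 + a\cos(k\varphi') + t\,(w(m\varphi') - 1/2))$
on a 512 px canvas: $E$ is an ellipse envelope (elongation = length/width)
locally reshaped at the poles (straight wedges for acute/cuneate/attenuate
flanks, a flat cap for truncate, a Gaussian dip for the cordate notch);
$a$ and $k$ are lobe amplitude and count, phased so a lobe sits on the
apex; $w$ is the tooth waveform — an asymmetric ramp (saw), a mildly
concave symmetric ramp (shark tooth; the concavity keeps the enclosed area
at or below the peak/valleys triangle, the defining property of that
shape), or a rectified sine (rounded). Tooth amplitudes are fractions of
the local radius, so they target the 1/16 and 1/8 taxonomy bands directly:
0.085 for regular teeth, 0.022 for diminutive ones — the measured
height/midrib ratio runs about twice the amplitude on the flanks, which
places those choices safely inside their bands. Doubly serrate margins
amplify every fourth tooth 2.2-fold in place, sharing valleys with the
neighbours, so the two tooth orders have equal periods and remain
distinguishable from merged-tooth artifacts. Optional extras: a 5 px
petiole and a mid-vein colour stripe tapering from 6 px at the base to 2 px
at the apex, painted in a hue distinct from the blade.

Rendering is deterministic per spec; all dataset randomness (rotation,
amplitude/elongation/scale jitter of ±6–8%) flows from the single seed of
`generate_dataset()`, which restores the global RNG state afterwards.

What the generator does **not** emulate: venation networks, surface
texture, lighting gradients, occlusion, damage, petiole curvature, or the
natural within-species covariance of real herbarium material. Passing the
recovery tests therefore demonstrates the pipeline's geometric correctness
and its invariances (rotation, translation, moderate rescaling), not field
accuracy on photographs.

## Species identification

`extract_features()` assembles lobes, sinuses, apex/base types and angles,
the two CCG vectors, margin class, ripples ratio and tooth count.
`knn_classify()` matches a query under a mixed distance — z-scored
numerics, Euclidean distance between CCG vectors (scaled by the reference
pool's spread), 0/1 mismatch per categorical — with 1 nearest neighbour by
default; the matcher is deliberately simple and configurable since the
method's discriminative power lives in the features. Accuracy is the
fraction of matching labels.

## Problem sizes and determinism

The validation suite works at the pipeline's native 512 px scale:
exhaustive-oracle equivalence of the extremum detector on 500 random
arrays; exact lobe recovery for 3–9 lobes across 12 rotations each; margin
recovery on 400 jittered leaves spanning all eight classes (≥ 90%); apex
recovery on 300 leaves over acuminate/acute/rounded (≥ 85%); and a
ten-species, 200-leaf identification round trip (accuracy ≥ 0.9). All
stochastic tests fix their seeds; `scripts/acceptance.R` reruns the
pipeline from scratch for any `--seed`.

## Known limitations

* Teeth on steep flank segments (strong wedge tips, high elongation) are
  invisible to a radial signature: the monotone envelope change across a
  tooth period can exceed the tooth's own oscillation. Tooth *counts* are
  therefore lower bounds; class decisions survive because they aggregate
  the detected majority.
* The apex label of a lobed leaf describes its apical lobe tip, which need
  not match the envelope's nominal apex shape.
* Petiole removal assumes a stalk narrower than 15% of the incircle
  diameter and longer than a quarter of the incircle radius; very narrow
  acuminate drip-tips of similar proportions could be mistaken for a
  petiole, which is why removal is off by default.
* Apex/base disambiguation needs either a colour mid-vein or a sharpness
  contrast between the tips; on binary scans of blunt-ended leaves the
  assignment can flip (features still extract, with apex/base swapped).
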