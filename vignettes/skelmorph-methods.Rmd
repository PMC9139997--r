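---
title: "Skeleton-based shape generation and part-structure morphing: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Skeleton-based shape generation and part-structure morphing: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skelmorph)
```

## The growth model

Every shape is a **main body** plus a tree of **parts**, each represented
by a skeletal path. Growth of a path is a first-order angular random walk:
the first segment deviates from a reference direction (upward for the main
body, the outward normal of the parent for attached parts) by a turning
angle drawn uniformly within ±`angle_range_deg`, and each subsequent
segment deviates from its predecessor by an independent draw from the same
range. Segment lengths are uniform in `seg_length_range`. For highly
curved limbs the *magnitude* of each turning angle is drawn uniformly in
[`angle_min_deg`, `angle_range_deg`] (50–100° for the curved stimulus
family) with a random sign, which guarantees visible articulation at every
joint rather than merely allowing it.

Key representational choice: a part stores its growth *realization* in a
root-local frame — the first-segment deviation, the turning angles, the
segment lengths, and the width parameters — rather than rendered
coordinates. Mirroring is then an exact sign flip of the angular
quantities, straightening is an exact multiplication of the turning
angles, and re-rooting (displacement, transplantation) changes only the
attachment frame. All geometric invariants the test suite checks to 1e-9
or better (mirror involution, segment-length conservation, displacement
arc-length exactness) follow from this exactness by construction; the only
approximation in the pipeline is the polygon union.

"Angle between joints" is interpreted as the *unsigned turning angle*
between successive skeletal segments (deviation from collinearity), since
scaling it toward zero straightens a limb out while preserving inter-joint
distances — the behavior the straightening operation must have. The
interior-angle reading would not have this property.

## Silhouettes

The joints are interpolated by a natural cubic spline parameterized by
cumulative chord length (the simplest C² interpolant consistent with
"smoothing" a polyline), sampled at `samples_per_segment` points per
segment. The silhouette offsets every sampled point perpendicular to the
local tangent by half the local width:

```
width(s) = base_width × rel_width × profile(s) × (1 + (taper − 1)·s)
```

with `profile` the per-joint width factors interpolated linearly in arc
length, `s` the arc-length fraction from root to tip, and rounded
(semicircular) end caps. Rare micro self-intersections of the offset at
high curvature are resolved by a nonzero-fill polygon simplification,
keeping the largest ring. A straight constant-width path therefore yields
a stadium whose area and perimeter match the closed forms to well under 1%
at default sampling — one of the acceptance-level geometry checks.

The main body is deliberately simple: a straight vertical 3-joint skeleton
of length 1 (the canvas unit) with a mild mid-bulge width profile
(defaults 0.82/1.00/0.72 of a 0.34 maximum width), giving an upright,
elongated blob with a well-behaved boundary. Its perimeter is
parameterized by arc length with origin at the topmost boundary point,
oriented counterclockwise — so fractions in (0, 0.5) cover the left flank
and (0.5, 1) the right, and mirroring maps t to 1 − t. Limb roots are
restricted to the lateral zone t ∈ [0.06, 0.44] (and its mirror) to keep
them off the top/bottom cap regions.

## Composition

The composed silhouette is the boolean union (via the Clipper polygon
library, `polyclip`, at an explicit resolution of 1e-12 canvas units) of
the body polygon and all part polygons, accumulated parents-first. A union
that leaves a part disconnected raises a composition error; sibling limb
overlap is permitted and resolved by the union. One segmentation point is
recorded per part: its root, which lies on the parent's boundary for
first-order limbs and on the parent's skeleton for sprouts. Zero-size
sprouts ("non-existent", the most animal-like end of the growing-sprout
schedule) are recorded in the part list and contribute a segmentation
point but no geometry.

## The three manipulations

* **Symmetry displacement.** Exactly one limb of each mirrored pair moves
  along the perimeter by a fraction in {0.025, …, 0.125}; which member and
  which direction are random. A shift that would cross into a cap region
  is clamped with a warning in the low-level operation; the experiment
  builders instead sample the direction among those with room, so the
  nominal displacement is always realized exactly. Wrapping a limb across
  the body's top was rejected as biologically nonsensical.
* **Straightening.** Turning angles are multiplied by a factor in (0, 1];
  segment lengths are untouched; joints are rebuilt by forward
  reconstruction. The operation is a multiplicative semigroup:
  straightening by a then b equals straightening by ab.
* **Sprouting.** Sprouts root at a uniform skeletal fraction in
  [0.3, 0.8] of their parent (avoiding root and tip, matching the look of
  mid-limb branching), grow orthogonally to the parent tangent on a random
  side, and have summed length `size_scale` × parent length. Transplanting
  re-roots an existing first-order pair onto a host pair under the same
  placement rule, preserving the donors' articulation.

## Morph sequences

A sequence holds part identity fixed and varies three schedules across 5
steps. All schedules are linear — the simplest monotone choice consistent
with a continuous animal→plant progression: displacement 0 → 0.125 (the
largest level of the pair experiments), straightening factor 1.0 → 0.05,
and sprout size 0 → 0.6 of the parent in the *growing* condition or
constant 0.6 in the *symmetrical* condition (where sprouts also form
mirror pairs whenever their parent does). Sprouts straighten along with
the first-order limbs. First-order limb counts run 2–6; odd counts leave
one limb unpaired, placed on a random side at a position that mirrors no
existing root. The displacement plan (which pair member, which direction)
is drawn once per sequence so steps differ only in the scheduled
magnitudes.

## Stimulus designs

* Design 1 (pairs isolating one cue): limb counts {2,3,4,5} × 5 levels ×
  20 replicates = 400 pairs per condition. Symmetry pairs: one member with
  exact mirror pairs, the other with one limb per pair displaced by the
  level. Curvedness pairs: a curved member (angle magnitudes 50–100°) and
  the same shape straightened by the level factor — attachments and
  segment lengths identical within the pair.
* Design 2 (part hierarchy): 4 types (symmetrical/asymmetrical ×
  curved/straight, the modifiers applied identically to both members
  using the middle level of each scale, 0.075 and 0.15) × 125 pairs = 500.
  Member A has two symmetric first-order pairs (insect-like); member B has
  one pair transplanted onto the other (tree-like).
* Design 3 (morphing): 110 sequences × 5 steps = 550 shapes. The split
  across cells is a balanced factorial — 5 limb counts × 2 sprouting
  conditions × 11 replicates — and the 550 shapes are presented in a
  seeded random order so sequences are not apparent.

Wherever a count or level set is fixed above, it is part of the study
conditions; everything else (body proportions, limb widths, attachment
zones, sprout placement ranges) is a package default chosen once for
visual plausibility and documented here, and overridable through the
growth-parameter and spec objects. Reproducibility follows a single
documented scheme: one root seed per design, per-shape child seeds derived
by a fixed affine counter map, and all drawing routed through a
state-restoring seed guard.

## Cues and the synthetic observer

Three deterministic cue measurements operationalize the manipulations:
mean attachment offset of nominal pairs as a perimeter fraction
(asymmetry; NA when no pairs exist), mean unsigned turning angle over
first-order limbs in degrees (curvedness), and summed second-order part
area over total silhouette area (sprout prominence). These are *artifact*
definitions — they exist to make the generator's manipulations measurable
and the observer testable, not as claims about human feature extraction.

The observer weights the cues linearly into "plant evidence". Under the
default `"sum"` pooling the mean asymmetry and curvedness cues are scaled
by their part multiplicities (pairs and first-order limbs respectively),
so evidence accumulates across parts. This is the one mechanism in the
package by which limb count affects responses; with it, psychometric
slopes grow with the number of limbs (more parts → stronger evidence swing
across the morph), and without it (`"mean"` pooling) they do not. In the
2-AFC task the probability of choosing member B is
`lapse + (1 − 2·lapse) · plogis(Δevidence)`, saturating at `1 − lapse`;
in the slider task the rating is `plogis(evidence + ε)` with Gaussian ε on
the logit — which keeps ratings in [0, 1] with no clipping — plus uniform
lapses. Default weights (12, −0.012, 8; bias 0.55; noise 0.8; lapse 0.02)
are plant-positive: asymmetric, straight, sprouting shapes look more
plant-like, and pooled ratings come out mildly plant-biased, matching the
qualitative direction of the reference findings.

Cue weights are recovered from simulated 2-AFC data by logistic regression
on the effective cue differences. The identifiability harness uses a
balanced pool — symmetry pairs, curvedness pairs, and dedicated
sprout-size pairs (identical shapes except sprouts of a random size
0.3–1.0, two per limb) — because the sprout-prominence cue spans a
structurally narrow numeric range and needs deliberate variation to be
well conditioned at 5200 trials.

## Statistics

The binomial preference test, one-way ANOVA, Tukey HSD and one-sample t
are thin, validated wrappers over the standard R implementations; the test
suite checks each against an independent brute-force computation (pmf
summation, explicit sums-of-squares, the studentized-range formula, the
closed-form t). Two components are authored here:

* the **JZS Bayes factor** for a t-contrast — a Cauchy(0, 0.707) prior on
  effect size expressed as a normal-by-inverse-gamma mixture and
  integrated adaptively over the mixing variable, cross-checked against a
  200,001-point trapezoidal quadrature on a bounded substitution to 1e-6
  relative error;
* the **psychometric fit** — a bounded maximum-likelihood logistic with
  lapse and guess rates (Bernoulli likelihood for binary data, squared
  error for ratings), multi-start L-BFGS-B, with a `flat` flag (and a
  warning rather than an error) when the data carry no usable slope. This
  is a deliberately deterministic, dependency-light summary of sigmoidal
  trends; it reports point estimates, not posterior distributions.

"One-sided ANOVA" is read as the standard one-way ANOVA, F tests being
inherently one-tailed. A one-sample t on constant data is treated as a
degenerate-input error rather than t = 0, since the statistic is 0/0
there.

## Numerical choices and problem sizes

Canvas units are continuous Cartesian, y-up, body height 1. Boundary
sampling defaults to 24 points per segment for the body and 12 for limbs;
polygon-union resolution is 1e-12; silhouette vertex dedup rounds at
1e-12. The test suite exercises the full published design sizes (400 +
400 + 500 pairs and 110 sequences with SVG rendering), 1000-path angle
sweeps, 20-replicate weight-recovery and slope-pattern simulations at
5200 and 7700 trials, and a 1000² rasterization oracle for the union —
the complete run takes a few minutes on a single core.

## What the synthetic data do and do not show

The generator and observer emulate the *structure* of the reference
experiments: trial counts, factor crossings, response formats, and the
direction of every cue effect. Passing tests therefore demonstrate that
the stimulus machinery delivers the intended parametric manipulations and
that the analysis battery is correct — not that human observers behave
like the synthetic one. Numbers that depend on human data (overall
preference rates, the 0.59 rating bias, specific F and BF values) are not
reproduction targets; where the suite uses printed counts (e.g. 4735 of
5200), it checks the *statistics pipeline* against them, not the observer.
Known limitations: no texture, shading or 3-D; no collision avoidance
between sibling limbs beyond the union; holes created by self-overlapping
part arrangements are discarded with the largest-ring rule; and the
local symmetry of sprouts themselves is not manipulated.
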