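---
title: "Measuring digital clubbing from finger profiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring digital clubbing from finger profiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfsa)
```

## The clinical quantity

Digital clubbing is a bulbous enlargement of the fingertip associated
with lung and cardiovascular disease. Its earliest objective sign is a
change in the **Lovibond angle** (profile angle): the angle at the nail
base between the dorsal line of the distal phalanx and the nail plate,
seen in lateral view. A normal finger shows roughly 160°; the angle
approaches 180° as the nail base swells and exceeds 180° in frank
clubbing. The package grades this angle into four levels:

| severity | angle (degrees) |
|----------|-----------------|
| normal   | ≤ 160           |
| mild     | 160 – (180 − ε) |
| moderate | within ε of 180 |
| severe   | > 180 + ε       |

A mathematically "exactly 180°" profile has probability zero for
continuous landmark coordinates, so the moderate class is implemented
as a band `|angle − 180| ≤ ε` with configurable half-width ε
(default 0.5°). Without the band the moderate class would be
unreachable by any measured angle.

## The triangle construction and its ambiguity

Three anatomical points are extracted from a segmentation of the
finger: **A**, the nail base (nail matrix); **B**, the first phalanx
nail fold on the dorsal skin proximal to A; **C**, a distal point on
the dorsal nail-plate edge. Their pairwise distances give a triangle;
the law of cosines gives the interior angles, e.g.

$$\theta_A = \arccos\!\left(\frac{AB^2 + AC^2 - BC^2}{2\,AB\,AC}\right),$$

and the scored quantity is the *remaining angle*
$360° - \max(\theta_A, \theta_B, \theta_C)$.

This transform has a genuine ambiguity: the interior angle at A is the
same whether the nail plate dips below the phalanx dorsal line (normal)
or lifts above it (clubbed). A 160° profile and a 200° profile both
yield a remaining angle of 200°. The package therefore computes both:

* `remaining_angle()` — the literal transform, kept for fidelity;
* `profile_angle()` — an orientation-resolved angle that uses a dorsal
  reference direction: when C lies on the dorsal side of the line
  through A along A→B the angle is `360 − θ_A`, ventrally it is `θ_A`.

Grading uses the profile angle by default; `grading_config(grading_basis
= "remaining")` switches to the literal transform. This dual is an
interpretation forced by the geometry, not a claim that either variant
is canonical.

Numerical choices: the cosine argument is clamped to [−1, 1] before
`arccos`, so exactly collinear landmarks give angles {180, 0, 0} and a
straight profile grades as moderate rather than erroring; ties in
`max(θ_A, θ_B, θ_C)` break in the fixed order A, B, C; degrees are used
at every API boundary; image coordinates have the origin at the
top-left pixel centre with y growing downward.

## The phantom generator

Real clinical photographs need a trained segmenter and carry no exact
ground truth, so verification runs on **phantoms**: rendered lateral
finger silhouettes in which the true profile angle θ\* is a parameter.
The phantom is a horizontal finger band (default 56 px thick on a
200×150 px canvas) with a rounded ventral tip; a nail band (~6 px) runs
along the dorsal edge near the tip, and its dorsal edge leaves the
phalanx dorsal line at the nail base with exterior dorsal angle θ\*.
Ground-truth landmarks are placed analytically — B at 0.6·`nail_length`
proximal to A on the phalanx line, C at `nail_length` along the nail
edge — so `cfsa()` on the truth reproduces θ\* exactly; θ\* from 140°
to 220° covers all four severity classes. Gray levels (background 0.05,
finger 0.55, nail 0.95) are separated by ≥ 0.15 so that intensity
segmentation is well-posed.

Corruptions mirror common image degradations and are applied in the
fixed order **rotate → blur → salt-and-pepper**: rotation about the
image centre (bilinear for intensities, nearest-neighbour for masks,
exact coordinate transform for landmarks, canvas enlarged so nothing is
clipped), Gaussian blur by separable convolution with a sampled
normalised kernel and mirror boundaries (total intensity conserved),
and impulse noise that flips each pixel with probability `density` to
black or white with equal odds (the split is a convention; equal odds
is the usual choice when unstated). Rotation angles for augmentation
default to ±30° and blur sigmas to 1–2 px; these are ordinary
photographic ranges, not fitted values.

Dataset labels use the grading thresholds with a ±2° exclusion buffer
around each boundary so that no phantom's label depends on sub-degree
measurement error. The buffer empties the moderate band (180 ± 0.5°),
so moderate-class phantoms are generated at exactly 180°.

What the phantoms do **not** emulate: skin texture, specular lighting,
nail translucency, camera perspective, multi-finger scenes, and
anatomical variation beyond the angle itself. Passing the phantom suite
shows the geometry, landmark logic and robustness machinery are
correct; it does not certify performance on clinical photographs, which
additionally depends on the segmenter used.

## Segmentation and the contract seam

The neural detection and segmentation stages of a deployed system are
out of scope as implementations; the package fixes a **segmenter
contract** — any function `image → seg_mask` — and ships a classical
baseline: optional 3×3 median prefilter (on by default; it is the
intended setting whenever impulse noise is expected), a two-threshold
Otsu split into three intensity classes assigned
background/finger/nail by increasing mean intensity, per-class
morphological opening (radius 1) and closing (radius 2), retention of
the largest 8-connected finger component and the largest adjacent nail
component. Opening clips one to two pixels off the nail's sharp base
corner — exactly where the measurement is anchored — so nail-intensity
pixels adjacent to the kept nail component are restored afterwards
(bounded to `open_radius + 1` growth steps). Remaining dropped pixels
join the finger if they touch it, otherwise the background. Connectivity
is 8-neighbour throughout. A mock segmenter in the test suite verifies
that any contract-conforming callable can replace the baseline.

## Landmark extraction

No published procedure exists for locating A, B, C automatically, so
the scheme here is the package's own and is fully parameterised:

1. Align the digit (finger ∪ nail) with its principal axis; the tip
   (+u) is the side holding the nail centroid, the dorsal side (+v)
   the axis side holding the nail centroid (fallback: image-up).
2. For each axis column, record the dorsal-most boundary pixel and its
   class; trim leading/trailing points whose column-to-column dorsal
   jump exceeds 3 px — those sit on the near-vertical end faces of the
   digit, not on the dorsal surface (dorsal slopes of interest stay
   below tan 63° ≈ 2).
3. Smooth the contour with a 5-point moving average.
4. A = proximal-most nail-tagged point; C = the nail point at arc
   distance `nail_span_fraction` (default 1.0, the distal end of the
   nail run) from A; B = the finger-tagged point at
   `fold_offset_fraction` (default 0.6) of the nail-run arc length
   proximal to A. Fractions of the nail run, rather than fixed pixel
   offsets, make the scheme scale-invariant across finger sizes.
5. The dorsal reference at A is the contour normal pointing away from
   the finger centroid.

The moving average trades a small corner bias (the smoothed curve cuts
the corner at A by `0.6·tan|θ* − 180°|` px, under 2° of angle error at
the extreme θ\* = 140°/220°) for robustness to single-pixel
boundary noise; window 5 is the default compromise and is
configurable.

## Losses and metrics

The detection and segmentation training objectives are provided as
standalone numerics so they can be verified against elementwise
oracles: Smooth-L1 box regression (quadratic within |d| ≤ 1, linear
beyond, summed), summed Bernoulli cross-entropies for class and
confidence, and their weighted sum (unit weights by default); pixel-
**mean** binary cross-entropy, Dice loss
`1 − 2Σpy/(Σp + Σy)`, and `BCE + λ·Dice` with λ = 1. The mean/sum
asymmetry between the segmentation and detection cross-entropies is
implemented exactly as specified by the respective definitions.
Probabilities are clipped to `[10⁻⁷, 1 − 10⁻⁷]` before logs so
saturated predictions stay finite, and the Dice ratio carries a 10⁻⁷
smoothing term so the all-empty case is 0 by convention.

Evaluation uses a K-class confusion matrix (rows actual, columns
predicted, class order normal/mild/moderate/severe), one-vs-rest
reduction to TP/FP/TN/FN per class, and the four ratios accuracy,
sensitivity, specificity, precision. A zero-denominator metric is
reported as an explicit undefined marker and excluded from macro
averages with the count of contributing classes reported — never
silently coerced to zero. Three published four-class severity matrices
ship as CSV fixtures (`reference_confusion()`); they exercise the
metrics code against integer counting oracles. Their printed headline
percentages are not reproducible from the matrices themselves under
any standard aggregation (the clean matrix's trace/total is 153/176 ≈
86.9%), so the fixtures validate counting, not headline claims.

## Problem sizes and verification scope

The shipped verification uses 10,000 random triangles for the geometry
oracle, a 200-phantom noise-free sweep with θ\* uniform in [140°, 220°]
(target: ≥ 95% of estimates within ±3°, severity exact ≥ 5° from every
boundary), and a 200-phantom balanced set evaluated clean and at 2%
impulse noise (target: micro-accuracy drop ≤ 5 points). These sizes
give stable rates while keeping a full run in minutes on one core;
`scripts/acceptance.R` recomputes all of them from scratch.

## Known limitations

* The baseline segmenter is intensity-based and assumes three separable
  gray populations; it is a stand-in satisfying the contract, not a
  clinical segmenter.
* Landmark extraction assumes a single finger whose nail is visible in
  profile; multi-finger scenes and nail-free masks yield explicit
  failure reports rather than guesses.
* The phantom family varies only the profile angle and pose; estimator
  bias on real nail shapes (curved plates, irregular folds) is not
  bounded by the phantom results.
* 3-D curvature measures (Schamroth window, phalangeal depth ratio) are
  out of scope.
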