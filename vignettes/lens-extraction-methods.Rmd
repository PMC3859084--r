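---
title: "Extracting eyeglasses lens contours by Fourier shape morphing and Monte Carlo matching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting eyeglasses lens contours by Fourier shape morphing and Monte Carlo matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lenstrace)
```

## The problem

Optometric centering requires several morphological measurements of a
patient wearing their frames: the *bridge* (horizontal gap between the
rims), each lens's *boxing size* (bounding-box width and height) and the
*fitting height* (vertical distance from the lens bottom to the pupil).
All of them follow directly from the closed contours of the two lenses
in a frontal facial image, so the computational problem is accurate lens
contour extraction. The difficulty is that rim shapes are too varied for
a low-dimensional parametric curve family, while the image evidence — an
edge map around the eyes — is cluttered by eyebrows, reflections and
gaps in the rim edges.

## Shape model

A closed contour with points $(x_i, y_i)$, $i = 0,\dots,N-1$, is treated
as the complex sequence $z_i = x_i + j\,y_i$ and represented by its
discrete Fourier coefficients

$$c(k) = \sum_{i=0}^{N-1} z_i \, e^{-j 2\pi k i / N}.$$

Low-frequency coefficients carry the coarse outline; higher ones add
detail. Two coefficients have a direct reading: $c(0)$ is $N$ times the
centroid (the only position-dependent term) and $|c(1)|$ scales linearly
with the shape. Dropping $c(0)$ and dividing by $|c(1)|$ therefore
yields translation- and scale-invariant descriptors. Phases are left
untouched: rims are matched in image orientation, so no rotation or
start-point normalization is applied.

Fourteen normalized coefficients describe rim outlines accurately. The
package truncates the raw transform to the fifteen lowest-frequency
terms $k \in \{0, \pm1, \dots, \pm7\}$; normalization removes $k = 0$,
leaving the fourteen shape-carrying terms $\{\pm1,\dots,\pm7\}$. A
symmetric index set has the practical benefit that horizontal mirroring
— $c(k) \mapsto -\overline{c(-k)}$, used to derive the right rim from
the left — is closed on the retained frequencies.

New shapes are generated by **morphing**: because a linear combination
of Fourier series is again a Fourier series, the coefficient-wise blend
$C_m = \beta C_{s1} + (1-\beta) C_{s2}$, $\beta \in [0,1]$, interpolates
two rim shapes continuously. Morphing is restricted to shapes of the
same class so that intermediates remain realistic rims. A candidate rim
pair is thus fully described by the vector (class, centroid, size,
reference pair $\{S_1, S_2\}$, $\beta$); the right rim is the mirrored
left shape with its own horizontal position.

## Shape database

The built-in database holds 42 normalized left-rim descriptor sets in
three classes: `rectangular_symmetric` (superellipses with exponents
3.5–7 and aspect ratios 1.25–1.7), `elliptic_symmetric` (exponents
1.7–2.4) and `asymmetric` (moderate exponents with a bottom-heavy
fullness term and shear, emulating aviator-like rims). The families are
swept over deterministic parameter grids, and every entry — and every
same-class morph of entries — reconstructs as a simple closed curve,
which the test suite verifies exhaustively.

All database contours are resampled to $N = 64$ arc-length-equidistant
points and canonicalized (clockwise on screen, starting at the rightmost
vertex) before the transform. Resampling makes all descriptor sets share
one frequency index set, which coefficient-wise morphing requires;
canonicalization aligns the boundary parameterizations so a morph blends
corresponding boundary regions rather than phase-shifted ones.

The package also ships the three published per-class sample coefficient
lists verbatim (`published_rim_fixtures()`). Their frequency assignment is not
stated in the source; no assignment we tried reconstructs a simple
closed curve, so these fixtures serve serialization and flip tests only
and are excluded from the morphable pool.

## Matching score

Candidates are scored against the Euclidean distance transform
$DT(x,y)$ of a Canny edge map of the search region: the score of a rim
contour $\vartheta$ is the mean distance over its rasterized boundary
pixels,

$$\mathrm{score}(\vartheta) = \frac{1}{|\vartheta|}
  \sum_{(x,y)\in\vartheta} DT(x,y),$$

and a rim pair scores the average of its two rims. The transform is
zero exactly on edge pixels, so **lower is better**: a contour lying on
the true rim edges scores near zero, and the score grows linearly as a
candidate drifts away. The boundary is rasterized 8-connectedly from 64
reconstructed points; pixels clipped at the field border contribute the
border value.

Scoring alone cannot distinguish the rims from eyebrow or reflection
edges, so every candidate must also pass geometric plausibility checks
before scoring: each eye center strictly inside its rim; each lens
centroid within a quarter of the interpupillary distance (IPD) of its
eye center; each lens bounding box strictly larger than its eye
rectangle; the lens verticals confined to the facial-fifths bands (the
neoclassical canon divides the face into five equal vertical bands with
the intercanthal gap as the middle fifth — the left lens may span bands
1–3, the right bands 3–5); and both rims inside the search region.

## The pipeline

1. **Eye localization.** Any single-eye candidate detector can be
   plugged in; its rectangles go through the grouping rules: discard
   candidates without an opposite-side partner at similar height, split
   into left/right groups about the joint center, merge overlapping
   zones into enclosing rectangles, and take centers as zone centroids
   with an eye size midway between the smallest and the mean zone. An
   inter-eye slope above 10° aborts (such images are unusable for
   measurement). The package ships a dark-blob template detector for
   synthetic scenes and accepts externally supplied pupil positions;
   the pairing tolerance accepts slopes up to twice the tilt gate so
   that the gate, not the pairing, decides tilted cases.
2. **Search region.** A rectangle centered on the inter-eye midpoint,
   $(1+\delta)\,\mathrm{IPD}$ wide and $\delta\,\mathrm{IPD}$ high with
   $\delta = 1.5$ — large enough for oversized frames, small enough to
   bound the search.
3. **Monte Carlo sampling** (per class): centroids uniform in a box of
   half-width $0.25\,\mathrm{IPD}$ around each eye center, size uniform
   in $[0.35, 0.70]\,\mathrm{IPD}$, uniform $\beta$ and a uniformly
   drawn same-class reference pair. Valid candidates are scored in
   batch.
4. **Clustering.** Agglomerative merging of hypothesis bounding boxes:
   the pair with the largest mutual overlap fraction (intersection over
   the smaller box) merges while that fraction is at least
   $\alpha = 0.90$. A cluster scores the *mean* of its members, which
   suppresses lone false positives: a lucky decoy sits in a cluster
   dragged down by its poor neighbors, while the true rim's cluster is
   uniformly good. The best member of the best cluster seeds the next
   stage.
5. **Random-walk refinement.** Hill climbing that perturbs one
   dimension at a time — left centroid, right centroid, size or $\beta$
   — with a Gaussian proposal, keeping only proposals that stay valid
   and strictly lower the score. $\beta$ is clamped to $[0,1]$; the
   reference pair is never re-drawn.
6. **Class selection.** Steps 3–5 run once per class; the class with
   the lowest refined score wins. A best score above
   `pipeline.reject_score` (5 px mean edge distance) signals an
   extraction failure, e.g. rimless frames with no usable edges.

## Parameters

| key | default | meaning |
|---|---|---|
| `roi.delta` | 1.5 | ROI size relative to IPD |
| `descriptors` | 14 | normalized coefficients per shape |
| `search.max_hypotheses` | 4000 | Monte Carlo draws per class |
| `search.alpha` | 0.90 | cluster merge overlap threshold |
| `search.centroid_box_ipd` | 0.25 | centroid sampling half-width (× IPD) |
| `search.size_min_ipd`, `search.size_max_ipd` | 0.35, 0.70 | lens size bounds (× IPD) |
| `refine.max_iterations` | 150 | random-walk proposals |
| `refine.sigma_pos_ipd`, `refine.sigma_size_ipd` | 0.02 | proposal sd (× IPD) |
| `refine.sigma_beta` | 0.05 | proposal sd for β |
| `canny.sigma` | 1.4 | blur before gradients (px) |
| `canny.low`, `canny.high` | NA | hysteresis thresholds; NA → Otsu-derived high, low = high/2 |
| `eyes.max_tilt_deg` | 10 | inter-eye slope gate |
| `pipeline.reject_score` | 5 | failure threshold (px) |
| `gamma` | 0.95 | true-positive overlap criterion |

Two defaults deserve comment. The published heuristics for this family
of pipelines are roughly 2000 samples per class and 30 refinement
iterations, on the premise that sampling already lands very close to
the optimum. In this implementation the premise does not hold: near the
optimum the score landscape is nearly flat (see the next section for
why), so single-dimension proposals accept rarely and recovery keeps
improving well past those values. The defaults 4000/150 were fixed once
from a parameter sweep at the point where clean-scene recovery
saturates, at about 2.5 s per 800×600 scene on one core; both smaller
published values remain one config key away.

## The synthetic scene generator

No public imagery with ground-truth lens contours exists, so the
package generates its own study conditions: 800×600 frontal "portraits"
with an IPD of 180–220 px, two dark elliptical eye blobs, anti-aliased
2 px rim strokes rendered from a morphed database shape (the right rim
the mirrored left), optional eyebrow arcs, a nose line, specular blobs
and an off-face decoy contour, contiguous boundary gaps erasing a set
fraction of each rim, and Gaussian intensity noise (σ = 4 by default).
Lens size is drawn from $[0.38, 0.46]\,\mathrm{IPD}$ and lens centroids
within $0.08\,\mathrm{IPD}$ of the eye centers — comfortably inside the
search bounds, and sized so the rims never collide. Scenes are pure
functions of their spec (bit-identical re-renders), and the generator
returns the exact rendered contours as ground truth.

One rendering consequence matters for interpretation: Canny localizes
the two *flanks* of a 2 px stroke, two edge chains about ±1.2 px from
the stroke centerline, rather than the centerline itself. The truth
contour therefore scores ≈1.0–1.3 px (not 0) against its own scene, the
global score optimum lies on one of the flanking chains, and the score
landscape between the chains is flat — the reason refinement needs more
iterations than the published heuristic, and a ~±1 px bias floor on any
recovered contour. The γ-criterion (detected interior covering ≥95% of
the truth interior) tolerates this floor at realistic lens sizes.

What the generator does *not* emulate: skin texture and shading,
specular highlights on the lens surface between edges, hair occlusion,
rimless and semi-rimless frames, perspective and pose variation beyond
a ≤2% eye-line tilt. Passing the synthetic benchmarks therefore
demonstrates correct and robust implementation of the model and search
machinery under controlled clutter — not field performance on
photographs, which the private imagery this method targets would
require.

## Evaluation

A detection on a synthetic scene counts as a true positive when, for
*both* lenses, the detected interior covers at least γ = 0.95 of the
truth interior (the fraction divides by the truth area only; the test
suite also tracks intersection-over-union, which unlike the coverage
fraction penalizes oversized detections — relevant when judging
refinement improvements, since a slightly oversized start already
covers the truth area completely). Three seeded batteries are packaged:
`clean` (no clutter or gaps), `cluttered` (eyebrows, nose line, 20%
boundary gaps) and `decoy` (clean plus an off-face closed contour).
`run_benchmark()` reports per-scene overlaps, the TP rate at γ, the
class identification rate and runtimes; `scripts/acceptance.R`
recomputes all headline quantities from scratch.

## Numerical choices and edge cases

* Truncation keeps the lowest-|k| frequencies, ties favoring $+k$;
  reconstruction treats missing frequencies as zero.
* `size` on a hypothesis is in pixels on the first-harmonic-radius
  scale (a circular rim of radius $r$ px has size $r$); internally the
  raw $|c(1)|$ equals $N \times$ size.
* Normalization divides by the scalar $|c(1)|$, never the complex
  value, preserving orientation.
* Scoring deduplicates rasterized pixels, so $|\vartheta|$ is the count
  of distinct boundary pixels; clipped pixels take the border distance.
* Cluster merging breaks ties toward the earliest pair in input order;
  selection breaks ties toward the earliest cluster and the earliest
  generation index — the whole pipeline is deterministic given the
  seed.
* Degenerate inputs fail loudly: contours need ≥3 finite points,
  normalization refuses $|c(1)| = 0$, the distance transform refuses
  empty edge maps, bridge computation refuses horizontally overlapping
  rims (the tool then reports the contours without measurements).

## Known limitations

* The ±1 px localization floor from stroke-flank edges caps achievable
  overlap at roughly 97–99% for typical lens sizes; γ above ~0.97 would
  not be attainable on the packaged scenes.
* Shape recovery is limited to the morph span of the database classes;
  a rim outside all three families is approximated by the nearest
  morph.
* The score uses edge proximity only — no gradient orientation or
  intensity terms — so dense parallel clutter (e.g. a thick eyebrow
  hugging the rim top) can bias the fit locally.
* Frontal geometry is assumed throughout; vertex distance and wrap
  angle need non-frontal views and are out of scope, as is
  pixel-to-millimeter device calibration (a user-supplied scale factor
  converts measurements to mm).
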