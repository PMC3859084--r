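# lenstrace

Extracts the closed contours of eyeglasses lenses from frontal facial
images and derives the optometric frame measurements from them: the
**bridge** (horizontal gap between the rims), each lens's **boxing
size** (bounding-box width × height) and the **fitting height**
(vertical distance from the lens bottom to the pupil). It is written
for optometric measurement workflows — where these quantities feed lens
centering — and, more broadly, for anyone fitting a flexible family of
closed shapes to noisy edge data: the machinery generalizes to any
object whose outline can be covered by a database of representative
shapes.

## Method

A closed contour with points $z_i = x_i + j\,y_i$ is represented by its
Fourier descriptors

$$c(k) = \sum_{i=0}^{N-1} z_i\,e^{-j2\pi ki/N},$$

truncated to the lowest frequencies: 14 coefficients after dropping
$c(0)$ (the centroid term) and dividing by $|c(1)|$ (the size term),
which makes the descriptors translation- and scale-invariant. New rim
shapes are generated by **morphing** — the coefficient-wise blend
$C_m = \beta C_{s1} + (1-\beta)C_{s2}$ of two same-class database
shapes — so a candidate rim pair is just the vector (class, centroid,
size, $\{S_1,S_2\}$, $\beta$), the right rim being the horizontal
mirror of the left.

Candidates are fitted to an image in stages: eye localization fixes a
search region scaled by the interpupillary distance; a Canny edge map
and its Euclidean distance transform $DT$ turn fit quality into the
chamfer-style score $\frac{1}{|\vartheta|}\sum_{(x,y)\in\vartheta}
DT(x,y)$ over the rasterized boundary (lower is better); uniform Monte
Carlo sampling scores thousands of geometrically validated candidates
per shape class; agglomerative clustering by bounding-box overlap
suppresses lucky false positives (clusters score the *mean* of their
members); and a random-walk hill climb fine-tunes position, size and
morph factor one dimension at a time. The best class wins.

A seeded synthetic scene generator renders facial scenes with exact
ground-truth contours (eye blobs, anti-aliased rim strokes, eyebrow
clutter, boundary gaps, noise, decoy contours), which supplies all
benchmark and test data. See the methods vignette
(`vignettes/lens-extraction-methods.Rmd`) for the model, parameters and
design choices in full.

## Worked example

```r
library(lenstrace)

db    <- builtin_database()                       # 42 rim shapes, 3 classes
spec  <- random_scene_spec(db, cls = "elliptic_symmetric", seed = 7)
scene <- generate_scene(spec, db)                 # image + ground truth

res <- extract_lenses(scene$image, db, lens_config(seed = 42))
res
#> <extraction_result: class elliptic_symmetric, score 1.018 px, ipd 220.0 px>

measure_glasses(res, scale_mm_per_px = 0.35)
#> <glasses_measurements (px): bridge 35.8, boxing L 195.2 x 153.3,
#>  R 195.2 x 153.3, fitting L 94.7, R 96.7>

overlap_fraction(res$left_contour, scene$truth$left)
#> [1] 0.986
```

The extraction result reports the winning shape class, the mean
edge-distance score of the fitted pair (1.018 px here — the fitted
boundary sits about one pixel from the nearest image edges, the
localization floor for 2 px rim strokes), and the detected
interpupillary distance. The measurements are read directly off the
fitted contours, in pixels and (given a scale factor) millimeters, and
the fitted left lens covers 98.6% of the true lens interior.

The same pipeline is scriptable from a shell via
`inst/cli/lenstrace.R` (`extract`, `benchmark`, `gen-scene`
subcommands), writing result JSON, an overlay PNG and a log.

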