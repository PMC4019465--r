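---
title: "Quantifying cell proportionality: the shape-factor pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cell proportionality: the shape-factor pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stentorshape)
```

## The measurement problem

*Stentor coeruleus* is a giant unicellular ciliate with a striking
trumpet ("wine-glass") shape: a broad anterior ring of cilia — the oral
apparatus (OA) — tapering to a narrow posterior holdfast. Perturbations
of polarity regulators (for instance knocking down the kinase cofactor
Mob1 by RNAi) make cells lose this proportionality and become nearly
cylindrical. To turn that qualitative impression into a statistic, each
cell silhouette is reduced to a one-dimensional width profile —
perpendicular chord width sampled along the cell's midline — and the
profile is summarised by a single unit-less **shape factor**.

Let $w(s)$ be the full cell width at arc position $s$ along the midline.
The widest station is taken to be the OA; the station farthest from it
in arc length is the tail. Writing $s_t, s_o$ for their positions,

$$
\mathrm{SF} \;=\;
\frac{\int_{s_t}^{s_o} w(s)\,\mathrm{d}s}
     {\tfrac12\,\bigl(w(s_t)+w(s_o)\bigr)\,\lvert s_o-s_t\rvert },
$$

with the numerator evaluated by the trapezoidal rule over the measured
stations. The denominator is the area of the right trapezoid obtained by
joining the tail and OA widths with a straight line; when the tail width
is zero it degenerates to a right triangle. A cell with perfectly
straight sides — a right cone, or the constant-width cylinder as its
special case — has $\mathrm{SF}=1$ exactly; a concave, wine-glass taper
gives $\mathrm{SF}<1$; a convex mid-body bulge gives $\mathrm{SF}>1$.
Loss of tapering therefore appears as an *increase* of the shape factor
toward 1. Because it is a ratio of areas, the statistic is invariant to
image scale, to pixel size, and to whether widths are recorded as full
or half chords.

## Pipeline stages

`analyze_cell()` composes the whole chain; each stage is exported on its
own.

1. **Binarization** (`binarize`): a global threshold by the iterative
   intermeans (IsoData) rule — the threshold is repeatedly replaced by
   the mean of the two class means it induces. The cell is the
   *border-minority* side of the threshold by default: with one cell per
   image, the class dominating the image border is the background,
   whichever polarity the optics produced. (`"smaller"`, `"bright"` and
   `"dark"` are available when that assumption does not hold.)
2. **Binary smoothing** (`smooth_binary`, default 2 rounds): each round
   applies a 3×3 mean filter to the {0, 255} mask with replicate-border
   padding and re-thresholds at ≥ 128. This removes isolated specks and
   fills single-pixel notches while leaving large convex bodies
   essentially unchanged.
3. **Component cleaning** (`clean_mask`): keep the largest 8-connected
   component, fill all holes, warn if the cell touches the border.
4. **Outline** (`trace_outline`): the 0.5-level marching-squares
   isocontour of the mask — a subpixel closed polygon running midway
   between foreground and background pixel centres.
5. **Midline** (`extract_midline`): Zhang–Suen thinning to a one-pixel
   skeleton; the skeleton pixel graph's weighted diameter is the axis
   (side branches are pruned); terminal branches are trimmed back to the
   last junction within 2.2 × the inscribed half-width of each end
   (near a flat end the medial axis forks into the corners, and the
   longest geodesic would otherwise terminate in a corner); a cubic
   smoothing spline of $x(s)$ and $y(s)$ is fitted; both ends are
   extended linearly along their tangents to the outline so the midline
   spans the whole cell.
6. **Width profile** (`measure_widths`): stations every 10 px of arc
   (plus the far endpoint); at each station the line perpendicular to
   the local tangent is intersected with the outline and the distance
   between the nearest intersection on each side is the full width.
   Stations whose perpendicular cannot cross both sides are dropped and
   logged.
7. **Normalization** (`normalize_profile`): positions are rescaled to
   $x = s/L \in [0,1]$ and the profile is oriented so the widest station
   falls in the upper half — tail at 0, OA at 1.
8. **Shape factor** (`compute_shape_factor`) as defined above, plus
   cohort-level aggregation (`trend_curve`, `compare_groups`) and the
   end-to-end driver (`run_pipeline`).

## Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `step_px` | 10 | px | arc spacing of width stations |
| `smooth_rounds` | 2 | – | rounds of 3×3 mean-filter mask smoothing |
| `spline_df` | `clamp(L/40, 4, 25)` | – | midline spline flexibility |
| `pixel_size` | 1 | physical/px | scalar calibration applied to outputs |
| `test` | `"welch"` | – | group test (`"student"` optional) |

The 10 px station spacing matches the measurement protocol the statistic
was defined with; at the 300–1500 px cell lengths the pipeline targets
this yields 30–150 stations per cell, ample for a trapezoidal integral.
The spline default makes stiffness proportional to midline length so
that straight cells stay straight while gently curved cells can follow
their arc. No magnification is assumed anywhere; `pixel_size` only
rescales lengths and widths in tabulated outputs, and the shape factor
is unaffected by it.

Welch's unequal-variance *t* is the default group comparison because
control and perturbed cohorts typically differ severalfold in variance;
the pooled Student form is one configuration switch away.

## The synthetic generator and its ground truth

`render_silhouette()` sweeps a parametric width profile perpendicular to
a straight or constant-curvature axis and rasterizes the result over
0-based pixel centres, so the true midline, the true width at every
station and the analytic shape factor are known exactly. Profile
families cover the cases the statistic is designed to separate: `cone`
($w = x$), `cylinder` ($w = 1$), `power_taper` ($w = x^p$, analytic
$\mathrm{SF} = 2/(p+1)$), `wineglass` (a concave taper flaring from a
positive stem width), `bulge` (analytic $\mathrm{SF} = 1 + b/3 > 1$) and
`custom`. Noise is layered on top: smooth per-side boundary jitter,
isolated speckle, punched holes and an illumination ramp — the failure
modes thresholded brightfield images actually show. `make_cohort()`
draws per-cell parameter jitter reproducibly from one master seed.

Rendering conventions that matter:

* **Half-open sampling.** A straight cell of length $L$ and width $w$
  covers exactly $L \times w$ pixel centres, so mask areas equal the
  swept-profile integral up to rasterization of the tapered end.
* **Grid alignment.** Axis-aligned straight cells are laid on a
  pixel-centre row. Idealized profiles like $w = x^p$ have
  sub-pixel-thin tails that no physical cell has; off-grid placement
  would alias them away, breaking the correspondence between the
  rendered object and its analytic ground truth.
* **End caps.** The OA end is capped flat. The tail carries a
  semicircular cap only when it is narrow (holdfast-like,
  $w(0) \le 0.3\,w_{\max}$); a wide untapered tail (a cylinder) is
  capped flat, which keeps the cylinder an exact rectangle.
* **Silhouette-level oracle.** When a rounded cap is rendered, the
  cell's true farthest-from-OA point is the cap tip, whose width tends
  to zero; `truth$analytic_sf` is therefore computed for the full
  rendered silhouette (cap included), while `truth$profile_sf` keeps the
  bare-profile value. The two coincide whenever no cap is rendered.

What the generator does **not** emulate: brightfield halos and defocus,
cilia, internal organelles, multi-cell scenes, and the multipolar
"medusoid" morphology of severe knockdowns. Passing tests therefore
demonstrate the geometry chain is correct on clean, single, roughly
convex elongated silhouettes — not that segmentation of difficult real
micrographs is solved.

## Numerical choices and degenerate cases

* **Landmark ties.** Raster widths are quantized to about half a pixel,
  so all stations within 0.5 px of the maximum are treated as tied for
  widest; the tie is resolved toward the largest tail–OA span.
  Anatomically the OA sits at the anterior extreme; for a constant
  profile the rule reduces to "OA at one end, tail at the other", which
  provably leaves the shape factor of a constant profile at 1.
* **"Farthest" is arc length.** The tail is the station farthest from
  the OA *along the midline*, not in the image plane; for straight
  cells the two coincide, and the along-axis choice is the one
  consistent with the 1-D profile the statistic integrates.
* **Terminal stations.** The stations at $s = 0$ and $s = L$ sit on the
  outline itself, where the perpendicular chord is degenerate. They are
  evaluated a quarter pixel inside; on each side the farthest
  intersection within 0.75 × the neighbouring station's width is used
  (reading through the corrugations of a noisy end wall), and a chord
  that terminates on a contour edge nearly parallel to itself (within
  about 10°) is discarded as an end-cap artifact.
* **Multiple intersections** on one side of a concave outline: the
  intersection nearest the midline is used — the local width, robust to
  folds.
* **Skeleton pathologies.** Noise can close small loops in the thinned
  skeleton; path terminals are chosen by the weighted graph diameter
  over all vertices, not only leaves, so looped arms remain reachable.
  A skeleton with no free endpoint at all (a pure cycle) is an error.
* **Integration domain.** The integral uses absolute arc positions; the
  ratio is invariant to normalizing them (verified in the tests).

## Smoothing and sub-pixel tails

The 3×3 mean filter with a ≥ 128 re-threshold provably erodes foreground
thinner than about 3 px. Real cells are safely wider than that
everywhere, but the idealized zero-width-tail families ($w = x^p$) lose
their tail region under smoothing, which truncates the integration
domain and biases the shape factor upward (for $p = 2$ at 600 px the
truncation alone moves 0.667 to about 0.75). Denoising has no function
on noise-free synthetic renders, so validation against the analytic
oracle is run with `smooth_rounds = 0`; the cone and cylinder limits are
insensitive to truncation (any straight-sided profile integrates to its
own trapezoid) and are validated through the full default pipeline,
smoothing included. On real images the default of two rounds stands.

## Problem sizes used by the test-suite

Reference silhouettes are 600 × 120 px (with 480 × 96 and 360 × 72
variants in the oracle-equivalence sweep, and 0.5×/2× rescales in the
invariance suite); synthetic cohorts use n = 15 cells of 400 × 80 px
with 1 px boundary jitter, matching the cohort sizes the statistic is
typically reported for; pipeline integration tests use 300 × 60 px
cells. These sizes sit inside the 300–1500 px range of real binarized
cells at typical magnifications.

## Known limitations

* **Strong curvature.** Midline recovery is accurate for bends up to
  roughly 30°; at 60° of total bend the midline shortens by a few
  percent and the shape factor drifts low by several hundredths. Cells
  curved that strongly are better excluded, as they would be in manual
  analysis.
* **Small rounded caps.** For cells a few hundred pixels long whose tail
  cap is under ~10 px, the degenerate tip chord costs the shape factor
  up to about 5% relative to the continuous-silhouette oracle; at the
  600 px reference size the error is within 2%.
* **One cell per image.** Scene segmentation, touching cells and
  time-lapse tracking are out of scope.
* The widest-point proxy for the OA is a geometric definition; no
  attempt is made to recognise the membranellar band by texture.
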