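---
title: "Quantifying pelleted and dispersed fungal growth from culture images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pelleted and dispersed fungal growth from culture images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pelletmorph)
```

## The measurement problem

Submerged cultures of filamentous fungi are morphologically heterogeneous:
the same flask contains millimetre-scale pellets, loose clumps and free
dispersed hyphae, and the balance between these forms governs mass
transfer, rheology and product secretion. `pelletmorph` quantifies this
heterogeneity from ordinary photographs of culture samples taken with
light-coloured fungal material on a dark background. The pipeline is: read
every image under an input tree, condition it to a binary foreground mask,
capture connected particles, measure calibrated shape descriptors per
particle, classify each particle by area, and report per-directory CSVs, a
pooled pelleted-fraction statistic and indexed quality-control overlays.

## Descriptors and the morphology number

For a particle with foreground pixel count $N$ and calibration $u$
(µm/pixel):

* **Area** $A = N u^2$. Interior holes are not filled and not counted: the
  conditioning chain has no hole-filling step, so area means observed
  foreground.
* **Feret diameters.** The particle outline is traced along pixel edges
  (pixel-corner convention, below); the convex hull of its vertices is
  taken, the maximum caliper diameter found by a rotating-calipers
  antipodal sweep, and the minimum caliper width as the smallest projection
  width over hull-edge orientations. Both scale by $u$.
* **Aspect ratio** $AR = F_{max}/F_{min} \ge 1$. This is the caliper-based
  definition, not a fitted-ellipse axis ratio; the two differ for concave
  particles and the caliper form matches the "maximum diameter over minimum
  diameter" reading used for pellet circularity.
* **Solidity** $S = A / A_{hull}$, with $A_{hull}$ the shoelace area of the
  hull polygon. Convex smooth particles give $S \approx 1$; surface
  irregularity drives $S$ toward 0. The opposite ratio (hull over observed)
  would grow without bound for irregular particles and contradict the
  stated behaviour of the measure, so the bounded form is used.
* **Morphology number**
  $$\mathrm{MN} = \frac{2\sqrt{A}\,S}{\sqrt{\pi}\,F_{max}\,AR},$$
  a dimensionless composite equal to 1 for an ideal circle (substituting
  $A=\pi r^2$, $S=1$, $F_{max}=2r$, $AR=1$ cancels every term) and tending
  to 0 for a vanishing-width line. MN is reported unclamped: pixelation can
  push it marginally above 1 and truncating would hide that.

## Classification and the pelleted fraction

Classification is a pure threshold rule on calibrated area, with both lower
bounds inclusive: pellet at $A \ge 500$ µm², dispersed at
$95 \le A < 500$ µm², artefact below 95 µm². The defaults suit roughly
10× magnification; at 50× a dispersed lower bound of 20 µm² resolves small
hyphal fragments. Because the rule acts on calibrated area, the same pixel
scene photographed at different magnification can legitimately classify
differently — that is the intended behaviour, not an inconsistency.
Artefacts are removed from every table and total; only their count and
summed area are logged.

The per-directory heterogeneity readout pools areas across all images of
the directory:
$$\text{pelleted fraction} = 100 \times
  \frac{\sum A_{pellet}}{\sum A_{pellet} + \sum A_{dispersed}}.$$
Pooling (rather than averaging per-image percentages) makes the statistic
invariant to how the culture was split across photographs; the test suite
asserts this splitting invariance. Artefact area is excluded from the
denominator, consistent with artefacts being removed from all analyses. A
directory with no fungal area reports a missing value with a warning.

## Image conditioning

* **Contrast enhancement.** "Enhance by 5%" is implemented as a symmetric
  percentile stretch: intensities are linearly rescaled so 2.5% of pixels
  clip at each end. Percentiles come from the exact 256-bin histogram and
  the mapping is applied through a lookup table, so the operation is O(n)
  and integer-exact. When the foreground covers less than half the
  saturation allowance (very sparse fields), both percentiles collapse
  onto the background mode; the stretch then falls back to min–max, which
  preserves separability instead of amplifying background noise. A truly
  constant image is returned unchanged with a warning.
* **Red channel.** The RGB image is reduced to its red channel exactly;
  on light-on-dark culture photographs red carries the fungal signal with
  the least background texture.
* **Thresholding.** Default is the per-image isodata (iterative intermeans)
  rule: the cutoff is the fixed point
  $\tau = (\mu_{\le\tau} + \mu_{>\tau})/2$ on the 256-bin histogram.
  A fixed global cutoff can be pinned instead to reproduce a hand-selected
  standard threshold; the published grey value is not recoverable, so both
  modes exist. Comparison is strict: a pixel equal to the cutoff is
  background. Foreground always means fungal material — the mask polarity
  is normalised here once, so no downstream step inverts anything.

## Segmentation conventions

* **Connectivity** defaults to 8, matching the common particle-analyser
  behaviour; 4 is available for study. A compiled flood-fill labeller
  assigns indices 1..N in raster-scan order of each component's first
  pixel, so numbering is reproducible and identical between CSV rows and
  overlay labels. The labeller is validated against a naive BFS oracle on
  randomized masks for both connectivities.
* **Outlines** follow the pixel-corner convention: pixel $(r, c)$ spans the
  unit square $[c-1,c]\times[r-1,r]$, so a single pixel has polygon area 1
  and Feret $\sqrt2$, and outline area equals pixel count for hole-free
  particles. At a diagonal self-touch the boundary walk takes the left
  turn, which wraps the loop around the background corner it is following;
  this keeps one outer loop per particle under either connectivity.
* **Border policy.** By default every particle touching the first or last
  row or column is excluded — partially captured structures would bias all
  descriptors low. The published behaviour is only stated for pelleted and
  clumped forms, and its extension to dispersed fragments is ambiguous, so
  a `keep_all` policy is provided and the exclusion count is logged per
  run. Exclusion never renumbers survivors.

## The synthetic generator

Every test runs against generated scenes, not stored images. Shapes (disc,
ellipse, rectangle, cross, blob) are rasterized by a pixel-centre inclusion
test against the analytic geometry — simple, unbiased and convergent — onto
a dark canvas (background 20, foreground 200 by default, mimicking
light-on-dark capture), optionally with seeded additive Gaussian noise.
Disc/ellipse/rectangle/cross truths are closed-form; the concave blob
(union of discs) gets a numeric truth computed at 10× supersampling and is
tagged `derived`. Scene manifests carry each shape's truth and expected
class, and `make_test_tree()` writes nested directory fixtures with
analytic per-directory pelleted fractions.

Default generator conditions: pellets are discs of radius 15–30 µm-scale
pixels (areas ≈ 700–2800 µm² at 1 µm/px), dispersed fragments rectangles
of 12–20 × 10–12 µm (areas 120–240 µm²), specks discs of radius 2–4 µm
(< 55 µm²). The dispersed range deliberately keeps a margin of a few
pixels' worth of area from both class boundaries so that rasterization
cannot flip a class; boundary behaviour itself is tested directly on exact
areas, which is the right instrument for it. The standard validation scene
holds 3 pellets, 5 dispersed fragments, 2 specks and one border-straddling
disc on a 512×512 canvas.

What the generator does not emulate: hyphal texture, optical blur,
illumination gradients, touching pellets and out-of-focus material. Passing
tests therefore demonstrate correct geometry, classification, accounting
and reproducibility — not robustness to optical artefacts of real
micrographs, which is what the QC overlay workflow is for.

## Numerical behaviour and known biases

Rasterized measurements converge to analytic truth as particles grow, but
the pixel-corner convention has a known systematic at the scale of one
pixel: hull vertices sit up to half a pixel outside the true boundary, so
a caliper diameter overshoots by about one pixel ($\approx 1.2/2r$
relative for a disc of radius $r$) and the hull area is inflated by a
half-pixel band, depressing solidity by $\approx (1+0.4/r)^{-2}$. MN
compounds the solidity, Feret and aspect-ratio terms, giving a relative
bias of roughly $-1.5/r$: about $-6\%$ at $r=30$ px, $-1.5\%$ at
$r=150$ px, $-0.8\%$ at $r=300$ px. Area is essentially unbiased
(boundary fluctuations cancel in expectation). The test suite asserts the
measured envelopes: area and Feret within 0.5% at $r = 150$; MN within 2%
at that radius, since a 0.5% MN claim is not attainable under these
conventions at that size. Dimensionless descriptors are exactly invariant
to calibration (the same pixel set measured at 1 vs 2 µm/px yields
identical AR, solidity and MN to the last bit), and descriptors of an
80/40-pixel ellipse vary by under 3% across rotations.

Problem sizes used by the test suite: oracle equivalence runs 100 random
convex hulls (up to 200 vertices) and 100 random masks up to 32×32 in both
connectivities; the throughput check renders and analyses 200 images of
1024×1024 — one user-day of captures — through the complete workflow, which
finishes in a few minutes on a single CPU.

## Quality control and correlation utilities

For every raw image the pipeline writes one overlay per analysed class,
drawing each reported particle's boundary pixels in red with its index
stamped at the centroid from a built-in bitmap digit font (no graphics
device involved, so overlays are byte-reproducible). Indices match the
ascending `raw_data.csv` rows, so a wrong call spotted by eye can be named
as an (image, index) pair; `run_pipeline(qc_flags = ...)` (or
`drop_flagged()` directly) removes exactly those calls and recomputes every
table and total, erroring on unknown references rather than ignoring them.
In practice roughly 1% of calls need manual removal on real cultures.

`linear_fit_r2()` is a small ordinary-least-squares utility (slope,
intercept, $R^2$) for correlating morphology summaries — mean pellet
diameter, MN, pelleted fraction — against external scalar measurements such
as biomass or secreted protein. Degenerate inputs are explicit: constant
$x$ is an error, constant $y$ reports $R^2 = 0$ with a warning.

## Limitations

* Mycelial rafts and other composite structures are not detected as such;
  they classify purely by area.
* Touching pellets are not split (the capture protocol separates pellets
  physically before imaging); no watershed step is included.
* Hyphal tip number is not measured; solidity is intended as the
  first-line surface-integrity screen at low magnification.
* The area cut-offs are magnification-dependent by design: recalibrate
  them when changing optics, as the 50× profile (20 µm² dispersed bound)
  illustrates.
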