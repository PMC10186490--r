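---
title: "Methods: layer-wise printing accuracy assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: layer-wise printing accuracy assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(printfid)
```

# The measurement problem

A printed food layer should reproduce its digital design. `printfid`
quantifies the mismatch from a single top-view photograph by comparing two
binary rasters on a metric reference frame: the digital layer image **G**
rendered from the G-code, and the segmented print **P** extracted from the
photograph. All accuracy metrics — infill %, over-/under-extrusion %, and
the localization heatmap — are pixel counts on these two masks.

# The filament width model

An extrusion move advances the syringe piston by ΔE (mm), expelling a
volume πD²ΔE/4 that is laid over the travelled length X. A soft-paste bead
flattens to a stadium cross-section of height H (a rectangle capped by two
semicircles of diameter H), whose area is WH − H² + πH²/4. Volume
conservation yields the closed form

$$W = \frac{\pi \Delta E D^2}{4 X H} + H\left(1 - \frac{\pi}{4}\right).$$

Below W = H the stadium degenerates, so the width is clamped at H (a round
bead); a move with ΔE > 0 but X = 0 is a blob deposit with undefined width
and is flagged rather than drawn. The model is exact by construction:
`stadium_area(W, H) · X = πD²ΔE/4` to floating-point precision above the
clamp, and the package tests hold it to 1e-9 relative across a parameter
sweep. Widths are strictly increasing in ΔE and decreasing in X, which the
tests also verify.

Two parameters the printer documentation must supply have package defaults
chosen once for a syringe-type food printer with a 1.2 mm nozzle:

* **layer height H = 1.2 mm** (equal to the nozzle bore, the common choice
  when laying soft dough beads that flatten rather than stack tightly);
* **syringe bore D = 30 mm** (a typical food cartridge; D only matters when
  absolute extrusion distances do, e.g. in `width_mode = "model"`).

Digital layer images for visual comparison use a **fixed 1.5 mm line
width** — deliberately wider than the 1.2 mm nozzle because die swell
expands the extruded filament.

# Slicer emulation and the design infill

`generate_design_path()` emulates the sliced block designs
(50 × 25 mm, one perimeter shell, rectilinear or honeycomb infill). The key
modelling decision is that the digital layer image represents *the top view
of the repeating layer stack*, because that is what a top-view photograph
of a multi-layer block shows and what the reference imagery depicts
(crosshatch grids and full hexagons, not single-layer stripes).

* **Line pitch.** Adjacent flattened beads tile at the *extrusion spacing*
  `w_sp = w − H(1 − π/4)`, not at the nominal width w, so an infill density
  d maps to a per-layer centreline pitch `w_sp / d`.
* **Rectilinear** layers alternate 0°/90°, and same-orientation layers
  interleave at half pitch; the visible union is a crosshatch of two
  perpendicular stripe families at pitch `w_sp / (2d)`. The union area is
  exact for perpendicular stripe families:
  `c = 1 − (1 − f)²` with `f = min(1, 2wd/w_sp)`.
* **Honeycomb** layers trace hexagon walls whose pattern cycles through the
  three interlocking offsets natural to a hexagonal lattice. Rather than
  rasterizing three overlapping grids, a single full hexagonal wall grid is
  drawn whose pitch is solved so its exact material fraction
  `1 − (1 − w/pitch)²` equals the three-phase union target
  `1 − (1 − wd/w_sp)³` (independent-overlap approximation). This is an
  emulation of the union's material budget, not a clone of any particular
  slicer's path planner.
* Infill pitches below the line width are clamped to solidity with a
  warning; density 0 emits the shell alone.

With these choices the rendered design infill of the blocks is about 77 %
for rectilinear 20 %, about 89 % for honeycomb 40 %, and above 99 % for
rectilinear 40 % — far above the nominal slicer settings, because the shell
and the finite line width dominate small blocks. These are the reference
values `scripts/acceptance.R` recomputes.

# Rasterization conventions

The frame raster uses half-open pixel indexing with pixel centres at
`(i + 0.5)/scale` mm; printer coordinates are y-up, raster rows are y-down,
and the single flip happens at rasterization. A pixel is foreground when its
centre lies within W/2 of the segment (round caps and joins — extruded
filament ends are rounded, and it makes footprint areas analytic:
`W·X + π(W/2)²` for an isolated segment). Rendering is deterministic, and
the rendered footprint of a generic segment matches the analytic stadium
area to within raster error (≈1–3 % at 10 px/mm). When a band edge falls
*exactly* on a row of pixel centres the binary inclusion is ambiguous by
half a pixel row; the generated designs place lines so edges land on pixel
boundaries, where inclusion is unambiguous.

# Photograph preparation

Marker detection screens pixels in HSV space (hue window 0.20–0.45 with
saturation/value floors, thresholds exposed as arguments), labels connected
components, and takes the four largest blobs' centroids ordered by
quadrant; anything other than exactly four candidates is an error, not a
guess. The four correspondences determine the homography exactly (8-unknown
direct linear solve), and the photo is pulled onto the frame raster with
bilinear interpolation. Otsu's threshold is computed after excluding marker
neighbourhoods; polarity is auto-resolved by taking as object the side with
less border contact; components above a minimum area are all retained
(oozed satellites are genuine material) and internal holes are kept (pores
carry the infill signal).

# Registration and set logic

Registration searches integer shifts only — sub-pixel shifts are
ill-defined on binary masks. The default maximizes the binary
cross-correlation (computed by FFT) within a configurable radius, breaking
ties toward the smaller displacement; the centre-of-mass alternative is
also available and selectable. The defect maps follow the OR/XOR
composition `U = [P|G] ⊕ P`, `O = [P⊕G] ⊕ U`, which the tests pin to
brute-force per-pixel set differences on a thousand random masks, along
with the exact conservation identity `|P| − |G| = |O| − |U|`.

**Denominator convention.** Over- and under-extrusion percentages are both
normalized by the design area |G|, so 0 % means a perfect print and values
are comparable across designs and with each other. This is a convention —
a print-area or frame-area denominator would be defensible — so every
report states it.

# Localization

Defects are localized on g × g pixel grids (default g = 9, matching the
survey grids) with the index `i_over = ΣO_n/(ΣP_n + 1)`; the +1 keeps empty
grids finite. Index lists are normalized by a modified percentile scheme:
values above the 99th percentile q99 map to 1, the rest to
`(i − min I)/(q99 − min I)`. The percentile uses linear interpolation, and
`min(I)` is taken over the full list (not after clipping) — with a
99th-percentile anchor the difference is immaterial and the full-list
minimum is the simpler contract. A constant field normalizes to all zeros
with a warning rather than an error. The displayed heatmap smooths the
normalized field with a Gaussian of σ = 2 grid units (configurable; the
choice is cosmetic smoothing across neighbouring grids, not a fitted
parameter). Note that an over-extrusion blob centred *on* the printing path
shows up as a ring of high-index grids around the designed line — the grid
containing the line itself has a large ΣP — so spatial coverage checks read
the smoothed field, which integrates the ring.

# Survey aggregation

Responses are validated against the survey protocol (ratings 0–100, 3–10
clicks, clicks in bounds) with per-record reason codes. Click heatmaps
count clicks per 9 × 9 px grid (counts conserve clicks exactly) and smooth
with σ = 1.5 grid units by default. The marks/rating association is the
Pearson correlation between per-image total marks and per-image *mean*
rating (mean, not median, matching the per-image treatment of the reference
analyses); a per-response mode is available for sensitivity checks.

# The synthetic fixture generators

`simulate_print()` injects defects in **mask space** so ground truth is
exact: half-width changes via the Euclidean distance transform (exact disk
dilation/erosion), disks at start/stop points, ooze bands along the
stop-to-start travel polylines, then a global integer-pixel shift. The
ledger's O/U masks satisfy O = P∖G and U = G∖P by construction, which makes
the generator an oracle for the accuracy module rather than a copy of it
(the module computes the maps through the OR/XOR route and is checked
against an independent brute-force loop). A toolpath-space ΔE perturbation
would be more physical but has no exact ledger; mask space was chosen for
testability. `simulate_photo()` renders bright dough on a darker plate with
green corner disks, a known projective warp, and Gaussian noise — it
emulates geometry and contrast, **not** illumination gradients, shadows,
specular highlights, colour casts, or depth effects, so passing tests
demonstrate the pipeline's logic, not robustness to difficult real
photography.

`simulate_survey()` draws per-respondent click counts as 3 plus a binomial
that rises with the image's defect load (a click count independent of load
could never produce a marks/rating association), scatters clicks around
defect sites with uniform background clicks, and builds per-image mean
ratings from the standardized expected mark totals plus a deterministic
orthogonal "appeal" component scaled so the image-level correlation equals
the configured target exactly in expectation; respondent noise averages
out at realistic panel sizes.

# Problem sizes and numerical tolerances

The test-suite and acceptance computations run the blocks on an
80 × 50 mm frame and the outline design on 80 × 60 mm, both at 10 px/mm
(1 px = 0.1 mm, enough to resolve 0.1 mm defect magnitudes); photo
round-trips that only exercise geometry use 5 px/mm. These sizes keep a
full simulate → photograph → assess loop to a couple of seconds while
leaving sub-millimetre defects several pixels wide. Registration recovery
is tested over ±20 px with 1 % salt noise; the volume balance to 1e-9
relative; rendered footprints to 2–3 %; defect-percentage recovery through
the full photo loop to 10 % relative.

# Known limitations

* Arc moves (G2/G3) are rejected; the emulated slicer output is
  polyline-only.
* The honeycomb emulation reproduces the material budget of the hexagonal
  union, not any slicer's exact wall layout or path ordering.
* Multi-layer Z semantics are collapsed into the top view; per-layer
  in-situ assessment would need depth sensing.
* A single global shift models misposition; local warps (shrinkage
  gradients) are not registered and will surface as paired O/U bands.
* Real-photo robustness (markers under difficult lighting, non-bimodal
  backgrounds) is a configuration concern, not a contract the synthetic
  scenes can certify.
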