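---
title: "Measuring seedling length and growth vitality from instance masks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring seedling length and growth vitality from instance masks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedlingvigor)
```

## The measurement problem

A fixed overhead RGB camera images a 25 cm x 25 cm germination box on a
1600 x 1600 px frame (64 px/cm), every 50 minutes over a 90 h growth
window. An instance-segmentation model outputs one probability mask per
seedling. Two systematic effects separate the pixel geometry of those masks
from the physical seedling length:

* **Radial pincushion distortion.** Magnification grows with distance from
  the optical centre, so peripheral seedlings are over-measured. We model
  the warp as `p -> c + d (1 + k1 r^2)` with `d = p - c` and `r` the radius
  normalised by the half frame diagonal; only the *corrector* matters, and
  it never sees `k1` — it is calibrated empirically.
* **Phototropic tilt.** Seedlings lean towards the lighting (four lamps at
  compass azimuths 45/135/225/315 degrees, each effective within about
  +/-15 degrees), so the top-down view forshortens them. With tilt `t`
  measured from the vertical, the apparent length is `L sin(t)`.

`seedlingvigor` recovers length in a fixed composition:

```
length_cm = (perimeter_px * ring_ratio / 2) * (1 / sin(clamped tilt)) * box_cm / frame_px
            \__ distortion __/  \_ halve _/   \______ tilt ______/      \__ scale __/
```

The *half-perimeter rule* reflects that a thin seedling's closed outline
runs up one flank and down the other: half the contour perimeter is the
midline length plus a small end-cap term.

## Contours and perimeters

Masks are binarised at 0.5, merged with clipping (overlapping instances
cannot overflow the valid range), and contoured by marching squares with
linear interpolation at the 0.5 iso-level (`grDevices::contourLines`).
Sub-pixel iso-contours, rather than integer pixel-border walks, are what
make 1-3 px wide strokes measurable: on soft coverage masks the traced
boundary sits on the true outline to well under a tenth of a pixel at any
stroke orientation, where a binary border walk would be biased by up to
~8 % depending on angle. When a mask splits into several connected
components the largest is kept (small specks are segmentation noise) and
the count is reported. The traced level is offset by 1e-6 below 0.5:
synthetic coverage fields take the value 0.5 exactly on grid vertices, a
degenerate marching-squares configuration that would otherwise split the
contour loop.

## Ring-stratified distortion correction

Calibration captures re-image the same physical seedlings at different
radial positions (20 groups of 7 images; the first image of each group
places the seedling at the centre, the calibration point). Observations
are stratified into three equal-width radial rings, and each ring receives
the median, across seedlings, of

```
ratio(ring) = perimeter at the seedling's most central innermost-ring observation
              -------------------------------------------------------------------
              mean perimeter of the same seedling in that ring
```

The innermost ratio is 1 by construction; under pincushion the outer
ratios fall below 1. Using the *most central* innermost observation as the
reference (rather than the ring average) anchors the model at the
calibration point — ring 1 spans a range of radii, and averaging over it
would leak distortion into the reference, biasing all ratios towards 1.

Two protocol choices matter and are deliberate:

* The box is slid along each calibration seedling's lean azimuth. Radial
  distortion is anisotropic for elongated shapes (a stroke aligned with the
  radius stretches like `1 + 3 k1 r^2`, a tangential one like
  `1 + k1 r^2`); phototropic seedlings lean towards the corner lights,
  i.e. roughly radially, so sweeping along the lean keeps the calibration
  poses statistically matched to the poses being corrected.
* The sweep stops at 0.47 x frame side, the radial range that planted
  seedlings can actually occupy. Extrapolating ring ratios beyond the
  measurement domain would calibrate where nothing is ever measured.

Centroids beyond the outermost ring edge reuse the outermost ratio, with a
warning.

## Tilt correction and angle smoothing

Tilt is an input (in production it comes from an oriented-box detector; in
the synthetic pipeline it is ground truth). The correction multiplier is
`1 / sin(t)` with `t` clamped below at 30 degrees: the measured lighting
elevations are 45 +/- 15 degrees, so apparent tilts steeper than 30
degrees are treated as angle-estimation noise, and the clamp caps the
amplification at 2 rather than letting a near-vertical estimate blow up
the length. No upper clamp is applied below 90 degrees — a fully in-plane
seedling (t = 90) genuinely needs no correction, and any upper clamp short
of 90 would contradict that. Raw lean azimuths are shrunk towards the
nearest lighting prior on the circle, `(1 - lambda) raw + lambda prior`
along the shorter arc, with angles already inside the +/-15 degree band
passed through untouched (lambda defaults to 0.7). The rotation alignment
`R(theta)` that uprights an instance is exposed as a diagnostic isometry;
the length chain uses the tilt factor only.

Detection confidence is filtered age-dependently: threshold 0.4 before 60 h
(tillering — keep weak seedlings), 0.6 after (jointing — drop noise). The
60 h cutoff is a configuration default; the stages are biological, not
clock-defined.

## Dual-index vitality

Per treatment cell (six NaCl levels x six nano-iron priming levels):

* **static vitality** — mean seedling length over the series (cm);
* **dynamic vitality** — slope of the OLS line of length on time (cm/h).

Within each normalisation block both indices are divided by their block
maxima and combined with equal weights 0.5/0.5; per priming level the cell
scores are averaged and expressed as percentage shares of the total.
"Equivalent conditions" is read as *per salt level* by default (each salt
level has its own maxima), with a `strategy = "global"` switch for pooled
normalisation — the aggregation is genuinely ambiguous, so both are
provided and the choice is recorded in the output. Negative slopes are
floored at zero before normalisation so scores stay in `[0, 1]` (a
no-growth group should score zero, not negative). Means, not medians, are
used across salt levels, consistent with the averaging used everywhere
else in the index.

## The synthetic scene generator

The generator replaces the camera and the segmentation network, not the
measurement chain. Study conditions are fixed at the rig constants: 1600 px
frame, 25 cm box, 7 x 7 planting grid, `k1 = 0.08`, lighting azimuths
45/135/225/315 +/- 15 degrees, 50-minute captures over 90 h, 36 treatment
cells.

* **Midlines** are quadratic Bezier curves rescaled to an exact arc length
  (the stored ground truth), foreshortened by `sin(tilt)`, rotated to the
  lean azimuth, and warped by the pincushion model.
* **Strokes** are rasterised as signed-distance coverage fields
  `clip(0.5 + R - d, 0, 1)` whose 0.5 level set is exactly the stroke
  boundary, with width 3 px tapering to half width over the terminal 15 %
  at both ends (shoots thin at the soil line and the tip). The taper keeps
  the half-perimeter end-cap bias near 1 % for typical lengths; the
  minimum radius stays above `sqrt(2)/2` px so rasterised tips remain
  8-connected at every lean angle.
* **Placement** draws each seedling's pose and redraws (with slight base
  jitter, shrinking length as a last resort) until its warped midline
  keeps a safe distance from everything already placed — overlapping
  labels are an error by contract, and the procedure stays deterministic
  under the scene seed.
* **Scene poses**: lengths uniform on 12.8-15.2 % of the box side
  (3.2-3.8 cm), tilt uniform on 30-60 degrees, azimuth = nearest corner
  light +/- 15 degrees, confidence uniform on [0.45, 1], age uniform over
  the second half of the horizon.
* **Growth series** follow
  `L(t) = 0.06 * salt_mult * fe_mult * t + N(0, 0.05^2)` cm, clipped at 0,
  with salt multipliers 1/.85/.65/.45/.30/.15 and priming relief
  multipliers 1/1.30/1.16/1.12/1.05/1.38 for 0/20/50/100/200/300 mg/L; the
  (0 mg/L, 150 mmol/L) cell is forced to zero growth. These encode the
  qualitative structure of the study system — monotone salt inhibition, no
  control growth at the harshest salinity, strongest average relief at
  300 mg/L followed by 20 mg/L — not its numerical values.

What the generator does **not** emulate: soil texture and background
clutter, RGB appearance, segmentation failures (missed, merged or
hallucinated instances), adhesion between touching seedlings, motion blur,
or tangential distortion. Passing tests therefore demonstrate that the
*measurement and scoring chain* is correct under its stated geometric
model, not that any particular segmentation network meets a given accuracy
on real imagery.

## Validation layout

Distortion/tilt recovery is validated on a dedicated radial-sweep layout
(`validation_layout()`): 16 seedlings of 5.5-6.5 cm placed along the frame
diagonals from centre to corner, leaning towards their corner lights. The
planting grid is ill-suited for this check — its seedlings are short
(end-cap effects of the same order as the distortion residual) and stop
well inside the outer ring. Recovery tests pool three seeded layouts
(48 instances).

## Numerical choices and problem sizes

* Contour level `0.5 - 1e-6`; contour selection by largest enclosed area.
* Ring count 3 (configurable), equal-width edges over the observed radial
  range; ratio estimator: median across seedlings (robust to odd masks).
* Tilt clamp `[30, 90]` degrees; smoothing weight `lambda = 0.7`.
* OLS fits use the closed-form normal equations; slope standard errors are
  reported for diagnostics.
* Test and acceptance runs use the full-size rig (1600 px frame, 20 x 7
  calibration captures, 49-instance scenes, 109-point series) — chosen
  because the constants above are the study conditions; recovery checks
  pool 3 validation scenes, and slope-recovery checks use 500 replicated
  series.

## Known limitations

* The half-perimeter rule carries a positive end-cap bias of roughly
  `pi * tip_radius` px; it is about 1 % at the validated lengths and grows
  for shorter seedlings.
* A piecewise-constant three-ring correction cannot remove the within-ring
  distortion gradient; the residual is the dominant error term for
  peripheral instances.
* Tilt correction trusts the supplied angle; a biased detector propagates
  `cot(t) * dt` relative error into the length.
* The vitality shares depend on the normalisation strategy when salt
  levels differ strongly in scale; both strategies are reported rather
  than adjudicated.
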