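---
title: "Measuring acetabular cup anteversion with the ellipse method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring acetabular cup anteversion with the ellipse method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cupav)
```

## The measurement problem

After total hip arthroplasty, the orientation of the acetabular component
is monitored on anteroposterior (AP) pelvic radiographs. The cup's
opening rim is a circle in 3D; under (approximately parallel-ray)
projection it appears as an ellipse, and the flatness of that ellipse
encodes the cup's **anteversion** — the forward tilt of its opening
plane out of the coronal plane. Detecting a change of a degree or two in
anteversion between serial films is clinically meaningful: small changes
can be the earliest radiographic sign of cup migration or loosening.

Three progressively stronger readings of the same film are implemented:

1. **Radiographic (planar) anteversion** — McLaren's formula,
   $u = \arcsin(\text{short axis}/\text{long axis})$, read directly off
   the projected ellipse.
2. **Trigonometric anteversion** — $\arcsin(\tan\beta_p)$, where
   $\beta_p = \arctan(b/a)$ is the angle between the ellipse's major
   axis and the segment joining adjacent endpoints of the major and
   minor axes. Because $\tan(\arctan(b/a)) = b/a$, this is
   mathematically identical to the planar value; it differs only in
   which quantities the observer reads off the film, and the identity is
   enforced to $10^{-9}$ degrees as a standing regression property.
3. **Standardized anteversion** — the planar value corrected for the
   patient's pelvic tilt and axial rotation at acquisition, estimated
   from three midline landmarks. This is the quantity whose precision
   supports serial comparison.

## Geometry and conventions

Image coordinates are raster pixels: x rightward, y downward; on a
standard AP film the patient's left is on the image right. Internally a
right-handed *film frame* is used: X toward the patient's left, Y
superior, Z anterior (toward the X-ray source). Projection is
orthographic along Z.

The cup opening axis (unit normal of the opening plane) at planar
anteversion $u$ and inclination $w$ is
$n = (s_x \sin w\cos u,\ \cos w \cos u,\ \sin u)$, with $s_x = \pm 1$ by
side. Orthographic projection of the circular rim of radius $r$ gives an
ellipse with semi-major axis $a = r$, semi-minor axis $b = r\,|n_Z|$,
and major axis perpendicular to the in-plane component of $n$ — hence
$b/a = \sin u$ and the McLaren formula. The cup axis is modeled as
pointing supero-latero-anteriorly; the inclination $w$ is the acute
angle between the projected major axis and the trans-teardrop line.

**Pelvic pose.** The patient's deviation from the reference position is
a tilt $\theta$ about the transverse (trans-teardrop) axis followed by
an axial rotation $\phi$ about the craniocaudal axis:
$R = R_y(\phi)R_x(\theta)$. This order is fixed and used identically by
the simulator and the standardizer, which makes the round-trip recovery
property well defined.

**Landmarks.** The vector from the sacrococcygeal junction (SCJ) to the
upper pole of the symphysis pubis defines the pelvic axis; the line
through both teardrops is the pelvic horizontal. The SCJ displacement
relative to the symphysis pole, decomposed along and across the
trans-teardrop line, gives $(h, v)$; $v$ is positive when the SCJ is
superior, and $h$ is positive toward the measured acetabulum (so its
sign flips with the measured side). Because the symphysis-to-SCJ vector
is nearly anteroposterior, its projection is exquisitely
pose-sensitive, which is what makes the pose recoverable:

$$v = n_v\cos\theta + q\sin\theta, \qquad
  h = \sin\phi\,(n_v\sin\theta - q\cos\theta), \qquad
  q = \sqrt{ssd^2 - n_v^2}.$$

Here $ssd$ is the calibrated 3D length of the symphysis-to-SCJ vector
and $n_v$ (`neutral_v`) its projected vertical displacement in the
reference position. The $v$ equation has two tilt solutions
($\theta = \delta \pm \arccos(v/ssd)$, $\delta = \operatorname{atan2}(q, n_v)$);
the minimal-$|\theta|$ branch is the default because small tilts are the
common clinical case, and the alternative branch is selectable.

**Standardization** is implemented as an explicit rotation composition:
reconstruct the cup axis in the film frame from the measured $(u, w)$
and side, rotate it back by $R_x(-\theta)R_y(-\phi)$, and re-read the
anteversion as $\arcsin$ of the anteroposterior component. With an
identity pose this returns $u$ exactly. The correction is validated
end-to-end against the forward simulator rather than against any closed
algebraic transcription, keeping the standardizer and its oracle
independent of each other: the simulator rotates 3D geometry forward
and projects; the standardizer sees only the 2D annotations.

### The version-sign flag

A single AP ellipse cannot distinguish an anteverted from a
retroverted-looking rim: axes tilted anteriorly or posteriorly by the
same amount project identically. For cups with low anteversion imaged
under a strong backward tilt this matters — the posed axis crosses the
film plane and the apparent version flips. The annotation therefore
carries an `apparent_version` flag ("ante"/"retro", default "ante" —
the overwhelmingly common case), to be supplied externally (lateral
view, cup marker wire); the simulator fills it from ground truth,
playing the role of the informed annotator. Only the standardized value
consumes the flag; the reported planar magnitude stays in $[0, 90]$.

## Ellipse fitting

The interactive axis-matching step of the original workflow is replaced
by a reproducible direct least-squares conic fit constrained to an
ellipse (Fitzgibbon's $4AC - B^2 = 1$ constraint, solved via the
numerically stable Halir–Flusser block decomposition) on at least five
annotated rim points. The ellipse constraint is essential for the
partial, noisy arcs produced when the femoral head obscures most of the
rim; a warning fires below 120° of angular span, where fit variance
grows sharply. Points are centered and isotropically scaled before
fitting; the reported residual is the RMS Sampson distance in pixels.
Exact 64-point inputs are recovered to $10^{-6}$ relative error, and
1 px Gaussian noise on a typical cup (a = 100 px) stays within 2%.

For drawing, the ellipse is rendered as a 64-sided polygon sampled at
uniform parametric angle — the polygon's shoelace area differs from
$\pi a b$ by only 0.16%, and each vertex satisfies the implicit ellipse
equation exactly.

## The simulator as oracle

`cup_scene()`/`project_scene()` build the ground-truth forward model: a
circular rim and the landmark model posed by $(\theta, \phi)$ and
projected orthographically. Orthographic projection is the baseline
because the planar formulas themselves are stated in parallel-ray
terms; no source-to-film distance enters them. Defaults (chosen once as
a realistic scale and used throughout the validation): $ssd = 100$
length-units with `neutral_v` = 30 (the symphysis-to-SCJ vector is
mostly anteroposterior, projecting about a third of its length
vertically on a neutral film), cup radius 25 (≈ a 56 mm cup if 100
units ≈ 11 cm), teardrops ±60 units from midline, annotation noise
applied to clicked points (not to ellipse parameters) because human
clicking error is the error source the precision statistic quantifies.

What the simulator does **not** emulate: perspective magnification
(a point-source mode is out of scope), occlusion beyond restricting the
annotated arc, liner/marker ambiguity at the rim, osteophytes or bony
overlap, and observer bias that correlates across films. Passing the
synthetic recovery tests therefore demonstrates the internal
consistency and noise behavior of the geometry chain, not clinical
accuracy on real films.

## Precision statistics

The repeated standard deviation pools within-patient variability over
repeated films:

$$RSD = \sqrt{\frac{\sum_{j=1}^{c}\sum_{i=1}^{n_j}(X_{ij} - \bar X_j)^2}
                   {\sum_{j=1}^{c}(n_j - 1)}}$$

Patients with a single film contribute nothing and are skipped (their
count is reported). Twice the RSD serves as the significant-change
threshold for serial films — implemented literally as $2\times$, the
conventional ≈95% band without a formal distributional claim. Paired
observer comparisons use the standard paired t-test; zero-variance
differences are flagged degenerate instead of fabricating a p-value.

## Validation summary (what the test suite computes)

All problem sizes below were chosen to exercise the stated parameter
ranges densely while keeping the default suite fast; they are fixed in
the tests and the acceptance script.

* Formula identity to $10^{-9}$ degrees over 400 axis ratios plus 300
  random ellipses (the 45° endpoint is computed via `tanpi`, which is
  exact there).
* Noiseless recovery: 500 simulated films over anteversion 5–60°,
  inclination 30–60°, tilt ±15°, rotation ±10° — standardized output
  within 0.1° of truth; the signed planar reading deviates by > 1°
  across a pure-tilt sweep at |tilt| ≥ 5°.
* Precision ordering: 50 replicate cohorts (8 patients × 4 films,
  poses random per film, 1 px annotation noise) — the standardized RSD
  beats the planar RSD in every cohort, the synthetic analogue of the
  clinical precision comparison.
* Fit recovery, the RSD hand-example $\sqrt 2$, the 64-segment polygon
  and the 1.59° (2 × 0.795°) change threshold.

## Known limitations

* `ssd` and `neutral_v` must be calibrated per patient for real films;
  the defaults are simulation-scale values, and mis-calibration biases
  the tilt estimate directly.
* Pose estimation uses only the three named midline/teardrop landmarks;
  films where these are not clearly visible cannot be standardized.
* The version-sign flag must come from outside the AP film.
* Orthographic projection ignores magnification and beam divergence;
  for centered pelvic films the induced angular error is small but not
  zero.
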