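# cupav — ellipse-method measurement of acetabular cup anteversion

`cupav` measures the orientation of the acetabular component after total
hip arthroplasty from a single anteroposterior (AP) pelvic radiograph.
It is aimed at orthopedic imaging researchers and at anyone building
reproducible follow-up pipelines where a 1–2° change in cup anteversion
between serial films (an early sign of cup migration or loosening) must
be detected reliably.

## The method

The circular cup rim projects onto the film as an ellipse with semi-axes
`a ≥ b`. Three readings of the same film are computed:

* **Radiographic (planar) anteversion** (McLaren):
  `u = arcsin(short axis / long axis) = arcsin(b/a)`.
* **Trigonometric anteversion** (Liaw): `arcsin(tan βp)` where
  `βp = arctan(b/a)` is the angle between the ellipse's major axis and
  the segment joining adjacent endpoints of the major and minor axes.
  Algebraically identical to the planar value; enforced to 1e-9° as a
  standing regression property.
* **Standardized anteversion**: the planar value corrected for the
  patient's pelvic tilt θ and axial rotation φ at acquisition,
  estimated from the displacements (h, v) of the sacrococcygeal
  junction relative to the symphysis pubis upper pole (decomposed along
  the trans-teardrop line) together with the calibrated 3D
  symphysis-to-SCJ length `ssd`. The cup axis is reconstructed from
  (u, w, side), un-rotated by `Rx(-θ)Ry(-φ)`, and the anteversion
  re-read in the reference pelvic frame.

Instead of interactive axis matching, the rim ellipse is recovered from
≥ 5 annotated rim points by a direct least-squares fit constrained to an
ellipse (Fitzgibbon / Halir–Flusser). A forward-projection simulator
(`cup_scene()` / `project_scene()` / `generate_cohort()`) provides
ground truth for every step. Precision is quantified by the repeated
standard deviation (RSD) — the pooled within-patient SD of repeated
measurements — with `2 × RSD` as the significant-change threshold for
serial films, and paired t-tests for observer agreement.

See `vignettes/cup-anteversion-methods.Rmd` for conventions, the pose
model, parameter defaults, and what the simulator does and does not
emulate.

## Worked example

Simulate a film of a right hip with true anteversion 15° and inclination
45°, taken with the pelvis tilted 10° and rotated 5°, with 1 px
annotation noise, then measure it back:

```r
library(cupav)
scene <- cup_scene(anteversion_deg = 15, inclination_deg = 45,
                   theta_deg = 10, phi_deg = 5, side = "right",
                   noise_sigma = 1, seed = 42)
film <- project_scene(scene)
rec <- measure_film(film_annotation(film))
print(rec)
#> <measurement_record> film sim (right hip)
#>   radiographic anteversion    26.690 deg
#>   beta_p / Liaw anteversion   24.188 / 26.690 deg
#>   inclination                 46.727 deg
#>   h, v, ssd                    7.274, 44.843, 100.000
#>   pose (theta, phi)            9.186, 4.668 deg
#>   standardized anteversion    16.972 deg
```

The uncorrected planar reading (26.7°) is off by almost 12° because of
the simulated malposition; the estimated pose (9.2°, 4.7°, vs the true
10°, 5°, blurred by the landmark noise) brings the standardized value
back to 17.0°, within 2° of the true 15°. On a noiseless film the
recovery is exact to better than 0.1°.

Precision statistics from repeated measurements:

```r
vals <- c(14.8, 15.3, 14.9, 15.4, 16.1, 15.8)
pats <- c("p1", "p1", "p1", "p2", "p2", "p2")
r <- repeated_sd(vals, pats)
cat(sprintf("RSD = %.3f deg, change threshold = %.3f deg\n",
            r, change_threshold(r)))
#> RSD = 0.311 deg, change threshold = 0.622 deg
```

A command line tool wraps the same functions:

```sh
Rscript inst/cli/cupav.R simulate --n 10 --seed 7 --out-dir films/
Rscript inst/cli/cupav.R measure --annotation films/annotations.json --out records.csv
Rscript inst/cli/cupav.R rsd --series series.csv
```

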