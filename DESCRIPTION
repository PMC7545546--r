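Package: cupav
Title: Ellipse-Method Measurement of Acetabular Cup Anteversion on Pelvic Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Measures the anteversion of the acetabular component after total
    hip arthroplasty from anteroposterior pelvic radiographs using the ellipse
    method: a 64-segment ellipse is matched to the projected cup rim, from
    which the radiographic (McLaren) anteversion arcsin(short/long axis) and
    the trigonometric (Liaw) anteversion arcsin(tan beta_p) are computed, and
    a standardized anteversion is derived by correcting for pelvic tilt and
    axial rotation estimated from the symphysis pubis, sacrococcygeal junction
    and teardrop landmarks. Includes a direct least-squares ellipse fit to
    annotated rim points, a forward-projection simulator that serves as a
    ground-truth oracle, the repeated-standard-deviation (RSD) precision
    statistic with its 2xRSD significant-change threshold, paired observer
    agreement tests, annotation file input/output (JSON/CSV, PNG/DICOM), and a
    command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
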