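#' Render a measurement overlay to PNG
#'
#' Debug/inspection rendering of an annotated film: the cup rim drawn as
#' the 64-segment polygon (green), the radiographic pelvic axis (purple)
#' and the trans-teardrop line (blue) on a background image (the
#' radiograph if given, otherwise white).
#'
#' @param ann an \code{\link{annotation}}.
#' @param path output PNG path.
#' @param ellipse optional \code{\link{ellipse2d}}; fitted from the
#'   annotation's rim points when omitted.
#' @param background optional numeric matrix in [0, 1] used as backdrop.
#' @param size length-2 image size (width, height) in pixels when no
#'   background is supplied.
#' @return \code{path}, invisibly.
#' @export
render_overlay <- function(ann, path, ellipse = NULL, background = NULL,
                           size = c(512, 512)) {
  stopifnot(inherits(ann, "cup_annotation"))
  if (is.null(ellipse))
    ellipse <- if (!is.null(ann$ellipse)) ann$ellipse
               else fit_ellipse(ann$rim_points)
  if (is.null(background)) {
    img <- array(1, dim = c(size[2], size[1], 3))
  } else {
    background <- pmin(pmax(background, 0), 1)
    img <- array(rep(background, 3),
                 dim = c(nrow(background), ncol(background), 3))
  }
  poly <- render_ellipse_polygon(ellipse, 64L)
  for (i in seq_len(nrow(poly))) {
    j <- if (i == nrow(poly)) 1L else i + 1L
    img <- draw_segment(img, poly[i, ], poly[j, ], c(0, 0.8, 0))  # green rim
  }
  lm <- ann$landmarks
  img <- draw_segment(img, lm$scj, lm$symphysis, c(0.6, 0, 0.8))  # pelvic axis
  img <- draw_segment(img, lm$teardrop_l, lm$teardrop_r, c(0, 0.2, 1))
  png::writePNG(img, path)
  invisible(path)
}

## set pixels along a segment (sub-pixel stepped; clips to the image)
draw_segment <- function(img, p0, p1, rgb) {
  len <- sqrt(sum((p1 - p0)^2))
  n <- max(2L, ceiling(len * 2))
  t <- seq(0, 1, length.out = n)
  xs <- round(p0[1] + t * (p1[1] - p0[1])) + 1L
  ys <- round(p0[2] + t * (p1[2] - p0[2])) + 1L
  keep <- xs >= 1 & xs <= dim(img)[2] & ys >= 1 & ys <= dim(img)[1]
  for (k in which(keep)) img[ys[k], xs[k], ] <- rgb
  img
}
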