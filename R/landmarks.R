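#' Pelvic landmark annotations
#'
#' Bundle of the four 2D landmarks the standardization needs: the upper
#' pole of the symphysis pubis, the center of the sacrococcygeal junction
#' (SCJ), and the two teardrops. Teardrop laterality is the patient's
#' (on a standard AP film the patient's left teardrop appears on the image
#' right).
#'
#' @param symphysis,scj,teardrop_l,teardrop_r numeric length-2 image
#'   coordinates (pixels, x rightward, y downward).
#' @return object of class \code{pelvic_landmarks}.
#' @export
pelvic_landmarks <- function(symphysis, scj, teardrop_l, teardrop_r) {
  for (nm in c("symphysis", "scj", "teardrop_l", "teardrop_r")) {
    v <- get(nm)
    if (is.null(v)) stop(sprintf("missing landmark '%s'", nm), call. = FALSE)
    check_num(v, nm, 2)
  }
  if (isTRUE(all.equal(as.numeric(teardrop_l), as.numeric(teardrop_r))))
    stop("teardrop_l and teardrop_r coincide: trans-teardrop line undefined",
         call. = FALSE)
  structure(list(symphysis = as.numeric(symphysis),
                 scj = as.numeric(scj),
                 teardrop_l = as.numeric(teardrop_l),
                 teardrop_r = as.numeric(teardrop_r)),
            class = "pelvic_landmarks")
}

#' @export
print.pelvic_landmarks <- function(x, ...) {
  cat("<pelvic_landmarks>\n")
  for (nm in names(x))
    cat(sprintf("  %-10s (%.2f, %.2f)\n", nm, x[[nm]][1], x[[nm]][2]))
  invisible(x)
}

#' Radiographic pelvic axis
#'
#' Unit vector from the center of the sacrococcygeal junction to the
#' upper pole of the symphysis pubis; the midline axis drawn on the film.
#'
#' @param landmarks a \code{\link{pelvic_landmarks}}.
#' @return numeric length-2 unit vector in image coordinates.
#' @export
pelvic_axis <- function(landmarks) {
  stopifnot(inherits(landmarks, "pelvic_landmarks"))
  d <- landmarks$symphysis - landmarks$scj
  n <- sqrt(sum(d^2))
  if (n == 0)
    stop("symphysis and sacrococcygeal junction coincide: pelvic axis undefined",
         call. = FALSE)
  d / n
}

#' Trans-teardrop line
#'
#' The pelvic horizontal: the line through the bilateral teardrops.
#'
#' @param landmarks a \code{\link{pelvic_landmarks}}.
#' @return a \code{\link{line2d}} through both teardrops, directed from
#'   the patient's right teardrop toward the patient's left (image
#'   rightward on a standard AP film).
#' @export
trans_teardrop_line <- function(landmarks) {
  stopifnot(inherits(landmarks, "pelvic_landmarks"))
  line2d(landmarks$teardrop_r, landmarks$teardrop_l - landmarks$teardrop_r)
}

#' Landmark displacements h and v
#'
#' Decomposes the displacement of the sacrococcygeal junction relative to
#' the upper pole of the symphysis pubis in the frame spanned by the
#' trans-teardrop direction (horizontal) and its in-image perpendicular
#' (superior positive). The sign conventions follow the standardization
#' formulas:
#' \itemize{
#'   \item \code{v} is positive when the SCJ lies above (superior to) the
#'     symphysis upper pole;
#'   \item \code{h} is positive when the SCJ is displaced toward the
#'     measured acetabulum (i.e., lies between the acetabulum and the
#'     symphysis pole), negative otherwise — so its sign depends on which
#'     hip is being measured.
#' }
#' \code{h_raw} is the side-independent horizontal component, positive
#' toward the patient's left; it is what the pose estimator consumes.
#'
#' @param landmarks a \code{\link{pelvic_landmarks}}.
#' @param side `"left"` or `"right"`: the hip being measured.
#' @return list with \code{h} (signed per side), \code{v}, and
#'   \code{h_raw} (positive toward patient's left), all in pixels.
#' @export
displacements <- function(landmarks, side = c("left", "right")) {
  stopifnot(inherits(landmarks, "pelvic_landmarks"))
  side <- match.arg(side)
  xhat <- trans_teardrop_line(landmarks)$direction   # toward patient's left
  yhat_up <- c(xhat[2], -xhat[1])                    # superior (image y down)
  d <- landmarks$scj - landmarks$symphysis
  h_raw <- sum(d * xhat)
  v <- sum(d * yhat_up)
  h <- if (side == "left") h_raw else -h_raw
  list(h = h, v = v, h_raw = h_raw)
}
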