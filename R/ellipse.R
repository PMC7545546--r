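#' Ellipse representing the projected cup rim
#'
#' Constructs an \code{ellipse2d}, the geometric ellipse matched to the
#' projected rim of the acetabular component on the radiograph. Axes are
#' stored as semi-lengths; the axis ratio (all the anteversion formulas
#' need) is identical for semi- and full lengths.
#'
#' If \code{b > a} the axes are swapped and the orientation rotated by 90
#' degrees, so that \code{a >= b >= 0} always holds; annotation tools may
#' return the axes in either order. Orientation is reduced modulo 180.
#'
#' @param cx,cy center, in image pixels (x rightward, y downward).
#' @param a,b semi-axes in pixels; after normalization \code{a} is the
#'   semi-major and \code{b} the semi-minor axis.
#' @param orientation_deg angle of the major axis against the image x-axis,
#'   in degrees. Positive angles turn from +x toward +y (downward on
#'   screen).
#' @return An object of class \code{ellipse2d} with fields \code{cx},
#'   \code{cy}, \code{a}, \code{b}, \code{orientation_deg}.
#' @examples
#' e <- ellipse2d(200, 150, a = 50, b = 25, orientation_deg = 30)
#' radiographic_anteversion(e)  # 30
#' @export
ellipse2d <- function(cx, cy, a, b, orientation_deg = 0) {
  check_num(cx, "cx", 1); check_num(cy, "cy", 1)
  check_num(a, "a", 1); check_num(b, "b", 1)
  check_num(orientation_deg, "orientation_deg", 1)
  if (a < 0 || b < 0) stop("semi-axes must be non-negative", call. = FALSE)
  if (b > a) {
    tmp <- a; a <- b; b <- tmp
    orientation_deg <- orientation_deg + 90
  }
  orientation_deg <- orientation_deg %% 180
  structure(list(cx = as.numeric(cx)[1], cy = as.numeric(cy)[1],
                 a = as.numeric(a)[1], b = as.numeric(b)[1],
                 orientation_deg = as.numeric(orientation_deg)[1]),
            class = "ellipse2d")
}

#' @export
print.ellipse2d <- function(x, ...) {
  cat(sprintf(
    "<ellipse2d> center (%.3f, %.3f)  a = %.3f  b = %.3f  orientation = %.3f deg\n",
    x$cx, x$cy, x$a, x$b, x$orientation_deg))
  invisible(x)
}

stop_if_degenerate <- function(ellipse) {
  if (!inherits(ellipse, "ellipse2d")) stop("not an 'ellipse2d'", call. = FALSE)
  if (ellipse$a <= 0)
    stop("degenerate ellipse: semi-major axis must be > 0", call. = FALSE)
  invisible(ellipse)
}

#' Radiographic (McLaren) anteversion of a projected cup rim
#'
#' The planar anteversion read directly off the projected ellipse,
#' \eqn{\arcsin(\mathrm{short\ axis} / \mathrm{long\ axis})}. A circle
#' (cup opening facing the beam) gives 90 degrees; a rim seen edge-on
#' projects to a segment and gives 0.
#'
#' The sign of the version (ante- vs retroversion) is not recoverable from
#' a single AP projection; the magnitude in [0, 90] is returned.
#'
#' @param ellipse an \code{\link{ellipse2d}} with \code{a > 0}.
#' @return anteversion in degrees, in [0, 90].
#' @seealso \code{\link{beta_p}}, \code{\link{liaw_anteversion}}
#' @export
radiographic_anteversion <- function(ellipse) {
  stop_if_degenerate(ellipse)
  rad2deg(asin(min(1, ellipse$b / ellipse$a)))
}

#' Auxiliary angle beta_p of the projected ellipse
#'
#' The angle between the major axis and the segment joining a major-axis
#' endpoint to the adjacent minor-axis endpoint; its tangent equals the
#' axis ratio b/a, so \code{beta_p} lies in [0, 45] by construction
#' (the \code{\link{ellipse2d}} constructor enforces a >= b).
#'
#' @param ellipse an \code{\link{ellipse2d}} with \code{a > 0}.
#' @return \eqn{\arctan(b/a)} in degrees, in [0, 45].
#' @export
beta_p <- function(ellipse) {
  stop_if_degenerate(ellipse)
  rad2deg(atan2(ellipse$b, ellipse$a))
}

#' Trigonometric (Liaw) anteversion from the beta_p angle
#'
#' \eqn{\arcsin(\tan\beta_p)}. Because \eqn{\tan(\arctan(b/a)) = b/a},
#' this is mathematically identical to the radiographic anteversion
#' \eqn{\arcsin(b/a)}; the two are computed through different measured
#' quantities on the film.
#'
#' @param beta_deg the beta_p angle in degrees, in [0, 45]. Values above
#'   45 would imply a minor axis longer than the major axis and raise an
#'   error.
#' @return anteversion in degrees, in [0, 90].
#' @export
liaw_anteversion <- function(beta_deg) {
  check_num(beta_deg, "beta_deg", 1)
  if (beta_deg < 0 || beta_deg > 45 + 1e-12)
    stop("beta_p must lie in [0, 45] degrees (tan beta_p <= 1)", call. = FALSE)
  ## tanpi is exact at the 45-degree endpoint, where plain tan(deg2rad(x))
  ## loses ~1e-6 deg through the radian conversion
  rad2deg(asin(min(1, tanpi(beta_deg / 180))))
}

#' Sample an ellipse as a closed polygon
#'
#' Renders the ellipse as an n-sided polygon by sampling the parametric
#' form at uniform parameter steps \eqn{2\pi k/n} (not uniform arc
#' length): each vertex is computed from the position and lengths of the
#' long and short axes. The default of 64 segments is the resolution used
#' for drawing the rim overlay. The polygon is closed implicitly: the last
#' vertex connects back to the first.
#'
#' @param ellipse an \code{\link{ellipse2d}}.
#' @param n_segments number of polygon sides, at least 3. Default 64.
#' @return an \code{n_segments x 2} matrix of vertices (columns \code{x},
#'   \code{y}, image pixels).
#' @export
render_ellipse_polygon <- function(ellipse, n_segments = 64L) {
  if (!inherits(ellipse, "ellipse2d")) stop("not an 'ellipse2d'", call. = FALSE)
  check_num(n_segments, "n_segments", 1)
  n_segments <- as.integer(n_segments)
  if (n_segments < 3L) stop("n_segments must be >= 3", call. = FALSE)
  t <- 2 * pi * (seq_len(n_segments) - 1L) / n_segments
  o <- deg2rad(ellipse$orientation_deg)
  xl <- ellipse$a * cos(t)
  yl <- ellipse$b * sin(t)
  cbind(x = ellipse$cx + xl * cos(o) - yl * sin(o),
        y = ellipse$cy + xl * sin(o) + yl * cos(o))
}

#' A 2D line given by a point and a direction
#'
#' @param point numeric length-2, a point on the line (image pixels).
#' @param direction numeric length-2, non-zero direction; stored
#'   normalized to unit length.
#' @return object of class \code{line2d}.
#' @export
line2d <- function(point, direction) {
  check_num(point, "point", 2)
  check_num(direction, "direction", 2)
  n <- sqrt(sum(direction^2))
  if (n == 0) stop("line direction must be non-zero", call. = FALSE)
  structure(list(point = as.numeric(point),
                 direction = as.numeric(direction) / n),
            class = "line2d")
}

#' Cup inclination (abduction) angle
#'
#' The acute angle between the major axis of the projected rim and the
#' pelvic horizontal, conventionally the trans-teardrop line. Angles above
#' 90 are folded back, so the result lies in [0, 90].
#'
#' @param ellipse an \code{\link{ellipse2d}} with \code{a > 0}.
#' @param trans_teardrop_line a \code{\link{line2d}}, usually from
#'   \code{\link{trans_teardrop_line}}.
#' @return inclination in degrees, in [0, 90].
#' @export
inclination <- function(ellipse, trans_teardrop_line) {
  stop_if_degenerate(ellipse)
  if (!inherits(trans_teardrop_line, "line2d"))
    stop("'trans_teardrop_line' must be a line2d", call. = FALSE)
  o <- deg2rad(ellipse$orientation_deg)
  major <- c(cos(o), sin(o))
  d <- trans_teardrop_line$direction
  rad2deg(acos(min(1, abs(sum(major * d)))))
}
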