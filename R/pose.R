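#' Pelvic pose (tilt and axial rotation)
#'
#' The patient's deviation from the standardized reference position:
#' \code{theta} is pelvic tilt, a rotation about the transverse
#' (trans-teardrop) axis, and \code{phi} is axial rotation about the
#' craniocaudal axis. In the film frame (X toward patient's left, Y
#' superior, Z anterior) the pose acts on pelvic-frame vectors as
#' \eqn{R = R_y(\phi)\, R_x(\theta)}: the tilt is applied first, then the
#' axial rotation. Positive \code{theta} rotates the superior direction
#' anteriorly (posterior pelvic tilt of the top of the pelvis toward the
#' beam source); positive \code{phi} rotates the patient's left side
#' anteriorly.
#'
#' @param theta_deg,phi_deg angles in degrees, each in (-90, 90).
#' @return object of class \code{pelvic_pose}.
#' @export
pelvic_pose <- function(theta_deg = 0, phi_deg = 0) {
  check_num(theta_deg, "theta_deg", 1)
  check_num(phi_deg, "phi_deg", 1)
  if (abs(theta_deg) >= 90 || abs(phi_deg) >= 90)
    stop("pelvic pose angles must lie in (-90, 90) degrees", call. = FALSE)
  structure(list(theta_deg = theta_deg, phi_deg = phi_deg),
            class = "pelvic_pose")
}

#' @export
print.pelvic_pose <- function(x, ...) {
  cat(sprintf("<pelvic_pose> tilt theta = %.3f deg, rotation phi = %.3f deg\n",
              x$theta_deg, x$phi_deg))
  invisible(x)
}

rot_x <- function(t) {
  c <- cos(t); s <- sin(t)
  matrix(c(1, 0, 0,
           0, c, s,
           0, -s, c), 3, 3)   # column-major: maps (x,y,z) -> (x, yc - zs, ys + zc)
}

rot_y <- function(t) {
  c <- cos(t); s <- sin(t)
  matrix(c(c, 0, -s,
           0, 1, 0,
           s, 0, c), 3, 3)    # maps (x,y,z) -> (xc + zs, y, -xs + zc)
}

## pelvic-frame -> film-frame rotation
pose_matrix <- function(pose) {
  stopifnot(inherits(pose, "pelvic_pose"))
  rot_y(deg2rad(pose$phi_deg)) %*% rot_x(deg2rad(pose$theta_deg))
}

#' Estimate pelvic pose from the landmark displacements
#'
#' Inverts the projection model of the midline symphysis-to-SCJ vector.
#' In the reference position that vector, of calibrated 3D length
#' \code{ssd}, projects to a purely vertical displacement
#' \code{neutral_v} with out-of-plane (posterior) depth
#' \eqn{\sqrt{ssd^2 - neutral_v^2}}. Tilting by \eqn{\theta} and rotating
#' by \eqn{\phi} moves its projection to
#' \deqn{v = n_v\cos\theta + q\sin\theta,\qquad
#'       h = \sin\phi\,(n_v\sin\theta - q\cos\theta),}
#' with \eqn{q = \sqrt{ssd^2 - n_v^2}}. The \eqn{v} equation has two
#' tilt solutions; by default the one with the smaller \eqn{|\theta|} is
#' returned (small tilts are the common clinical case), selectable via
#' \code{branch}.
#'
#' @param h horizontal displacement of the SCJ relative to the symphysis
#'   upper pole, positive toward the patient's left (the side-independent
#'   \code{h_raw} of \code{\link{displacements}}).
#' @param v vertical displacement, superior positive.
#' @param ssd calibrated 3D symphysis-to-SCJ length, same units as
#'   \code{h}, \code{v}.
#' @param neutral_v the projected \code{v} in the reference position
#'   (configuration parameter; see \code{\link{measure_config}}).
#' @param branch tilt-solution selection: \code{"min_tilt"} (default),
#'   \code{"lower"} or \code{"upper"} of the two analytic solutions.
#' @return a \code{\link{pelvic_pose}}.
#' @export
estimate_pelvic_pose <- function(h, v, ssd, neutral_v,
                                 branch = c("min_tilt", "lower", "upper")) {
  branch <- match.arg(branch)
  check_num(h, "h", 1); check_num(v, "v", 1)
  check_num(ssd, "ssd", 1); check_num(neutral_v, "neutral_v", 1)
  if (ssd <= 0) stop("ssd must be > 0", call. = FALSE)
  if (abs(neutral_v) >= ssd)
    stop("|neutral_v| must be < ssd", call. = FALSE)
  if (h^2 + v^2 > ssd^2 * (1 + 1e-12))
    stop("inconsistent landmarks: h^2 + v^2 exceeds ssd^2", call. = FALSE)
  q <- sqrt(ssd^2 - neutral_v^2)
  delta <- atan2(q, neutral_v)
  ca <- acos(max(-1, min(1, v / ssd)))
  cand <- c(lower = delta - ca, upper = delta + ca)
  ## wrap into (-pi, pi]
  cand <- ((cand + pi) %% (2 * pi)) - pi
  theta <- switch(branch,
                  min_tilt = cand[which.min(abs(cand))],
                  lower = cand["lower"],
                  upper = cand["upper"])
  wz <- neutral_v * sin(theta) - q * cos(theta)
  if (abs(wz) < 1e-12) {
    if (abs(h) < 1e-9) phi <- 0
    else stop("no pelvic pose reproduces the observed displacements",
              call. = FALSE)
  } else {
    sphi <- h / wz
    if (abs(sphi) > 1 + 1e-9)
      stop("no pelvic pose reproduces the observed displacements",
           call. = FALSE)
    phi <- asin(max(-1, min(1, sphi)))
  }
  pelvic_pose(rad2deg(as.numeric(theta)), rad2deg(phi))
}

#' Cup opening axis from planar angles
#'
#' Unit normal of the cup's opening plane in the film frame (X toward
#' patient's left, Y superior, Z anterior), reconstructed from the planar
#' anteversion \code{u}, inclination \code{w}, and the measured side:
#' \eqn{n = (s_x \sin w \cos u,\ \cos w \cos u,\ \sin u)} with
#' \eqn{s_x = +1} for a left hip and \eqn{-1} for a right hip (the axis
#' points laterally, superiorly and anteriorly). Under orthographic
#' projection the rim ellipse has axis ratio \eqn{b/a = |n_Z| = \sin u}
#' and its major axis makes the acute angle \code{w} with the horizontal.
#'
#' @param u_deg planar anteversion in degrees, [0, 90].
#' @param w_deg inclination in degrees, [0, 90].
#' @param side `"left"` or `"right"`.
#' @return numeric length-3 unit vector.
#' @export
cup_axis <- function(u_deg, w_deg, side = c("left", "right")) {
  side <- match.arg(side)
  check_num(u_deg, "u_deg", 1); check_num(w_deg, "w_deg", 1)
  u <- deg2rad(u_deg); w <- deg2rad(w_deg)
  sx <- if (side == "left") 1 else -1
  c(sx * sin(w) * cos(u), cos(w) * cos(u), sin(u))
}

## anteversion/inclination implied by a film-frame axis vector
axis_anteversion <- function(n) rad2deg(asin(min(1, abs(n[3]))))
axis_inclination <- function(n) {
  if (abs(n[1]) < 1e-15 && abs(n[2]) < 1e-15) return(0)
  rad2deg(atan2(abs(n[1]), abs(n[2])))
}

#' Per-film planar measurement
#'
#' Container for the planar quantities of one film: radiographic
#' anteversion \code{u}, inclination \code{w}, landmark displacements
#' \code{h} and \code{v}, the calibrated symphysis-to-SCJ length
#' \code{ssd} and the measured side. Validates the geometric consistency
#' \eqn{h^2 + v^2 \le ssd^2}.
#'
#' @param u,w angles in degrees, each in [0, 90].
#' @param h,v displacements (see \code{\link{displacements}}); \code{h}
#'   here is the side-independent horizontal component, positive toward
#'   the patient's left.
#' @param ssd calibrated 3D symphysis-to-SCJ length (same units as h, v).
#' @param side `"left"` or `"right"`.
#' @return object of class \code{planar_measurement}.
#' @export
planar_measurement <- function(u, w, h, v, ssd, side = c("left", "right")) {
  side <- match.arg(side)
  check_num(u, "u", 1); check_num(w, "w", 1)
  check_num(h, "h", 1); check_num(v, "v", 1); check_num(ssd, "ssd", 1)
  if (u < 0 || u > 90 || w < 0 || w > 90)
    stop("u and w must lie in [0, 90] degrees", call. = FALSE)
  if (h^2 + v^2 > ssd^2 * (1 + 1e-12))
    stop("inconsistent landmarks: h^2 + v^2 exceeds ssd^2", call. = FALSE)
  structure(list(u = u, w = w, h = h, v = v, ssd = ssd, side = side),
            class = "planar_measurement")
}

#' Standardized (position-corrected) anteversion
#'
#' Re-expresses the cup anteversion in the standardized pelvic reference
#' frame: the cup opening axis is reconstructed in the film frame from
#' the planar anteversion \code{u} and inclination \code{w}
#' (\code{\link{cup_axis}}), rotated back by the inverse of the pelvic
#' pose (\eqn{R_x(-\theta) R_y(-\phi)}), and the anteversion is re-read
#' as the arcsine of the resulting anteroposterior component. With an
#' identity pose this returns \code{u} unchanged.
#'
#' A single AP ellipse cannot distinguish an anteverted from a
#' retroverted-looking rim (the projection is identical for an axis
#' tilted anteriorly or posteriorly by the same amount). The
#' \code{apparent_version} flag supplies that sign externally (from a
#' lateral view, the cup's marker wire, or simulation ground truth);
#' the default \code{"ante"} is the overwhelmingly common clinical case.
#'
#' @param pm a \code{\link{planar_measurement}}.
#' @param pose a \code{\link{pelvic_pose}}, typically from
#'   \code{\link{estimate_pelvic_pose}}.
#' @param apparent_version \code{"ante"} if the projected cup axis points
#'   anteriorly on this film, \code{"retro"} if posteriorly.
#' @return standardized anteversion in degrees, in [0, 90].
#' @export
standardized_anteversion <- function(pm, pose,
                                     apparent_version = c("ante", "retro")) {
  stopifnot(inherits(pm, "planar_measurement"), inherits(pose, "pelvic_pose"))
  apparent_version <- match.arg(apparent_version)
  n_film <- cup_axis(pm$u, pm$w, pm$side)
  if (apparent_version == "retro") n_film[3] <- -n_film[3]
  Rinv <- rot_x(-deg2rad(pose$theta_deg)) %*% rot_y(-deg2rad(pose$phi_deg))
  n_pelvic <- as.numeric(Rinv %*% n_film)
  nz <- n_pelvic[3]
  if (abs(nz) > 1 + 1e-9)
    stop("numerical error: axis component magnitude exceeds 1", call. = FALSE)
  rad2deg(asin(min(1, abs(nz))))
}
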