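#' Measurement configuration
#'
#' Per-run configuration of the standardization chain.
#'
#' \code{ssd} is the calibrated 3D length of the symphysis-to-SCJ vector.
#' A single AP film only shows its projected displacements h and v; the
#' out-of-plane depth \eqn{\sqrt{ssd^2 - h^2 - v^2}} requires knowing the
#' true length, so \code{ssd} is supplied per patient (for example
#' calibrated from a film designated neutral). \code{neutral_v} is the
#' projected vertical displacement in the standardized reference
#' position. Defaults match the simulator's landmark model (100 and 30
#' length-units).
#'
#' @param ssd calibrated symphysis-to-SCJ 3D length (length units).
#' @param neutral_v projected v at the reference position (same units).
#' @param tilt_branch tilt-solution selection passed to
#'   \code{\link{estimate_pelvic_pose}}.
#' @param pixel_spacing physical size of one pixel (length units per
#'   pixel); 1 keeps everything in pixels. Only the ratio to \code{ssd}
#'   matters, so units cancel when \code{ssd} is calibrated in the same
#'   units as the scaled coordinates.
#' @return object of class \code{measure_config}.
#' @export
measure_config <- function(ssd = 100, neutral_v = 30,
                           tilt_branch = c("min_tilt", "lower", "upper"),
                           pixel_spacing = 1) {
  tilt_branch <- match.arg(tilt_branch)
  check_num(ssd, "ssd", 1); check_num(neutral_v, "neutral_v", 1)
  check_num(pixel_spacing, "pixel_spacing", 1)
  if (ssd <= 0) stop("ssd must be > 0", call. = FALSE)
  if (pixel_spacing <= 0) stop("pixel_spacing must be > 0", call. = FALSE)
  if (abs(neutral_v) >= ssd) stop("|neutral_v| must be < ssd", call. = FALSE)
  structure(list(ssd = ssd, neutral_v = neutral_v,
                 tilt_branch = tilt_branch, pixel_spacing = pixel_spacing),
            class = "measure_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA), f)
  as.character(tools::md5sum(f))
}

#' Measure one annotated film
#'
#' End-to-end measurement workflow for a single annotated AP film:
#' \enumerate{
#'   \item obtain the rim ellipse (explicit parameters, or
#'     \code{\link{fit_ellipse}} on the rim points);
#'   \item radiographic anteversion \eqn{u = \arcsin(b/a)}, the
#'     \eqn{\beta_p} angle and Liaw anteversion \eqn{\arcsin(\tan\beta_p)};
#'   \item trans-teardrop line and inclination \eqn{w};
#'   \item landmark displacements h, v (scaled by the pixel spacing);
#'   \item pelvic pose estimate from (h, v, ssd, neutral_v);
#'   \item standardized anteversion in the reference pelvic frame.
#' }
#'
#' @param ann an \code{\link{annotation}} (landmarks plus either
#'   \code{rim_points} or an explicit \code{ellipse}).
#' @param config a \code{\link{measure_config}}.
#' @return object of class \code{measurement_record} with all
#'   intermediate values, the estimated pose, the fit residual (NA when
#'   an explicit ellipse was supplied) and a provenance stamp (package
#'   version + configuration hash).
#' @export
measure_film <- function(ann, config = measure_config()) {
  stopifnot(inherits(ann, "cup_annotation"), inherits(config, "measure_config"))
  ellipse <- if (!is.null(ann$ellipse)) ann$ellipse
             else fit_ellipse(ann$rim_points)
  fit_rms <- attr(ellipse, "fit_rms") %||% NA_real_
  u <- radiographic_anteversion(ellipse)
  bp <- beta_p(ellipse)
  u_liaw <- liaw_anteversion(bp)
  ttl <- trans_teardrop_line(ann$landmarks)
  w <- inclination(ellipse, ttl)
  disp <- displacements(ann$landmarks, ann$side)
  sp <- config$pixel_spacing
  pose <- estimate_pelvic_pose(disp$h_raw * sp, disp$v * sp,
                               ssd = config$ssd,
                               neutral_v = config$neutral_v,
                               branch = config$tilt_branch)
  pm <- planar_measurement(u = u, w = w, h = disp$h_raw * sp,
                           v = disp$v * sp, ssd = config$ssd,
                           side = ann$side)
  std <- standardized_anteversion(pm, pose, ann$apparent_version %||% "ante")
  structure(list(
    film_id = ann$film_id,
    side = ann$side,
    ellipse = ellipse,
    radiographic_anteversion = u,
    beta_p = bp,
    liaw_anteversion = u_liaw,
    inclination = w,
    h = disp$h * sp,          # signed per the measured side
    v = disp$v * sp,
    ssd = config$ssd,
    pose = pose,
    standardized_anteversion = std,
    fit_rms = fit_rms,
    provenance = list(package = "cupav",
                      version = as.character(utils::packageVersion("cupav")),
                      config_md5 = config_hash(config))),
    class = "measurement_record")
}

#' @export
print.measurement_record <- function(x, ...) {
  cat(sprintf("<measurement_record> film %s (%s hip)\n", x$film_id, x$side))
  cat(sprintf("  radiographic anteversion  %8.3f deg\n",
              x$radiographic_anteversion))
  cat(sprintf("  beta_p / Liaw anteversion %8.3f / %.3f deg\n",
              x$beta_p, x$liaw_anteversion))
  cat(sprintf("  inclination               %8.3f deg\n", x$inclination))
  cat(sprintf("  h, v, ssd                 %8.3f, %.3f, %.3f\n",
              x$h, x$v, x$ssd))
  cat(sprintf("  pose (theta, phi)         %8.3f, %.3f deg\n",
              x$pose$theta_deg, x$pose$phi_deg))
  cat(sprintf("  standardized anteversion  %8.3f deg\n",
              x$standardized_anteversion))
  invisible(x)
}

#' Tabulate measurement records
#'
#' @param records a \code{measurement_record} or list of them.
#' @return data.frame, one row per film.
#' @export
records_table <- function(records) {
  if (inherits(records, "measurement_record")) records <- list(records)
  do.call(rbind, lapply(records, function(r) {
    data.frame(film_id = r$film_id, side = r$side,
               ellipse_cx = r$ellipse$cx, ellipse_cy = r$ellipse$cy,
               ellipse_a = r$ellipse$a, ellipse_b = r$ellipse$b,
               ellipse_orientation_deg = r$ellipse$orientation_deg,
               radiographic_anteversion_deg = r$radiographic_anteversion,
               beta_p_deg = r$beta_p,
               liaw_anteversion_deg = r$liaw_anteversion,
               inclination_deg = r$inclination,
               h = r$h, v = r$v, ssd = r$ssd,
               theta_deg = r$pose$theta_deg, phi_deg = r$pose$phi_deg,
               standardized_anteversion_deg = r$standardized_anteversion,
               fit_rms = r$fit_rms,
               stringsAsFactors = FALSE)
  }))
}
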