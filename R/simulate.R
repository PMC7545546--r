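#' Synthetic radiograph scene
#'
#' Fully specified 3D scene from which a synthetic AP film is projected:
#' a circular cup rim at known anatomical anteversion and inclination, a
#' midline symphysis-to-SCJ vector and bilateral teardrops, all expressed
#' in the standardized pelvic frame (X toward patient's left, Y superior,
#' Z anterior), then rotated by a pelvic pose. The simulator is the
#' ground-truth oracle for every measurement operation.
#'
#' Landmark model defaults: teardrops symmetric about the midline on the
#' transverse axis; the symphysis upper pole at the origin with the SCJ
#' displaced \code{neutral_v} superiorly and
#' \eqn{\sqrt{ssd^2 - neutral\_v^2}} posteriorly, so that a neutral film
#' shows \code{h = 0}, \code{v = neutral_v}. All lengths are in pixels of
#' the projected image (orthographic projection, unit magnification).
#'
#' @param anteversion_deg,inclination_deg true anatomical cup angles in
#'   degrees, each in [0, 90).
#' @param cup_radius rim radius (pixels), > 0.
#' @param theta_deg,phi_deg pelvic pose (tilt, axial rotation) in degrees.
#' @param side hip being simulated, `"left"` or `"right"`.
#' @param noise_sigma standard deviation (pixels) of Gaussian annotation
#'   noise added independently to every projected landmark and rim point;
#'   0 disables noise. Mimics human clicking error.
#' @param seed integer seed for the noise; required when
#'   \code{noise_sigma > 0}.
#' @param ssd 3D symphysis-to-SCJ length (pixels).
#' @param neutral_v projected vertical SCJ displacement in the reference
#'   position (pixels).
#' @param teardrop_halfwidth half the inter-teardrop distance (pixels).
#' @param cup_offset 3D position of the cup center for a left hip,
#'   mirrored in X for a right hip (pixels, pelvic frame).
#' @param image_offset length-2: image coordinates of the pelvic-frame
#'   origin (places the scene on the film).
#' @param film_id identifier carried into annotations.
#' @return object of class \code{cup_scene}.
#' @export
cup_scene <- function(anteversion_deg, inclination_deg,
                      cup_radius = 25,
                      theta_deg = 0, phi_deg = 0,
                      side = c("left", "right"),
                      noise_sigma = 0, seed = NULL,
                      ssd = 100, neutral_v = 30,
                      teardrop_halfwidth = 60,
                      cup_offset = c(45, 30, 0),
                      image_offset = c(256, 256),
                      film_id = "sim") {
  side <- match.arg(side)
  check_num(anteversion_deg, "anteversion_deg", 1)
  check_num(inclination_deg, "inclination_deg", 1)
  if (anteversion_deg < 0 || anteversion_deg >= 90 ||
      inclination_deg < 0 || inclination_deg >= 90)
    stop("anteversion and inclination must lie in [0, 90)", call. = FALSE)
  check_num(cup_radius, "cup_radius", 1)
  if (cup_radius <= 0) stop("cup_radius must be > 0", call. = FALSE)
  check_num(ssd, "ssd", 1)
  if (ssd <= 0) stop("ssd must be > 0", call. = FALSE)
  if (abs(neutral_v) >= ssd) stop("|neutral_v| must be < ssd", call. = FALSE)
  check_num(noise_sigma, "noise_sigma", 1)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (noise_sigma > 0 && is.null(seed))
    stop("a seed is required when noise_sigma > 0", call. = FALSE)
  sx <- if (side == "left") 1 else -1
  structure(list(
    anteversion_deg = anteversion_deg,
    inclination_deg = inclination_deg,
    cup_radius = cup_radius,
    pose = pelvic_pose(theta_deg, phi_deg),
    side = side,
    noise_sigma = noise_sigma,
    seed = seed,
    ssd = ssd,
    neutral_v = neutral_v,
    image_offset = as.numeric(image_offset),
    film_id = film_id,
    landmarks3d = list(
      symphysis = c(0, 0, 0),
      scj = c(0, neutral_v, -sqrt(ssd^2 - neutral_v^2)),
      teardrop_l = c(teardrop_halfwidth, 25, 0),
      teardrop_r = c(-teardrop_halfwidth, 25, 0)),
    cup_center = c(sx * cup_offset[1], cup_offset[2], cup_offset[3])),
    class = "cup_scene")
}

## film frame (X patient-left, Y superior, Z anterior) -> image pixels
film_to_image <- function(p3, offset) {
  cbind(x = p3[, 1] + offset[1], y = offset[2] - p3[, 2])
}

#' Project a scene onto the film plane
#'
#' Orthographic (parallel-ray) forward projection: the cup rim and the
#' landmark model are rotated by the scene's pelvic pose
#' (\eqn{R_y(\phi) R_x(\theta)}) and projected along the anteroposterior
#' axis onto the image. The projected rim is an exact ellipse whose
#' parameters are computed analytically (\code{true_ellipse}): semi-major
#' axis equal to the rim radius, semi-minor axis \eqn{r |n_Z|} where
#' \eqn{n} is the rotated opening axis, major axis perpendicular to the
#' in-plane component of \eqn{n}. With \code{noise_sigma > 0}, seeded
#' Gaussian noise is added to the projected annotation points (never to
#' the analytic ellipse).
#'
#' @param scene a \code{\link{cup_scene}}.
#' @param n_rim_points number of rim annotation points to emit.
#' @param arc_deg length-2 range of rim parameter angles (degrees)
#'   actually annotated; restrict below 360 to emulate occlusion of the
#'   rim by the femoral head.
#' @return object of class \code{synthetic_film}: \code{landmarks}
#'   (a \code{\link{pelvic_landmarks}}, noised if requested),
#'   \code{rim_points} (n x 2 matrix, noised if requested),
#'   \code{true_ellipse} (noiseless analytic \code{\link{ellipse2d}}),
#'   and \code{scene}.
#' @export
project_scene <- function(scene, n_rim_points = 64, arc_deg = c(0, 360)) {
  stopifnot(inherits(scene, "cup_scene"))
  R <- pose_matrix(scene$pose)
  n0 <- cup_axis(scene$anteversion_deg, scene$inclination_deg, scene$side)
  ## rim basis in the opening plane
  ref <- if (abs(n0[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  e1 <- cross3(n0, ref); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(n0, e1)
  tt <- deg2rad(seq(arc_deg[1], arc_deg[2], length.out = n_rim_points + 1L))
  tt <- tt[-length(tt)]
  rim3 <- t(scene$cup_center + scene$cup_radius *
              (outer(e1, cos(tt)) + outer(e2, sin(tt))))
  rim3 <- rim3 %*% t(R)
  rim <- film_to_image(rim3, scene$image_offset)
  lm3 <- do.call(rbind, scene$landmarks3d) %*% t(R)
  lmp <- film_to_image(lm3, scene$image_offset)
  rownames(lmp) <- names(scene$landmarks3d)
  ## analytic projected ellipse
  np <- as.numeric(R %*% n0)
  cp <- as.numeric(R %*% scene$cup_center)
  ctr <- film_to_image(matrix(cp, 1), scene$image_offset)
  b <- scene$cup_radius * abs(np[3])
  inplane <- sqrt(np[1]^2 + np[2]^2)
  if (inplane < 1e-12) {
    orient <- 0
  } else {
    m_film <- c(-np[2], np[1]) / inplane        # major axis, film frame
    orient <- rad2deg(atan2(-m_film[2], m_film[1])) %% 180
  }
  true_ellipse <- ellipse2d(ctr[1], ctr[2], a = scene$cup_radius, b = b,
                            orientation_deg = orient)
  if (scene$noise_sigma > 0) {
    rs <- with_local_seed(scene$seed, {
      list(rim = matrix(stats::rnorm(length(rim), sd = scene$noise_sigma),
                        ncol = 2),
           lmk = matrix(stats::rnorm(length(lmp), sd = scene$noise_sigma),
                        ncol = 2))
    })
    rim <- rim + rs$rim
    lmp <- lmp + rs$lmk
  }
  structure(list(
    landmarks = pelvic_landmarks(symphysis = lmp["symphysis", ],
                                 scj = lmp["scj", ],
                                 teardrop_l = lmp["teardrop_l", ],
                                 teardrop_r = lmp["teardrop_r", ]),
    rim_points = rim,
    true_ellipse = true_ellipse,
    scene = scene),
    class = "synthetic_film")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## evaluate expr under a temporary RNG state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Convert a synthetic film to an annotation
#'
#' Emits the same structure \code{\link{measure_film}} and
#' \code{\link{write_annotation}} consume, so simulated films flow
#' through the identical measurement path as real annotations. The
#' annotation's \code{apparent_version} flag is filled from the scene's
#' ground truth (whether the posed cup axis points anteriorly or
#' posteriorly), the information an informed annotator supplies from a
#' lateral view or the cup marker.
#'
#' @param film a \code{synthetic_film} from \code{\link{project_scene}}.
#' @return an \code{\link{annotation}} object.
#' @export
film_annotation <- function(film) {
  stopifnot(inherits(film, "synthetic_film"))
  sc <- film$scene
  n_posed <- as.numeric(pose_matrix(sc$pose) %*%
                          cup_axis(sc$anteversion_deg, sc$inclination_deg,
                                   sc$side))
  annotation(film_id = sc$film_id, side = sc$side,
             landmarks = film$landmarks, rim_points = film$rim_points,
             apparent_version = if (n_posed[3] >= 0) "ante" else "retro")
}

#' Generate a reproducible cohort of synthetic films
#'
#' Samples scene parameters uniformly from the stated ranges under a
#' single seed and projects each scene. The default ranges are the study
#' conditions used throughout the validation: anteversion 5-60,
#' inclination 30-60, tilt -15..15, axial rotation -10..10 degrees.
#'
#' @param n_films number of films, >= 1.
#' @param ranges named list of length-2 min/max ranges for
#'   \code{anteversion}, \code{inclination}, \code{theta}, \code{phi}
#'   (degrees). A degenerate range (min == max) fixes the parameter.
#' @param seed integer seed; the whole batch is reproducible from it.
#' @param noise_sigma annotation noise (pixels) applied per film.
#' @param sides candidate sides sampled per film.
#' @param patients optional number of patients: films are assigned
#'   round-robin; films of one patient share the anatomical parameters
#'   (anteversion, inclination, side) and differ only in pose and noise —
#'   the repeated-radiograph setting the RSD statistic is designed for.
#' @param ... further arguments passed to \code{\link{cup_scene}}.
#' @return list with \code{films} (list of \code{synthetic_film}) and
#'   \code{truth} (data.frame pairing each film with its generating
#'   parameters).
#' @export
generate_cohort <- function(n_films,
                            ranges = list(anteversion = c(5, 60),
                                          inclination = c(30, 60),
                                          theta = c(-15, 15),
                                          phi = c(-10, 10)),
                            seed = 1L,
                            noise_sigma = 0,
                            sides = c("left", "right"),
                            patients = NULL, ...) {
  check_num(n_films, "n_films", 1)
  n_films <- as.integer(n_films)
  if (n_films < 1) stop("n_films must be >= 1", call. = FALSE)
  for (nm in c("anteversion", "inclination", "theta", "phi")) {
    r <- ranges[[nm]]
    if (is.null(r) || length(r) != 2 || r[1] > r[2])
      stop(sprintf("range '%s' must be c(min, max) with min <= max", nm),
           call. = FALSE)
  }
  runif_rng <- function(n, r) if (r[1] == r[2]) rep(r[1], n)
                              else stats::runif(n, r[1], r[2])
  pars <- with_local_seed(seed, {
    n_anat <- if (is.null(patients)) n_films else as.integer(patients)
    anat <- data.frame(
      anteversion = runif_rng(n_anat, ranges$anteversion),
      inclination = runif_rng(n_anat, ranges$inclination),
      side = sample(sides, n_anat, replace = TRUE))
    idx <- if (is.null(patients)) seq_len(n_films)
           else rep_len(seq_len(n_anat), n_films)
    data.frame(
      film_id = sprintf("film%03d", seq_len(n_films)),
      patient_id = sprintf("pat%03d", idx),
      anteversion = anat$anteversion[idx],
      inclination = anat$inclination[idx],
      side = anat$side[idx],
      theta = runif_rng(n_films, ranges$theta),
      phi = runif_rng(n_films, ranges$phi),
      film_seed = sample.int(.Machine$integer.max, n_films),
      stringsAsFactors = FALSE)
  })
  films <- lapply(seq_len(n_films), function(i) {
    sc <- cup_scene(anteversion_deg = pars$anteversion[i],
                    inclination_deg = pars$inclination[i],
                    theta_deg = pars$theta[i], phi_deg = pars$phi[i],
                    side = pars$side[i],
                    noise_sigma = noise_sigma,
                    seed = if (noise_sigma > 0) pars$film_seed[i] else NULL,
                    film_id = pars$film_id[i], ...)
    project_scene(sc)
  })
  list(films = films, truth = pars)
}
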