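#' Film annotation
#'
#' One annotated film: the four pelvic landmarks, the measured side, and
#' the cup rim as either clicked rim points (>= 5) or an explicit
#' ellipse. Coordinates are 0-based image pixels, y increasing downward.
#'
#' @param film_id identifier string.
#' @param side `"left"` or `"right"`.
#' @param landmarks a \code{\link{pelvic_landmarks}}.
#' @param rim_points optional n x 2 matrix of rim coordinates.
#' @param ellipse optional explicit \code{\link{ellipse2d}}; exactly one
#'   of \code{rim_points} / \code{ellipse} must be given.
#' @param apparent_version \code{"ante"} (default) or \code{"retro"}:
#'   whether the projected cup axis points anteriorly or posteriorly on
#'   this film. Not decidable from the ellipse itself; supplied by the
#'   annotator (e.g. from a lateral view or the cup marker) and consumed
#'   by \code{\link{standardized_anteversion}}.
#' @return object of class \code{cup_annotation}.
#' @export
annotation <- function(film_id, side = c("left", "right"),
                       landmarks, rim_points = NULL, ellipse = NULL,
                       apparent_version = c("ante", "retro")) {
  side <- match.arg(side)
  apparent_version <- match.arg(apparent_version)
  stopifnot(inherits(landmarks, "pelvic_landmarks"))
  if (is.null(rim_points) && is.null(ellipse))
    stop("annotation needs either rim_points or an explicit ellipse",
         call. = FALSE)
  if (!is.null(rim_points)) {
    rim_points <- as.matrix(rim_points)
    if (ncol(rim_points) != 2 || !is.numeric(rim_points))
      stop("rim_points must be an n x 2 numeric matrix", call. = FALSE)
    colnames(rim_points) <- c("x", "y")
  }
  if (!is.null(ellipse)) stopifnot(inherits(ellipse, "ellipse2d"))
  structure(list(film_id = as.character(film_id), side = side,
                 landmarks = landmarks, rim_points = rim_points,
                 ellipse = ellipse, apparent_version = apparent_version),
            class = "cup_annotation")
}

lm_fields <- c(symphysis = "symphysis", scj = "scj",
               teardrop_l = "teardrop_l", teardrop_r = "teardrop_r")

annotation_from_list <- function(x) {
  for (f in c("film_id", "side", "landmarks"))
    if (is.null(x[[f]])) stop(sprintf("annotation missing field '%s'", f),
                              call. = FALSE)
  lk <- x$landmarks
  for (f in lm_fields)
    if (is.null(lk[[f]]) || length(lk[[f]]) != 2 || anyNA(lk[[f]]))
      stop(sprintf("annotation missing or malformed landmark '%s'", f),
           call. = FALSE)
  lm <- pelvic_landmarks(as.numeric(lk$symphysis), as.numeric(lk$scj),
                         as.numeric(lk$teardrop_l), as.numeric(lk$teardrop_r))
  cup <- x$cup
  if (is.null(cup) || (is.null(cup$rim_points) && is.null(cup$ellipse)))
    stop("annotation missing field 'cup' (rim_points or ellipse)",
         call. = FALSE)
  rim <- NULL; ell <- NULL
  if (!is.null(cup$rim_points)) {
    rim <- cup$rim_points
    if (is.list(rim) && !is.data.frame(rim)) rim <- do.call(rbind, rim)
    rim <- matrix(as.numeric(as.matrix(rim)), ncol = 2)
  } else {
    e <- cup$ellipse
    for (f in c("cx", "cy", "a", "b", "orientation_deg"))
      if (is.null(e[[f]])) stop(sprintf("ellipse missing field '%s'", f),
                                call. = FALSE)
    ell <- ellipse2d(e$cx, e$cy, e$a, e$b, e$orientation_deg)
  }
  annotation(x$film_id, x$side, lm, rim_points = rim, ellipse = ell,
             apparent_version = x$apparent_version %||% "ante")
}

annotation_to_list <- function(ann) {
  out <- list(film_id = ann$film_id, side = ann$side,
              apparent_version = ann$apparent_version,
              landmarks = lapply(unclass(ann$landmarks), as.numeric))
  out$cup <- if (!is.null(ann$rim_points)) {
    list(rim_points = unname(apply(ann$rim_points, 1, as.numeric,
                                   simplify = FALSE)))
  } else {
    e <- ann$ellipse
    list(ellipse = list(cx = e$cx, cy = e$cy, a = e$a, b = e$b,
                        orientation_deg = e$orientation_deg))
  }
  out
}

#' Read film annotations (JSON or CSV)
#'
#' JSON schema: \code{{film_id, side, landmarks: {symphysis: [x, y], scj,
#' teardrop_l, teardrop_r}, cup: {rim_points: [[x, y], ...]} | {ellipse:
#' {cx, cy, a, b, orientation_deg}}}}, either a single object or an array
#' of them. CSV schema: one row per point with columns \code{film_id,
#' side, point_type, x, y}, \code{point_type} in \{symphysis, scj,
#' teardrop_l, teardrop_r, rim\}. Coordinates are 0-based pixels, y
#' downward.
#'
#' @param path file path ending in .json or .csv.
#' @return a single \code{\link{annotation}} if the file holds one film,
#'   else a named list of annotations.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  anns <- switch(ext,
    json = {
      x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
      if (!is.null(x$film_id)) list(annotation_from_list(x))
      else lapply(x, annotation_from_list)
    },
    csv = {
      df <- utils::read.csv(path, stringsAsFactors = FALSE)
      need <- c("film_id", "side", "point_type", "x", "y")
      miss <- setdiff(need, names(df))
      if (length(miss))
        stop(sprintf("annotation CSV missing column(s): %s",
                     paste(miss, collapse = ", ")), call. = FALSE)
      lapply(split(df, df$film_id), csv_group_to_annotation)
    },
    stop(sprintf("unsupported annotation format '.%s' (use .json or .csv)",
                 ext), call. = FALSE))
  names(anns) <- vapply(anns, function(a) a$film_id, "")
  if (length(anns) == 1) anns[[1]] else anns
}

csv_group_to_annotation <- function(df) {
  one <- function(type) {
    r <- df[df$point_type == type, , drop = FALSE]
    if (nrow(r) == 0)
      stop(sprintf("annotation missing or malformed landmark '%s'", type),
           call. = FALSE)
    c(r$x[1], r$y[1])
  }
  lm <- pelvic_landmarks(one("symphysis"), one("scj"),
                         one("teardrop_l"), one("teardrop_r"))
  rim <- df[df$point_type == "rim", c("x", "y"), drop = FALSE]
  if (nrow(rim) == 0) stop("annotation CSV has no rim points", call. = FALSE)
  annotation(df$film_id[1], df$side[1], lm, rim_points = as.matrix(rim),
             apparent_version = if ("apparent_version" %in% names(df))
               df$apparent_version[1] else "ante")
}

#' Write film annotations (JSON or CSV)
#'
#' Inverse of \code{\link{read_annotation}}; write followed by read is
#' lossless.
#'
#' @param ann an \code{\link{annotation}} or list of them.
#' @param path output path ending in .json or .csv.
#' @return \code{path}, invisibly.
#' @export
write_annotation <- function(ann, path) {
  if (inherits(ann, "cup_annotation")) ann <- list(ann)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    payload <- lapply(ann, annotation_to_list)
    if (length(payload) == 1) payload <- payload[[1]]
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else if (ext == "csv") {
    rows <- do.call(rbind, lapply(ann, function(a) {
      if (is.null(a$rim_points))
        stop("CSV annotations require rim points (no explicit-ellipse form)",
             call. = FALSE)
      lm <- a$landmarks
      rbind(
        data.frame(film_id = a$film_id, side = a$side,
                   apparent_version = a$apparent_version,
                   point_type = names(lm_fields),
                   x = vapply(lm_fields, function(f) lm[[f]][1], 0),
                   y = vapply(lm_fields, function(f) lm[[f]][2], 0)),
        data.frame(film_id = a$film_id, side = a$side,
                   apparent_version = a$apparent_version, point_type = "rim",
                   x = a$rim_points[, 1], y = a$rim_points[, 2]))
    }))
    utils::write.csv(format_num_df(rows), path, row.names = FALSE,
                     quote = FALSE)
  } else {
    stop(sprintf("unsupported annotation format '.%s'", ext), call. = FALSE)
  }
  invisible(path)
}

## fixed 6-decimal formatting keeps CSV output byte-reproducible
format_num_df <- function(df) {
  for (nm in names(df))
    if (is.numeric(df[[nm]])) df[[nm]] <- sprintf("%.6f", df[[nm]])
  df
}

#' Write measurement records to CSV
#'
#' Numeric columns are written with exactly 6 decimal places so that
#' repeated runs with the same seed are byte-identical.
#'
#' @param records a \code{measurement_record} or list of them.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_measurements <- function(records, path) {
  utils::write.csv(format_num_df(records_table(records)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a measurement series for precision statistics
#'
#' CSV with at least columns \code{patient_id} and
#' \code{anteversion_deg}; typically also \code{film_id, observer_id,
#' session_id, method}.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_measurement_series <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("patient_id", "anteversion_deg"), names(df))
  if (length(miss))
    stop(sprintf("measurement series missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  df
}

#' Read a radiograph image (PNG or DICOM)
#'
#' PNG files carry no physical calibration; a pixel spacing of 1 px is
#' assumed with a warning. DICOM files are read by the package's minimal
#' reader (uncompressed explicit-VR little endian) and PixelSpacing is
#' honored when present.
#'
#' @param path image path (.png, .dcm/.dicom).
#' @return list with \code{pixels} (numeric matrix, rows = image rows),
#'   \code{spacing} (length-2, physical units per pixel, row then
#'   column), \code{unit} ("mm" or "px") and \code{source}.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- png::readPNG(path)
    if (length(dim(px)) == 3) px <- px[, , 1]
    warning("PNG carries no pixel spacing; using 1 px", call. = FALSE)
    list(pixels = px, spacing = c(1, 1), unit = "px", source = "png")
  } else if (ext %in% c("dcm", "dicom")) {
    read_dicom(path)
  } else {
    stop(sprintf("unsupported image format '.%s' (use .png or .dcm)", ext),
         call. = FALSE)
  }
}
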