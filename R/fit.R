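#' Conic coefficients
#'
#' Coefficients of the conic \eqn{Ax^2 + Bxy + Cy^2 + Dx + Ey + F = 0},
#' defined up to scale and normalized so that \eqn{A + C = 1} when
#' \eqn{A + C \neq 0}. The conic is an ellipse iff \eqn{B^2 - 4AC < 0};
#' the constructor stores any conic, and \code{\link{conic_to_geometric}}
#' enforces ellipse-ness.
#'
#' @param A,B,C,D,E,F real coefficients.
#' @return named numeric vector of class \code{conic}.
#' @export
conic_coefficients <- function(A, B, C, D, E, F) {
  v <- c(A = A, B = B, C = C, D = D, E = E, F = F)
  check_num(v, "conic coefficients", 6)
  if (all(v == 0)) stop("all conic coefficients are zero", call. = FALSE)
  s <- A + C
  if (s != 0) v <- v / s
  structure(v, class = "conic")
}

#' Convert conic coefficients to geometric ellipse parameters
#'
#' Center from the stationary point of the quadratic, semi-axes and
#' orientation from the eigen-decomposition of the quadratic form
#' \eqn{[[A, B/2], [B/2, C]]}. Errors unless the conic is a real,
#' non-degenerate ellipse (\eqn{B^2 - 4AC < 0}).
#'
#' @param conic a \code{\link{conic_coefficients}} object (or a named
#'   numeric vector A..F).
#' @return an \code{\link{ellipse2d}} with \code{a >= b} and orientation
#'   in [0, 180).
#' @export
conic_to_geometric <- function(conic) {
  v <- as.numeric(conic)
  if (length(v) != 6) stop("conic must have 6 coefficients", call. = FALSE)
  A <- v[1]; B <- v[2]; C <- v[3]; D <- v[4]; E <- v[5]; F <- v[6]
  disc <- B^2 - 4 * A * C
  if (!(disc < 0)) stop("conic is not an ellipse (B^2 - 4AC >= 0)", call. = FALSE)
  ## center: gradient of the quadratic vanishes
  M <- matrix(c(2 * A, B, B, 2 * C), 2, 2)
  ctr <- solve(M, -c(D, E))
  ## constant after recentering (gradient is zero there)
  F0 <- F + (D * ctr[1] + E * ctr[2]) / 2
  Q <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  eg <- eigen(Q, symmetric = TRUE)           # eigenvalues decreasing
  ax2 <- -F0 / eg$values                     # squared semi-axes
  if (any(ax2 <= 0)) stop("conic is a degenerate or imaginary ellipse",
                          call. = FALSE)
  i_major <- which.max(ax2)
  a <- sqrt(ax2[i_major]); b <- sqrt(min(ax2))
  major <- eg$vectors[, i_major]
  ang <- rad2deg(atan2(major[2], major[1])) %% 180
  ellipse2d(ctr[1], ctr[2], a = a, b = b, orientation_deg = ang)
}

## implicit ellipse equation residual: ((x'/a)^2 + (y'/b)^2) - 1 in the
## ellipse's own frame; zero on the ellipse. Used by tests and span checks.
ellipse_implicit <- function(ellipse, points) {
  o <- deg2rad(ellipse$orientation_deg)
  dx <- points[, 1] - ellipse$cx
  dy <- points[, 2] - ellipse$cy
  xl <- dx * cos(o) + dy * sin(o)
  yl <- -dx * sin(o) + dy * cos(o)
  (xl / ellipse$a)^2 + (yl / ifelse(ellipse$b > 0, ellipse$b, NA))^2 - 1
}

#' Fit an ellipse to annotated rim points
#'
#' Direct least-squares conic fit constrained to an ellipse
#' (Fitzgibbon's constraint \eqn{4AC - B^2 = 1}, solved with the
#' numerically stable block decomposition of Halir and Flusser), applied
#' to the cup-rim points clicked by the annotator. The constraint
#' guarantees an ellipse even for noisy partial arcs, the typical case
#' when the femoral head obscures part of the rim. Points are centered
#' and isotropically scaled before fitting for conditioning.
#'
#' A warning is issued when the points span less than 120 degrees of arc
#' around the fitted center, where the fit variance grows sharply.
#'
#' @param points an \code{n x 2} matrix (or data.frame) of image
#'   coordinates, \code{n >= 5}, not all collinear.
#' @return an \code{\link{ellipse2d}}; attribute \code{fit_rms} holds the
#'   root-mean-square Sampson (approximate geometric) residual in pixels,
#'   attribute \code{arc_span_deg} the angular span of the points about
#'   the fitted center.
#' @references Halir, R. and Flusser, J. (1998) Numerically stable direct
#'   least squares fitting of ellipses.
#' @export
fit_ellipse <- function(points) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 2)
    stop("'points' must be an n x 2 numeric matrix", call. = FALSE)
  if (anyNA(points) || any(!is.finite(points)))
    stop("'points' must be finite", call. = FALSE)
  n <- nrow(points)
  if (n < 5) stop("ellipse fitting needs at least 5 points", call. = FALSE)
  ctr <- colMeans(points)
  Z <- sweep(points, 2, ctr)
  sv <- svd(Z, nu = 0, nv = 0)$d
  if (sv[2] < 1e-10 * max(sv[1], 1))
    stop("points are collinear or coincident: no ellipse is defined",
         call. = FALSE)
  s <- sqrt(mean(rowSums(Z^2)) / 2)
  Z <- Z / s
  x <- Z[, 1]; y <- Z[, 2]
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  T <- -solve(S3, t(S2))
  M <- S1 + S2 %*% T
  ## premultiply by inverse of constraint matrix C1 = [[0,0,2],[0,-1,0],[2,0,0]]
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  eg <- eigen(M)
  vecs <- Re(eg$vectors)
  cond <- 4 * vecs[1, ] * vecs[3, ] - vecs[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0)
    stop("no ellipse solution: input is degenerate", call. = FALSE)
  a1 <- vecs[, ok[1]]
  a2 <- as.numeric(T %*% a1)
  co_n <- c(a1, a2)                          # conic in normalized coordinates
  e_n <- conic_to_geometric(co_n)
  e <- ellipse2d(ctr[1] + s * e_n$cx, ctr[2] + s * e_n$cy,
                 a = s * e_n$a, b = s * e_n$b,
                 orientation_deg = e_n$orientation_deg)
  ## Sampson residuals in pixel units
  xs <- points[, 1]; ys <- points[, 2]
  co <- conic_px(co_n, ctr, s)
  Qv <- co[1] * xs^2 + co[2] * xs * ys + co[3] * ys^2 +
    co[4] * xs + co[5] * ys + co[6]
  gx <- 2 * co[1] * xs + co[2] * ys + co[4]
  gy <- co[2] * xs + 2 * co[3] * ys + co[5]
  g <- sqrt(gx^2 + gy^2)
  res <- ifelse(g > 0, abs(Qv) / g, 0)
  attr(e, "fit_rms") <- sqrt(mean(res^2))
  ## angular span of the annotations about the fitted center
  ang <- sort(atan2(ys - e$cy, xs - e$cx))
  gaps <- diff(c(ang, ang[1] + 2 * pi))
  span <- rad2deg(2 * pi - max(gaps))
  attr(e, "arc_span_deg") <- span
  if (span < 120)
    warning(sprintf(
      "rim points span only %.0f deg of arc; fitted parameters may be unstable",
      span), call. = FALSE)
  e
}

## de-normalize conic coefficients: x_n = (x - cx)/s, y_n = (y - cy)/s
conic_px <- function(co, ctr, s) {
  A <- co[1]; B <- co[2]; C <- co[3]; D <- co[4]; E <- co[5]; F <- co[6]
  cx <- ctr[1]; cy <- ctr[2]
  c(A / s^2,
    B / s^2,
    C / s^2,
    (-2 * A * cx - B * cy) / s^2 + D / s,
    (-B * cx - 2 * C * cy) / s^2 + E / s,
    (A * cx^2 + B * cx * cy + C * cy^2) / s^2 - (D * cx + E * cy) / s + F)
}
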