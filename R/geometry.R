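# Cone-beam (central) projection of points and spheres onto the detector plane.
#
# View-frame convention used throughout the package: the X-ray source (focus)
# sits at the origin, the central beam runs along +z, and the detector plane is
# z = sdd_mm. Image coordinates are 2D positions in mm on the detector with the
# origin at the principal point (intersection of the central beam with the
# detector). The plane magnification of the coronal plane z = z0 is sdd/z0.

#' Beam geometry of a point-source radiograph
#'
#' @param sdd_mm Focus-detector distance in mm (source to detector plane along
#'   the central beam). The study setting is 1150 mm.
#'
#' @return An object of class `beam_geometry`.
#' @export
#' @examples
#' g <- beam_geometry(1150)
#' plane_cf(908, g)
beam_geometry <- function(sdd_mm = 1150) {
  if (!is.numeric(sdd_mm) || length(sdd_mm) != 1L || !is.finite(sdd_mm) ||
      sdd_mm <= 0) {
    stop("`sdd_mm` must be a single positive number (mm)", call. = FALSE)
  }
  structure(list(sdd_mm = as.numeric(sdd_mm)), class = "beam_geometry")
}

#' @export
print.beam_geometry <- function(x, ...) {
  cat(sprintf("<beam_geometry> focus-detector distance %.1f mm\n", x$sdd_mm))
  invisible(x)
}

#' Sphere in the view frame
#'
#' @param center Numeric length-3 position (mm) of the sphere centre in the
#'   view frame (source at origin, +z toward the detector).
#' @param diameter_mm True sphere diameter in mm.
#'
#' @return An object of class `sphere3d`.
#' @export
sphere3d <- function(center, diameter_mm) {
  if (!is.numeric(center) || length(center) != 3L || any(!is.finite(center))) {
    stop("`center` must be a finite numeric vector of length 3", call. = FALSE)
  }
  if (!is.numeric(diameter_mm) || length(diameter_mm) != 1L ||
      !is.finite(diameter_mm) || diameter_mm <= 0) {
    stop("`diameter_mm` must be a single positive number", call. = FALSE)
  }
  structure(list(center = as.numeric(center),
                 diameter_mm = as.numeric(diameter_mm)),
            class = "sphere3d")
}

.check_sphere_in_beam <- function(s, g) {
  r <- s$diameter_mm / 2
  z <- s$center[3]
  if (z - r <= 0) {
    stop("sphere must lie entirely on the detector side of the source ",
         "(center depth - radius must be positive)", call. = FALSE)
  }
  if (z + r >= g$sdd_mm) {
    stop("sphere must lie entirely between source and detector", call. = FALSE)
  }
  invisible(TRUE)
}

#' Project a point through the focus onto the detector
#'
#' Pinhole projection underlying all distance measurements: a point (x, y, z)
#' with 0 < z < sdd maps to (x, y) * sdd / z in image coordinates.
#'
#' @param p Numeric length-3 point, or an n x 3 matrix of points (view frame).
#' @param g A [beam_geometry()].
#'
#' @return A length-2 image point (mm), or an n x 2 matrix.
#' @export
project_point <- function(p, g) {
  stopifnot(inherits(g, "beam_geometry"))
  if (is.matrix(p)) {
    if (ncol(p) != 3L) stop("point matrix must have 3 columns", call. = FALSE)
    z <- p[, 3]
    if (any(!is.finite(z)) || any(z <= 0) || any(z > g$sdd_mm)) {
      stop("point depth must satisfy 0 < z <= sdd", call. = FALSE)
    }
    return(cbind(p[, 1] * g$sdd_mm / z, p[, 2] * g$sdd_mm / z))
  }
  if (!is.numeric(p) || length(p) != 3L || any(!is.finite(p))) {
    stop("`p` must be a finite numeric vector of length 3", call. = FALSE)
  }
  if (p[3] <= 0 || p[3] > g$sdd_mm) {
    stop("point depth must satisfy 0 < z <= sdd", call. = FALSE)
  }
  c(p[1], p[2]) * g$sdd_mm / p[3]
}

# Conic coefficients of the tangent-cone / detector-plane intersection.
# Cone: apex at the source, unit axis `u`, half-angle alpha with k = cos^2
# alpha; points p satisfy (p . u)^2 = k |p|^2. Substituting p = (x, y, sdd)
# gives a conic in image coordinates: x' A x + 2 b . x + c0 = 0.
.cone_conic <- function(u, k, sdd) {
  A <- matrix(c(u[1]^2 - k, u[1] * u[2],
                u[1] * u[2], u[2]^2 - k), 2L, 2L)
  b <- c(u[1] * u[3] * sdd, u[2] * u[3] * sdd)
  c0 <- u[3]^2 * sdd^2 - k * sdd^2
  list(A = A, b = b, c0 = c0)
}

# Centre, semi-axes and axis directions of the ellipse x' A x + 2 b.x + c0 = 0.
.conic_ellipse <- function(A, b, c0) {
  xc <- solve(A, -b)
  G <- -(sum(b * xc) + c0)           # (x - xc)' A (x - xc) = G
  e <- eigen(A, symmetric = TRUE)
  semi <- sqrt(G / e$values)          # both values share the sign of G
  if (any(!is.finite(semi))) {
    stop("cone does not intersect the detector in an ellipse", call. = FALSE)
  }
  i_maj <- which.max(semi)
  list(center = xc,
       semi_major = semi[i_maj],
       semi_minor = semi[-i_maj][1],
       major_dir = e$vectors[, i_maj])
}

.new_projected_ellipse <- function(center_xy, major, minor, major_dir) {
  structure(list(center_xy = as.numeric(center_xy),
                 major_axis_mm = as.numeric(major),
                 minor_axis_mm = as.numeric(minor),
                 major_dir = as.numeric(major_dir)),
            class = "projected_ellipse")
}

#' @export
print.projected_ellipse <- function(x, ...) {
  cat(sprintf(
    "<projected_ellipse> center (%.3f, %.3f) mm; axes %.3f x %.3f mm\n",
    x$center_xy[1], x$center_xy[2], x$major_axis_mm, x$minor_axis_mm))
  invisible(x)
}

#' Analytic shadow of a sphere under cone-beam projection
#'
#' Computes the outline of the tangent cone from the source to the sphere,
#' intersected with the detector plane. With `d` the source-to-centre
#' distance, `alpha = asin(r/d)` the cone half-angle and `theta` the angle
#' between the central beam and the source-to-centre ray, the radial extent of
#' the shadow spans `sdd * tan(theta - alpha)` to `sdd * tan(theta + alpha)`.
#' The ellipse centre therefore sits at radial distance
#' `sdd * (tan(theta + alpha) + tan(theta - alpha)) / 2`, which is farther from
#' the principal point than the projection of the sphere centre itself -- the
#' outward bias the iterative calibration solver has to absorb. The minor axis
#' is extracted from the conic of the cone/detector intersection.
#'
#' @param s A [sphere3d()].
#' @param g A [beam_geometry()].
#'
#' @return An object of class `projected_ellipse` with fields `center_xy`,
#'   `major_axis_mm`, `minor_axis_mm` (full axis lengths) and `major_dir`
#'   (unit 2D direction of the long axis, always radial).
#' @export
#' @examples
#' g <- beam_geometry(1150)
#' project_sphere(sphere3d(c(0, 0, 908), 32), g)  # on-axis: a circle
project_sphere <- function(s, g) {
  stopifnot(inherits(s, "sphere3d"), inherits(g, "beam_geometry"))
  .check_sphere_in_beam(s, g)
  sdd <- g$sdd_mm
  r <- s$diameter_mm / 2
  d <- sqrt(sum(s$center^2))
  alpha <- asin(r / d)
  theta <- acos(s$center[3] / d)
  if (theta + alpha >= pi / 2) {
    stop("tangent cone does not intersect the detector within numeric limits",
         call. = FALSE)
  }
  t_out <- tan(theta + alpha)
  t_in <- tan(theta - alpha)
  major <- sdd * (t_out - t_in)
  center_radial <- sdd * (t_out + t_in) / 2
  rho_xy <- sqrt(sum(s$center[1:2]^2))
  u_rad <- if (rho_xy > 0) s$center[1:2] / rho_xy else c(1, 0)

  # minor axis from the conic form of the cone/plane intersection
  u_axis <- s$center / d
  con <- .cone_conic(u_axis, cos(alpha)^2, sdd)
  ell <- .conic_ellipse(con$A, con$b, con$c0)

  .new_projected_ellipse(u_rad * center_radial, major,
                         2 * ell$semi_minor, u_rad)
}

#' Sampling oracle for the sphere shadow
#'
#' Independent validation path for [project_sphere()]: samples the tangency
#' (silhouette) circle of the sphere -- the locus of points where source rays
#' graze the surface -- projects every sample onto the detector, and fits a
#' general conic to the projected boundary by least squares. Used in tests
#' only; it shares no trigonometric shortcut with the analytic projection.
#'
#' @param s A [sphere3d()].
#' @param g A [beam_geometry()].
#' @param n_samples Number of boundary samples (at least 1e4).
#'
#' @return An object of class `projected_ellipse`.
#' @export
shadow_oracle <- function(s, g, n_samples = 1e4) {
  stopifnot(inherits(s, "sphere3d"), inherits(g, "beam_geometry"))
  if (n_samples < 1e4) stop("`n_samples` must be at least 1e4", call. = FALSE)
  .check_sphere_in_beam(s, g)
  r <- s$diameter_mm / 2
  cc <- s$center
  d <- sqrt(sum(cc^2))
  # tangency circle: centre cc*(1 - r^2/d^2), radius r*sqrt(d^2-r^2)/d,
  # lying in the plane perpendicular to the source->centre ray
  ct <- cc * (1 - r^2 / d^2)
  rt <- r * sqrt(d^2 - r^2) / d
  ax <- cc / d
  ref <- if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * ax) * ax
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(ax[2] * e1[3] - ax[3] * e1[2],
          ax[3] * e1[1] - ax[1] * e1[3],
          ax[1] * e1[2] - ax[2] * e1[1])
  psi <- seq(0, 2 * pi, length.out = n_samples + 1L)[-1L]
  pts <- cbind(ct[1] + rt * (cos(psi) * e1[1] + sin(psi) * e2[1]),
               ct[2] + rt * (cos(psi) * e1[2] + sin(psi) * e2[2]),
               ct[3] + rt * (cos(psi) * e1[3] + sin(psi) * e2[3]))
  img <- project_point(pts, g)

  # least-squares conic fit on normalized coordinates
  mu <- colMeans(img)
  xs <- img[, 1] - mu[1]
  ys <- img[, 2] - mu[2]
  sc <- sqrt(mean(xs^2 + ys^2))
  xs <- xs / sc
  ys <- ys / sc
  M <- cbind(xs^2, xs * ys, ys^2, xs, ys, 1)
  v <- eigen(crossprod(M), symmetric = TRUE)$vectors[, 6L]
  A <- matrix(c(v[1], v[2] / 2, v[2] / 2, v[3]), 2L, 2L)
  b <- v[4:5] / 2
  ell <- .conic_ellipse(A, b, v[6])
  .new_projected_ellipse(mu + sc * ell$center,
                         2 * sc * ell$semi_major,
                         2 * sc * ell$semi_minor,
                         ell$major_dir)
}

#' Calibration factor of a coronal plane
#'
#' The calibration (magnification) factor of the plane at depth `z0` is
#' `100 * sdd / z0`, reported as percent: 126 means a 1.26-fold magnification
#' of objects lying in that plane.
#'
#' @param z0_mm Perpendicular source-to-plane depth in mm.
#' @param g A [beam_geometry()].
#'
#' @return Calibration factor in percent.
#' @export
plane_cf <- function(z0_mm, g) {
  stopifnot(inherits(g, "beam_geometry"))
  if (!is.numeric(z0_mm) || any(!is.finite(z0_mm)) || any(z0_mm <= 0) ||
      any(z0_mm > g$sdd_mm)) {
    stop("`z0_mm` must satisfy 0 < z0 <= sdd", call. = FALSE)
  }
  100 * g$sdd_mm / z0_mm
}
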