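# Calibration solvers.
#
# The single-marker solver inverts the sphere-shadow forward model: given the
# measured major axis of the elliptical shadow and the measured radial offset
# of its centre from the principal point, it recovers the source-to-centre
# distance and beam angle of the marker, and hence the calibration factor of
# the coronal plane through the marker centre. The bi-planar solver combines
# an AP and a lateral radiograph of the external marker to transfer that
# calibration factor from the marker plane to the hip plane.

#' Solver settings
#'
#' @param tol_pp Convergence tolerance on the calibration factor, in
#'   percentage points.
#' @param max_iter Iteration cap.
#'
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(tol_pp = 1e-4, max_iter = 100L) {
  if (!is.numeric(tol_pp) || length(tol_pp) != 1L || tol_pp <= 0) {
    stop("`tol_pp` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(max_iter) || length(max_iter) != 1L || max_iter < 1) {
    stop("`max_iter` must be at least 1", call. = FALSE)
  }
  structure(list(tol_pp = as.numeric(tol_pp),
                 max_iter = as.integer(max_iter)),
            class = "solver_settings")
}

.new_calibration_result <- function(cf, marker_cf, depth, iterations,
                                    converged, residual, diagnostics = list()) {
  structure(c(list(cf_percent = cf,
                   marker_plane_cf_percent = marker_cf,
                   est_depth_mm = depth,
                   iterations = as.integer(iterations),
                   converged = isTRUE(converged),
                   residual = residual),
              diagnostics),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> CF %.3f%% (marker plane %.3f%%)\n",
              x$cf_percent, x$marker_plane_cf_percent))
  cat(sprintf("  est. depth %.2f mm; %d iterations; converged: %s; residual %.2e pp\n",
              x$est_depth_mm, x$iterations, x$converged, x$residual))
  invisible(x)
}

# Given theta (as u = tan theta), solve the major-axis equation
#   tan(theta + alpha) - tan(theta - alpha) = M / sdd
# for t = tan alpha. Reduces to the quadratic M u^2 t^2 + 2 s (1+u^2) t - M = 0.
.solve_tan_alpha <- function(major, u, sdd) {
  if (u < 1e-12) return(major / (2 * sdd))
  a <- major * u^2
  b <- 2 * sdd * (1 + u^2)
  (-b + sqrt(b^2 + 4 * a * major)) / (2 * a)
}

# Given alpha (as v = tan alpha), solve the ellipse-centre equation
#   tan(theta + alpha) + tan(theta - alpha) = 2 * rho_c / sdd
# for u = tan theta. Reduces to R v^2 u^2 + 2 (1+v^2) u - R = 0, R = 2 rho_c/s.
.solve_tan_theta <- function(R, v) {
  if (R < 1e-12) return(0)
  if (v < 1e-12) return(R / 2)
  a <- R * v^2
  b <- 2 * (1 + v^2)
  (-b + sqrt(b^2 + 4 * a * R)) / (2 * a)
}

#' Iterative single-marker calibration of the marker's own plane
#'
#' Recovers the calibration factor of the coronal plane through a spherical
#' marker's centre from two image measurements: the full major axis of its
#' elliptical shadow and the radial distance of the shadow's centre from the
#' principal point. Because the shadow centre is biased outward relative to
#' the projected sphere centre, the solution is found by fixed-point
#' iteration, alternating between the major-axis equation (updating the cone
#' half-angle) and the ellipse-centre equation (updating the beam angle),
#' starting from the on-axis closed form. This is the reference method used
#' for the internal calibration marker.
#'
#' @param major_axis_mm Measured full major axis of the shadow (mm).
#' @param radial_offset_mm Measured distance from the principal point to the
#'   shadow centre (mm).
#' @param true_diameter_mm True marker diameter (mm).
#' @param g A [beam_geometry()].
#' @param settings A [solver_settings()].
#'
#' @return A `calibration_result`; `cf_percent` is the calibration factor of
#'   the coronal plane through the marker centre, `est_depth_mm` that plane's
#'   depth.
#' @export
single_marker_plane_cf <- function(major_axis_mm, radial_offset_mm,
                                   true_diameter_mm, g,
                                   settings = solver_settings()) {
  stopifnot(inherits(g, "beam_geometry"), inherits(settings, "solver_settings"))
  if (!is.numeric(major_axis_mm) || length(major_axis_mm) != 1L ||
      !is.finite(major_axis_mm)) {
    stop("`major_axis_mm` must be a single finite number", call. = FALSE)
  }
  if (!is.numeric(radial_offset_mm) || length(radial_offset_mm) != 1L ||
      !is.finite(radial_offset_mm) || radial_offset_mm < 0) {
    stop("`radial_offset_mm` must be a single non-negative number",
         call. = FALSE)
  }
  if (major_axis_mm <= true_diameter_mm) {
    stop("infeasible measurement: shadow major axis (", major_axis_mm,
         " mm) does not exceed the true marker diameter (", true_diameter_mm,
         " mm); magnification below 1 is impossible", call. = FALSE)
  }
  sdd <- g$sdd_mm
  r <- true_diameter_mm / 2

  u <- radial_offset_mm / sdd          # tan(theta) initialisation
  cf_prev <- Inf
  cf <- NA_real_
  converged <- FALSE
  resid <- Inf
  iterations <- settings$max_iter
  for (it in seq_len(settings$max_iter)) {
    v <- .solve_tan_alpha(major_axis_mm, u, sdd)
    if (u * v >= 1) {
      stop("infeasible measurement: tangent cone grazes the detector plane",
           call. = FALSE)
    }
    u <- .solve_tan_theta(2 * radial_offset_mm / sdd, v)
    alpha <- atan(v)
    theta <- atan(u)
    dist <- r / sin(alpha)
    cf <- 100 * sdd / (dist * cos(theta))
    resid <- abs(cf - cf_prev)
    cf_prev <- cf
    if (resid < settings$tol_pp) {
      converged <- TRUE
      iterations <- it
      break
    }
  }
  depth <- 100 * sdd / cf
  if (depth >= sdd) {
    stop("infeasible measurement: solved marker plane lies at or behind ",
         "the detector", call. = FALSE)
  }
  .new_calibration_result(cf, cf, depth, iterations, converged, resid,
                          diagnostics = list(theta_deg = theta * 180 / pi,
                                             source_dist_mm = dist))
}

#' Reference calibration factor from the internal calibration marker
#'
#' Applies the iterative single-marker solver to the internal calibration
#' marker (ICM) measurements of an anteroposterior radiograph: `n` (ICM shadow
#' major axis) and `o` (direct distance image centre to ICM shadow centre).
#' Because the ICM sits at the hip centre, the result is the ground-truth
#' hip-plane calibration factor of the study.
#'
#' @param ap An [ap_measurements()] object.
#' @param icm_diameter_mm True ICM diameter (default 32 mm ball head).
#' @param g A [beam_geometry()].
#' @param settings A [solver_settings()].
#'
#' @return A `calibration_result`.
#' @export
icm_reference_cf <- function(ap, icm_diameter_mm = 32, g,
                             settings = solver_settings()) {
  stopifnot(inherits(ap, "ap_measurements"))
  if (is.na(ap$n) || is.na(ap$o)) {
    stop("ICM measurements `n` and `o` must be present", call. = FALSE)
  }
  single_marker_plane_cf(ap$n, ap$o, icm_diameter_mm, g, settings)
}

#' Estimate subject rotation from the lateral radiograph
#'
#' In a strictly lateral radiograph the two hip centres superimpose; rotation
#' of the subject separates their projections horizontally by `c`. The
#' rotation angle is recovered as `asin((c / lat_mag) / inter_hip_true)`,
#' demagnifying `c` with the external marker's own lateral magnification.
#'
#' @param c_mm Measured horizontal distance between the projected hip centres
#'   (mm).
#' @param inter_hip_true_mm True distance between the hip centres (mm).
#' @param lat_mag Lateral magnification used to demagnify `c` (greater than
#'   1, e.g. the external marker's plane magnification).
#'
#' @return Rotation angle in degrees.
#' @export
estimate_rotation <- function(c_mm, inter_hip_true_mm, lat_mag) {
  if (!is.numeric(c_mm) || length(c_mm) != 1L || c_mm < 0) {
    stop("`c_mm` must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(lat_mag) || length(lat_mag) != 1L || lat_mag <= 1) {
    stop("`lat_mag` must exceed 1", call. = FALSE)
  }
  if (!is.numeric(inter_hip_true_mm) || length(inter_hip_true_mm) != 1L ||
      inter_hip_true_mm <= 0) {
    stop("`inter_hip_true_mm` must be positive", call. = FALSE)
  }
  arg <- (c_mm / lat_mag) / inter_hip_true_mm
  if (arg > 1.05) {
    stop("inconsistent measurement: demagnified hip-centre separation ",
         "exceeds the true inter-hip distance by more than 5%", call. = FALSE)
  }
  asin(min(max(arg, 0), 1)) * 180 / pi
}

#' Estimate the marker's anterior offset from the hip plane
#'
#' Inverts the lateral measurement `d` (horizontal distance from the imaged
#' hip centre to the external marker's shadow centre) into the true anterior
#' distance between the marker centre and the coronal plane through the hip
#' centre. Under subject rotation `phi`, the marker's left-right separation
#' from the lateral beam axis couples into the horizontal image coordinate,
#' so the inversion is
#' `delta = (d / lat_ecm_mag - lateral_sep * sin(phi)) / cos(phi)`.
#'
#' @param d_mm Measured horizontal hip-centre-to-marker distance (mm).
#' @param lat_ecm_mag Lateral magnification of the marker's own plane (> 1).
#' @param rotation_deg Subject rotation in degrees (|rotation| < 45).
#' @param lateral_sep_mm True left-right separation between the marker and
#'   the lateral beam axis through the imaged hip centre (mm); with the
#'   marker offset laterally from the midline on the side away from the
#'   source this is `inter_hip/2 + lateral offset`.
#'
#' @return Anterior offset in mm.
#' @export
estimate_anterior_offset <- function(d_mm, lat_ecm_mag, rotation_deg,
                                     lateral_sep_mm) {
  if (!is.numeric(d_mm) || length(d_mm) != 1L || d_mm < 0) {
    stop("`d_mm` must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(lat_ecm_mag) || length(lat_ecm_mag) != 1L ||
      lat_ecm_mag <= 1) {
    stop("`lat_ecm_mag` must exceed 1", call. = FALSE)
  }
  if (abs(rotation_deg) >= 45) {
    stop("`rotation_deg` must satisfy |rotation| < 45", call. = FALSE)
  }
  if (lateral_sep_mm < 0) {
    stop("`lateral_sep_mm` must be non-negative", call. = FALSE)
  }
  phi <- rotation_deg * pi / 180
  (d_mm / lat_ecm_mag - lateral_sep_mm * sin(phi)) / cos(phi)
}

#' Bi-planar external-marker calibration of the hip plane
#'
#' The bi-planar method: a spherical external calibration marker (ECM) of
#' known diameter is radiographed in an anteroposterior (AP) and a lateral
#' view. The AP view yields the calibration factor of the marker's own
#' coronal plane; the lateral view yields the marker's anterior offset from
#' the hip plane, corrected for subject rotation. The hip-plane calibration
#' factor follows from shifting the marker-plane depth by the anterior
#' offset. The staged reconstruction iterates to a fixed point:
#'
#' 1. AP solve of the ECM shadow (`k`, `h`) gives `cf_E` and the marker-plane
#'    depth `z_E`.
#' 2. Lateral solve of the ECM shadow (`b`, `a`) gives the marker's lateral
#'    magnification.
#' 3. Starting from `cf_hip = cf_E`, repeat: demagnify the inter-hip distance
#'    `m` with `cf_hip`; estimate rotation from `c`; demagnify the marker's
#'    midline offset `i` with `cf_E`; invert `d` into the anterior offset;
#'    set `cf_hip = 100 * sdd / (z_E + delta)`; until the change falls below
#'    tolerance.
#'
#' @param ap An [ap_measurements()] object.
#' @param lat A [lateral_measurements()] object.
#' @param ecm_diameter_mm True ECM diameter (default 25 mm steel ball).
#' @param g_ap,g_lat Beam geometries of the AP and lateral exposures.
#' @param settings A [solver_settings()].
#'
#' @return A `calibration_result`; `cf_percent` is the hip-plane calibration
#'   factor, `marker_plane_cf_percent` the AP marker-plane factor, and the
#'   diagnostics include the estimated rotation and anterior offset.
#' @export
biplanar_hip_cf <- function(ap, lat, ecm_diameter_mm = 25, g_ap, g_lat,
                            settings = solver_settings()) {
  stopifnot(inherits(ap, "ap_measurements"),
            inherits(lat, "lateral_measurements"),
            inherits(g_ap, "beam_geometry"),
            inherits(g_lat, "beam_geometry"),
            inherits(settings, "solver_settings"))
  need_ap <- c("h", "i", "k", "m")
  if (any(vapply(ap[need_ap], is.na, logical(1L)))) {
    stop("AP measurements h, i, k, m must all be present", call. = FALSE)
  }
  if (any(vapply(lat[c("a", "b", "c", "d")], is.na, logical(1L)))) {
    stop("lateral measurements a, b, c, d must all be present", call. = FALSE)
  }

  sol_ap <- single_marker_plane_cf(ap$k, ap$h, ecm_diameter_mm, g_ap, settings)
  sol_lat <- single_marker_plane_cf(lat$b, lat$a, ecm_diameter_mm, g_lat,
                                    settings)
  cf_E <- sol_ap$cf_percent
  z_E <- sol_ap$est_depth_mm
  lat_ecm_mag <- sol_lat$cf_percent / 100
  ecm_lateral_true <- ap$i / (cf_E / 100)

  cf_hip <- cf_E
  converged <- FALSE
  resid <- Inf
  iterations <- settings$max_iter
  phi <- NA_real_
  delta <- NA_real_
  inter_hip_true <- NA_real_
  for (it in seq_len(settings$max_iter)) {
    inter_hip_true <- ap$m / (cf_hip / 100)
    phi <- estimate_rotation(lat$c, inter_hip_true, lat_ecm_mag)
    sep <- inter_hip_true / 2 + ecm_lateral_true
    delta <- estimate_anterior_offset(lat$d, lat_ecm_mag, phi, sep)
    z_hip <- z_E + delta
    if (z_hip <= 0 || z_hip >= g_ap$sdd_mm) {
      stop("infeasible measurement: reconstructed hip plane lies outside ",
           "the source-detector span", call. = FALSE)
    }
    cf_new <- 100 * g_ap$sdd_mm / z_hip
    resid <- abs(cf_new - cf_hip)
    cf_hip <- cf_new
    if (resid < settings$tol_pp) {
      converged <- TRUE
      iterations <- it
      break
    }
  }
  .new_calibration_result(
    cf_hip, cf_E, 100 * g_ap$sdd_mm / cf_hip, iterations,
    converged && sol_ap$converged && sol_lat$converged, resid,
    diagnostics = list(rotation_deg_est = phi,
                       anterior_offset_mm_est = delta,
                       inter_hip_mm_est = inter_hip_true,
                       ecm_lateral_mm_est = ecm_lateral_true,
                       lat_ecm_mag = lat_ecm_mag))
}
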