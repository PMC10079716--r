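# Virtual X-ray phantom.
#
# Replicates the physical proof-of-concept setup: a pelvic bone model on a
# rotating stand, an internal calibration marker (ICM, 32 mm ball) at the
# right hip centre, and an external calibration marker (ECM, 25 mm ball) on a
# base plate in front of the pubic symphysis, repositionable in anterior and
# lateral offsets. Phantom frame: +x toward the patient's right, +y superior,
# +z anterior; origin at the midpoint of the hip centres.

#' Phantom configuration
#'
#' Geometry of the virtual phantom and of one exposure pose. Defaults follow
#' the study conditions where printed (marker diameters, offset grids,
#' rotation grid, focus-detector distance of the companion
#' [beam_geometry()]); the remaining lengths are plausible adult-male values.
#'
#' @param inter_hip_mm Distance between the hip centres.
#' @param symphysis_anterior_mm Anterior offset of the pubic symphysis from
#'   the hip-centre coronal plane.
#' @param symphysis_inferior_mm Vertical offset of the symphysis below
#'   hip-centre level.
#' @param icm_diameter_mm Internal marker diameter (32 mm ball head).
#' @param ecm_diameter_mm External marker diameter (25 mm steel ball).
#' @param ecm_anterior_mm ECM anterior offset from the symphysis (study grid:
#'   20, 50, 80).
#' @param ecm_lateral_mm ECM lateral offset from the midline (study grid: 0,
#'   20, 40, 60), placed toward the patient's left.
#' @param rotation_deg Phantom rotation in the lateral exposure (study grid:
#'   0, 10, 20, 30); positive rotation displaces the contralateral hip centre
#'   anteriorly in the image.
#' @param pelvic_tilt_deg Pelvic tilt applied to the bony landmarks about the
#'   inter-hip axis (markers are mounted on stand and base plate and are not
#'   tilted).
#' @param ap_hip_depth_mm Source-to-hip-plane depth in the AP exposure.
#' @param lat_hip_depth_mm Source-to-hip-centre depth in the lateral exposure.
#'
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(inter_hip_mm = 170,
                           symphysis_anterior_mm = 30,
                           symphysis_inferior_mm = 45,
                           icm_diameter_mm = 32,
                           ecm_diameter_mm = 25,
                           ecm_anterior_mm = 50,
                           ecm_lateral_mm = 0,
                           rotation_deg = 0,
                           pelvic_tilt_deg = 10,
                           ap_hip_depth_mm = 908,
                           lat_hip_depth_mm = 850) {
  cfg <- list(inter_hip_mm = inter_hip_mm,
              symphysis_anterior_mm = symphysis_anterior_mm,
              symphysis_inferior_mm = symphysis_inferior_mm,
              icm_diameter_mm = icm_diameter_mm,
              ecm_diameter_mm = ecm_diameter_mm,
              ecm_anterior_mm = ecm_anterior_mm,
              ecm_lateral_mm = ecm_lateral_mm,
              rotation_deg = rotation_deg,
              pelvic_tilt_deg = pelvic_tilt_deg,
              ap_hip_depth_mm = ap_hip_depth_mm,
              lat_hip_depth_mm = lat_hip_depth_mm)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!all(vapply(cfg, num1, logical(1L)))) {
    stop("all phantom configuration fields must be single finite numbers",
         call. = FALSE)
  }
  nonneg <- c("symphysis_anterior_mm", "symphysis_inferior_mm",
              "ecm_anterior_mm", "ecm_lateral_mm")
  if (any(unlist(cfg[nonneg]) < 0)) {
    stop("phantom offsets must be non-negative", call. = FALSE)
  }
  if (cfg$inter_hip_mm <= 0 || cfg$icm_diameter_mm <= 0 ||
      cfg$ecm_diameter_mm <= 0 || cfg$ap_hip_depth_mm <= 0 ||
      cfg$lat_hip_depth_mm <= 0) {
    stop("lengths and depths must be positive", call. = FALSE)
  }
  if (abs(cfg$rotation_deg) >= 45) {
    stop("`rotation_deg` must satisfy |rotation| < 45", call. = FALSE)
  }
  structure(cfg, class = "phantom_config")
}

#' Build the phantom landmark set
#'
#' Places the landmarks in the phantom frame: hip centres at
#' `(+/- inter_hip/2, 0, 0)`, the ICM sphere at the right hip centre, the
#' (untilted) symphysis at `(0, -inferior, +anterior)`, and the ECM sphere at
#' the symphysis shifted by the configured lateral (toward the patient's
#' left) and anterior offsets. Pelvic tilt rotates the bony landmarks about
#' the inter-hip axis; markers sit on stand and base plate and are unaffected.
#'
#' @param cfg A [phantom_config()].
#'
#' @return An object of class `phantom_landmarks`: positions `hip_right`,
#'   `hip_left`, `symphysis`, and marker centres/diameters `icm_center`,
#'   `ecm_center`, `icm_diameter_mm`, `ecm_diameter_mm`.
#' @export
build_phantom <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  hip_r <- c(cfg$inter_hip_mm / 2, 0, 0)
  hip_l <- c(-cfg$inter_hip_mm / 2, 0, 0)
  sym0 <- c(0, -cfg$symphysis_inferior_mm, cfg$symphysis_anterior_mm)
  tau <- cfg$pelvic_tilt_deg * pi / 180
  sym <- c(sym0[1],
           sym0[2] * cos(tau) - sym0[3] * sin(tau),
           sym0[2] * sin(tau) + sym0[3] * cos(tau))
  ecm <- c(-cfg$ecm_lateral_mm,
           sym0[2],
           sym0[3] + cfg$ecm_anterior_mm)
  icm <- hip_r
  gap <- sqrt(sum((ecm - icm)^2)) -
    (cfg$icm_diameter_mm + cfg$ecm_diameter_mm) / 2
  if (gap <= 0) {
    stop("invalid phantom configuration: ECM and ICM spheres overlap",
         call. = FALSE)
  }
  structure(list(hip_right = hip_r,
                 hip_left = hip_l,
                 symphysis = sym,
                 icm_center = icm,
                 icm_diameter_mm = cfg$icm_diameter_mm,
                 ecm_center = ecm,
                 ecm_diameter_mm = cfg$ecm_diameter_mm),
            class = "phantom_landmarks")
}

#' Simulate the anteroposterior exposure
#'
#' The AP central beam runs along the patient's posterior direction and is
#' centred on the pubic symphysis; the hip-centre coronal plane lies at depth
#' `ap_hip_depth_mm`, anterior structures nearer the source. Returns the seven
#' AP measurements plus, as attributes, the ground truth used for scoring
#' (never consumed by the solvers).
#'
#' @param cfg A [phantom_config()].
#' @param g A [beam_geometry()].
#'
#' @return An [ap_measurements()] object with attribute `truth` (list with
#'   `hip_cf_percent`, `ecm_depth_mm`, `ecm_plane_cf_percent`).
#' @export
simulate_ap <- function(cfg, g) {
  stopifnot(inherits(cfg, "phantom_config"), inherits(g, "beam_geometry"))
  ph <- build_phantom(cfg)
  beam_y <- ph$symphysis[2]
  to_view <- function(q) c(q[1], q[2] - beam_y, cfg$ap_hip_depth_mm - q[3])

  ell_e <- project_sphere(sphere3d(to_view(ph$ecm_center),
                                   ph$ecm_diameter_mm), g)
  ell_i <- project_sphere(sphere3d(to_view(ph$icm_center),
                                   ph$icm_diameter_mm), g)
  hr_img <- project_point(to_view(ph$hip_right), g)
  hl_img <- project_point(to_view(ph$hip_left), g)

  meas <- ap_measurements(h = sqrt(sum(ell_e$center_xy^2)),
                          i = abs(ell_e$center_xy[1]),
                          k = ell_e$major_axis_mm,
                          m = sqrt(sum((hr_img - hl_img)^2)),
                          n = ell_i$major_axis_mm,
                          o = sqrt(sum(ell_i$center_xy^2)),
                          p = abs(ell_i$center_xy[1]))
  attr(meas, "truth") <- list(
    hip_cf_percent = plane_cf(cfg$ap_hip_depth_mm, g),
    ecm_depth_mm = cfg$ap_hip_depth_mm -
      (cfg$symphysis_anterior_mm + cfg$ecm_anterior_mm),
    ecm_plane_cf_percent = plane_cf(
      cfg$ap_hip_depth_mm -
        (cfg$symphysis_anterior_mm + cfg$ecm_anterior_mm), g))
  meas
}

#' Simulate the lateral exposure
#'
#' The lateral central beam enters from the patient's right and is centred on
#' the (rotated) right hip centre, placed at depth `lat_hip_depth_mm`; image
#' horizontal is the patient's anteroposterior axis, positive anterior.
#' Rotation turns the whole phantom about the vertical axis; because the beam
#' is re-centred on the hip, only the rigid relative geometry matters.
#'
#' @param cfg A [phantom_config()] (its `rotation_deg` sets the pose).
#' @param g A [beam_geometry()].
#'
#' @return A [lateral_measurements()] object with attribute `truth` (list
#'   with `ecm_depth_mm`, `ecm_plane_cf_percent`, `rotation_deg`,
#'   `ecm_anterior_offset_mm`).
#' @export
simulate_lateral <- function(cfg, g) {
  stopifnot(inherits(cfg, "phantom_config"), inherits(g, "beam_geometry"))
  ph <- build_phantom(cfg)
  phi <- cfg$rotation_deg * pi / 180
  rot_y <- function(q) c(q[1] * cos(phi) + q[3] * sin(phi),
                         q[2],
                         -q[1] * sin(phi) + q[3] * cos(phi))
  hr <- rot_y(ph$hip_right)
  hl <- rot_y(ph$hip_left)
  ec <- rot_y(ph$ecm_center)
  # view: beam along -x through the rotated right hip centre;
  # image x = anterior (+z of the rotated phantom), image y = superior
  to_view <- function(q) c(q[3] - hr[3],
                           q[2] - hr[2],
                           cfg$lat_hip_depth_mm + hr[1] - q[1])

  ecm_v <- to_view(ec)
  ell_e <- project_sphere(sphere3d(ecm_v, ph$ecm_diameter_mm), g)
  hr_img <- project_point(to_view(hr), g)
  hl_img <- project_point(to_view(hl), g)

  meas <- lateral_measurements(a = sqrt(sum(ell_e$center_xy^2)),
                               b = ell_e$major_axis_mm,
                               c = abs(hl_img[1] - hr_img[1]),
                               d = abs(ell_e$center_xy[1] - hr_img[1]))
  attr(meas, "truth") <- list(
    ecm_depth_mm = ecm_v[3],
    ecm_plane_cf_percent = plane_cf(ecm_v[3], g),
    rotation_deg = cfg$rotation_deg,
    ecm_anterior_offset_mm = cfg$symphysis_anterior_mm + cfg$ecm_anterior_mm)
  meas
}

#' Gaussian measurement-noise model
#'
#' Emulates manual PACS caliper error: independent Gaussian noise on every
#' distance, with separate spreads for centre-to-centre distances and for
#' axis-length measurements.
#'
#' @param sd_distance_mm SD for distance measurements (a, c, d, h, i, m, o, p).
#' @param sd_axis_mm SD for axis-length measurements (b, k, n).
#' @param seed Optional RNG seed; identical seeds give identical noise.
#'
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sd_distance_mm = 0.2, sd_axis_mm = 0.15, seed = NULL) {
  if (sd_distance_mm < 0 || sd_axis_mm < 0) {
    stop("noise SDs must be non-negative", call. = FALSE)
  }
  structure(list(sd_distance_mm = sd_distance_mm,
                 sd_axis_mm = sd_axis_mm,
                 seed = seed),
            class = "noise_model")
}

#' Apply measurement noise
#'
#' Adds independent Gaussian noise to every field (distance SD to
#' centre-to-centre distances, axis SD to shadow axes), truncates at zero and
#' re-clamps the horizontal components to their direct distances (`i <= h`,
#' `p <= o`). With both SDs zero this is the identity.
#'
#' @param meas An [ap_measurements()] or [lateral_measurements()] object.
#' @param nm A [noise_model()].
#'
#' @return A measurement object of the same class.
#' @export
apply_noise <- function(meas, nm) {
  stopifnot(inherits(nm, "noise_model"))
  if (!is.null(nm$seed)) set.seed(nm$seed)
  UseMethod("apply_noise")
}

.jitter <- function(x, sd) {
  if (is.na(x) || sd == 0) return(x)
  max(0, x + stats::rnorm(1L, 0, sd))
}

#' @export
apply_noise.ap_measurements <- function(meas, nm) {
  truth <- attr(meas, "truth")
  h <- .jitter(meas$h, nm$sd_distance_mm)
  i <- .jitter(meas$i, nm$sd_distance_mm)
  k <- .jitter(meas$k, nm$sd_axis_mm)
  m <- .jitter(meas$m, nm$sd_distance_mm)
  n <- .jitter(meas$n, nm$sd_axis_mm)
  o <- .jitter(meas$o, nm$sd_distance_mm)
  p <- .jitter(meas$p, nm$sd_distance_mm)
  out <- ap_measurements(h = h, i = min(i, h), k = k, m = m,
                         n = n, o = o, p = min(p, o))
  attr(out, "truth") <- truth
  out
}

#' @export
apply_noise.lateral_measurements <- function(meas, nm) {
  truth <- attr(meas, "truth")
  out <- lateral_measurements(
    a = .jitter(meas$a, nm$sd_distance_mm),
    b = .jitter(meas$b, nm$sd_axis_mm),
    c = .jitter(meas$c, nm$sd_distance_mm),
    d = .jitter(meas$d, nm$sd_distance_mm))
  attr(out, "truth") <- truth
  out
}

#' Generate the full factorial phantom study
#'
#' Runs the complete proof-of-concept design: every combination of anterior
#' offset, lateral offset (one series each, 12 by default) and, within each
#' series, one AP exposure plus one lateral exposure per rotation setting
#' (60 radiograph-equivalents by default). Optional measurement noise is
#' drawn reproducibly from the noise model's seed.
#'
#' @param base_cfg A [phantom_config()] supplying everything except the
#'   design factors.
#' @param g_ap,g_lat Beam geometries of the AP and lateral exposures.
#' @param anterior_mm,lateral_mm,rotations_deg Design grids.
#' @param noise Optional [noise_model()]; `NULL` for noiseless measurements.
#'
#' @return A list of exposure records (class `study_records`). Each record is
#'   a list with `series_id`, `view` ("ap" or "lateral"), `anterior_mm`,
#'   `lateral_mm`, `rotation_deg`, `measurements`, and `truth`.
#' @export
generate_study <- function(base_cfg = phantom_config(),
                           g_ap = beam_geometry(),
                           g_lat = beam_geometry(),
                           anterior_mm = c(20, 50, 80),
                           lateral_mm = c(0, 20, 40, 60),
                           rotations_deg = c(0, 10, 20, 30),
                           noise = NULL) {
  stopifnot(inherits(base_cfg, "phantom_config"))
  if (!is.null(noise)) {
    stopifnot(inherits(noise, "noise_model"))
    if (!is.null(noise$seed)) set.seed(noise$seed)
    nm <- noise_model(noise$sd_distance_mm, noise$sd_axis_mm, seed = NULL)
  }
  records <- list()
  for (ant in anterior_mm) {
    for (lat_off in lateral_mm) {
      sid <- sprintf("A%02dL%02d", ant, lat_off)
      cfg_s <- base_cfg
      cfg_s$ecm_anterior_mm <- ant
      cfg_s$ecm_lateral_mm <- lat_off
      cfg_s$rotation_deg <- 0
      ap <- simulate_ap(cfg_s, g_ap)
      if (!is.null(noise)) ap <- apply_noise(ap, nm)
      records[[length(records) + 1L]] <- list(
        series_id = sid, view = "ap", anterior_mm = ant,
        lateral_mm = lat_off, rotation_deg = NA_real_,
        measurements = ap, truth = attr(ap, "truth"))
      for (rot in rotations_deg) {
        cfg_r <- cfg_s
        cfg_r$rotation_deg <- rot
        lm <- simulate_lateral(cfg_r, g_lat)
        if (!is.null(noise)) lm <- apply_noise(lm, nm)
        records[[length(records) + 1L]] <- list(
          series_id = sid, view = "lateral", anterior_mm = ant,
          lateral_mm = lat_off, rotation_deg = rot,
          measurements = lm, truth = attr(lm, "truth"))
      }
    }
  }
  structure(records, class = "study_records")
}

#' Flatten study records into the measurement table
#'
#' One row per radiograph set (AP paired with one lateral exposure), in the
#' interchange CSV schema: `series_id`, `rotation_deg`, lateral fields
#' `a, b, c, d` and AP fields `h, i, k, m, n, o, p` (mm). The AP fields of a
#' series repeat across its rotation settings.
#'
#' @param records A `study_records` list from [generate_study()].
#'
#' @return A data frame with 13 columns.
#' @export
measurements_table <- function(records) {
  stopifnot(inherits(records, "study_records"))
  aps <- Filter(function(r) r$view == "ap", records)
  lats <- Filter(function(r) r$view == "lateral", records)
  ap_by_series <- stats::setNames(aps, vapply(aps, `[[`, "", "series_id"))
  rows <- lapply(lats, function(r) {
    ap <- ap_by_series[[r$series_id]]
    if (is.null(ap)) stop("lateral record without matching AP series: ",
                          r$series_id, call. = FALSE)
    data.frame(series_id = r$series_id, rotation_deg = r$rotation_deg,
               a = r$measurements$a, b = r$measurements$b,
               c = r$measurements$c, d = r$measurements$d,
               h = ap$measurements$h, i = ap$measurements$i,
               k = ap$measurements$k, m = ap$measurements$m,
               n = ap$measurements$n, o = ap$measurements$o,
               p = ap$measurements$p)
  })
  do.call(rbind, rows)
}
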