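# Radiograph measurement containers: the eleven distances (all in mm) a
# reader takes off the two images with PACS calipers. These are the only
# clinical inputs of the calibration algorithms; single-letter names follow
# the standard measurement protocol (lateral: a-d; anteroposterior: h-p).

#' Anteroposterior radiograph measurements
#'
#' @param h Direct distance image centre to ECM shadow centre (mm).
#' @param i Horizontal distance image centre to ECM shadow centre (mm), i.e.
#'   the projected lateral offset of the marker.
#' @param k ECM shadow major axis (mm).
#' @param m Distance right hip centre to left hip centre (mm).
#' @param n ICM shadow major axis (mm).
#' @param o Direct distance image centre to ICM shadow centre (mm).
#' @param p Horizontal distance image centre to ICM shadow centre (mm).
#'
#' @return An object of class `ap_measurements`.
#' @export
ap_measurements <- function(h, i, k, m, n, o, p) {
  vals <- list(h = h, i = i, k = k, m = m, n = n, o = o, p = p)
  vals <- lapply(vals, .check_meas_field)
  tol <- 1e-9
  if (!is.na(vals$i) && !is.na(vals$h) && vals$i > vals$h + tol) {
    stop("invalid AP measurements: i (horizontal component) exceeds h ",
         "(direct distance)", call. = FALSE)
  }
  if (!is.na(vals$p) && !is.na(vals$o) && vals$p > vals$o + tol) {
    stop("invalid AP measurements: p exceeds o", call. = FALSE)
  }
  if (!is.na(vals$k) && !is.na(vals$m) && vals$k >= vals$m) {
    stop("invalid AP measurements: marker shadow k must be smaller than the ",
         "inter-hip projection m", call. = FALSE)
  }
  structure(vals, class = "ap_measurements")
}

#' Lateral radiograph measurements
#'
#' @param a Direct distance image centre to ECM shadow centre (mm).
#' @param b ECM shadow major axis in the lateral view (mm).
#' @param c Horizontal distance right hip centre to left hip centre (mm);
#'   zero in a strictly lateral, noiseless exposure.
#' @param d Horizontal distance hip centre to ECM shadow centre (mm).
#'
#' @return An object of class `lateral_measurements`.
#' @export
lateral_measurements <- function(a, b, c, d) {
  vals <- list(a = a, b = b, c = c, d = d)
  vals <- lapply(vals, .check_meas_field)
  structure(vals, class = "lateral_measurements")
}

.check_meas_field <- function(x) {
  if (is.null(x) || (length(x) == 1L && is.na(x))) return(NA_real_)
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    stop("measurements must be single non-negative numbers (mm) or NA",
         call. = FALSE)
  }
  as.numeric(x)
}

#' @export
print.ap_measurements <- function(x, ...) {
  cat("<ap_measurements> (mm)\n")
  print(round(unlist(x), 3))
  invisible(x)
}

#' @export
print.lateral_measurements <- function(x, ...) {
  cat("<lateral_measurements> (mm)\n")
  print(round(unlist(x), 3))
  invisible(x)
}
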