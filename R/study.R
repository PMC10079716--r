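# Study pipeline: per-set calibration factors, descriptive summaries in the
# layout of the study's results table, MCID counting, group comparisons and
# reliability coefficients.

#' Compute the per-set study table
#'
#' Runs the reference solver once per series (the ICM calibration factor is
#' shared by all rotation settings of a series, since the AP exposure is) and
#' the bi-planar solver once per radiograph set. Differences are reported in
#' percentage points of magnification, signed as ICM minus ECM.
#'
#' @param records A `study_records` list from [generate_study()].
#' @param icm_diameter_mm,ecm_diameter_mm True marker diameters.
#' @param g_ap,g_lat Beam geometries of the AP and lateral exposures.
#' @param settings A [solver_settings()].
#'
#' @return A data frame with one row per set: `series_id`, `anterior_mm`,
#'   `lateral_mm`, `rotation_deg`, `cf_icm`, `cf_ecm`, `rel_diff_pp`,
#'   `abs_diff_pp`, `icm_converged`, `ecm_converged`. Solver failures yield
#'   NA rows, not errors.
#' @export
compute_study_table <- function(records, icm_diameter_mm = 32,
                                ecm_diameter_mm = 25,
                                g_ap = beam_geometry(),
                                g_lat = beam_geometry(),
                                settings = solver_settings()) {
  stopifnot(inherits(records, "study_records"))
  aps <- Filter(function(r) r$view == "ap", records)
  lats <- Filter(function(r) r$view == "lateral", records)
  icm <- lapply(aps, function(r) {
    tryCatch(icm_reference_cf(r$measurements, icm_diameter_mm, g_ap, settings),
             error = function(e) NULL)
  })
  names(icm) <- vapply(aps, `[[`, "", "series_id")
  ap_meas <- stats::setNames(lapply(aps, `[[`, "measurements"),
                             names(icm))
  rows <- lapply(lats, function(r) {
    ref <- icm[[r$series_id]]
    ecm <- tryCatch(
      biplanar_hip_cf(ap_meas[[r$series_id]], r$measurements,
                      ecm_diameter_mm, g_ap, g_lat, settings),
      error = function(e) NULL)
    cf_i <- if (is.null(ref)) NA_real_ else ref$cf_percent
    cf_e <- if (is.null(ecm)) NA_real_ else ecm$cf_percent
    data.frame(series_id = r$series_id,
               anterior_mm = r$anterior_mm,
               lateral_mm = r$lateral_mm,
               rotation_deg = r$rotation_deg,
               cf_icm = cf_i,
               cf_ecm = cf_e,
               rel_diff_pp = cf_i - cf_e,
               abs_diff_pp = abs(cf_i - cf_e),
               icm_converged = !is.null(ref) && ref$converged,
               ecm_converged = !is.null(ecm) && ecm$converged)
  })
  do.call(rbind, rows)
}

#' Grouped descriptive statistics of a study table
#'
#' Mean, minimum, maximum and sample SD (n - 1) of the two calibration
#' factors and their signed/absolute differences, overall or grouped by a
#' design factor.
#'
#' @param table A study table from [compute_study_table()].
#' @param grouping One of "all", "rotation", "anterior", "lateral".
#'
#' @return A long data frame with columns `group`, `variable`, `n`, `mean`,
#'   `min`, `max`, `sd`. Empty groups are dropped with a warning.
#' @export
summarize_study <- function(table,
                            grouping = c("all", "rotation", "anterior",
                                         "lateral")) {
  grouping <- match.arg(grouping)
  if (nrow(table) == 0L) stop("empty study table", call. = FALSE)
  key <- switch(grouping,
                all = rep("all", nrow(table)),
                rotation = table$rotation_deg,
                anterior = table$anterior_mm,
                lateral = table$lateral_mm)
  vars <- c("cf_icm", "cf_ecm", "rel_diff_pp", "abs_diff_pp")
  out <- list()
  for (g in unique(key)) {
    sub <- table[key == g, , drop = FALSE]
    for (v in vars) {
      x <- sub[[v]]
      x_ok <- x[!is.na(x)]
      if (length(x_ok) == 0L) {
        warning("group ", g, " has no valid values for ", v, "; omitted")
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        group = as.character(g), variable = v, n = length(x_ok),
        mean = mean(x_ok), min = min(x_ok), max = max(x_ok),
        sd = stats::sd(x_ok))
    }
  }
  do.call(rbind, out)
}

#' Results-table-shaped summary
#'
#' Arranges the descriptive statistics as in the study's results table: rows
#' Mean / Minimum / Maximum / SD for each of ICM, ECM, relative and absolute
#' difference; columns All and one per rotation setting.
#'
#' @param table A study table from [compute_study_table()].
#'
#' @return A data frame with columns `statistic`, `variable`, `All` and one
#'   column per rotation.
#' @export
table2_summary <- function(table) {
  s_all <- summarize_study(table, "all")
  s_rot <- summarize_study(table, "rotation")
  rots <- sort(unique(table$rotation_deg))
  vars <- c(cf_icm = "ICM", cf_ecm = "ECM",
            rel_diff_pp = "Relative difference",
            abs_diff_pp = "Absolute difference")
  stats_map <- c(mean = "Mean", min = "Minimum", max = "Maximum", sd = "SD")
  rows <- list()
  for (st in names(stats_map)) {
    for (v in names(vars)) {
      row <- data.frame(statistic = stats_map[[st]], variable = vars[[v]])
      row[["All"]] <- s_all[s_all$variable == v, st]
      for (r in rots) {
        cell <- s_rot[s_rot$variable == v & s_rot$group == as.character(r), st]
        row[[sprintf("%gdeg", r)]] <- cell
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count sets beyond the clinical calibration-error threshold
#'
#' Counts radiograph sets whose absolute ICM-ECM difference strictly exceeds
#' the minimal clinically important difference (1.5 percentage points of
#' magnification); a secondary count at the stricter 1.0 threshold is also
#' reported.
#'
#' @param table A study table from [compute_study_table()].
#' @param threshold_pp MCID threshold in percentage points (default 1.5).
#'
#' @return An object of class `mcid_report`: `threshold_pp`, `n_total`,
#'   `n_beyond`, `fraction`, a per-rotation breakdown data frame, and the
#'   secondary count `n_beyond_1pp`.
#' @export
mcid_report <- function(table, threshold_pp = 1.5) {
  d <- table$abs_diff_pp
  beyond <- !is.na(d) & d > threshold_pp
  rots <- sort(unique(table$rotation_deg))
  by_rot <- do.call(rbind, lapply(rots, function(r) {
    sel <- table$rotation_deg == r
    data.frame(rotation_deg = r, n = sum(sel),
               n_beyond = sum(beyond[sel]))
  }))
  structure(list(threshold_pp = threshold_pp,
                 n_total = nrow(table),
                 n_beyond = sum(beyond),
                 fraction = sum(beyond) / nrow(table),
                 by_rotation = by_rot,
                 n_beyond_1pp = sum(!is.na(d) & d > 1.0)),
            class = "mcid_report")
}

#' @export
print.mcid_report <- function(x, ...) {
  cat(sprintf("<mcid_report> %d/%d sets (%.1f%%) beyond %.1f pp\n",
              x$n_beyond, x$n_total, 100 * x$fraction, x$threshold_pp))
  print(x$by_rotation, row.names = FALSE)
  invisible(x)
}

#' Paired location test
#'
#' Classical paired two-sided t test for a mean difference between two
#' matched samples (here: ICM vs ECM calibration factors per set).
#'
#' @param x,y Paired numeric samples of equal length (n >= 3).
#'
#' @return A list with `statistic`, `df`, `p_value`, `mean_diff`,
#'   `degenerate` (TRUE when the differences have zero variance).
#' @export
paired_location_test <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("`x` and `y` must be paired samples of equal length >= 3",
         call. = FALSE)
  }
  d <- x - y
  if (stats::sd(d) == 0) {
    md <- mean(d)
    return(list(statistic = if (md == 0) 0 else sign(md) * Inf,
                df = length(d) - 1L,
                p_value = if (md == 0) 1 else 0,
                mean_diff = md, degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_diff = unname(tt$estimate),
       degenerate = FALSE)
}

#' Rank-based k-sample test
#'
#' Kruskal-Wallis H test (with tie correction, chi-square reference) for a
#' location difference across k groups; used for the subgroup analyses by
#' anterior offset, lateral offset and rotation.
#'
#' @param values Numeric response vector.
#' @param groups Group labels, at least two distinct.
#'
#' @return A list with `statistic` (H), `df`, `p_value`, `degenerate`.
#' @export
rank_ksample_test <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) {
    stop("need at least two groups", call. = FALSE)
  }
  if (length(unique(values)) == 1L) {
    return(list(statistic = NA_real_, df = nlevels(groups) - 1L,
                p_value = NA_real_, degenerate = TRUE))
  }
  kw <- stats::kruskal.test(values, groups)
  list(statistic = unname(kw$statistic), df = unname(kw$parameter),
       p_value = kw$p.value, degenerate = FALSE)
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation from the standard mean-squares decomposition, with the
#' Shrout-Fleiss confidence interval. Used for inter- and intrarater
#' reliability of the raw distance measurements.
#'
#' @param ratings Numeric matrix, subjects in rows, raters in columns
#'   (>= 5 subjects, >= 2 raters, no missing cells).
#' @param conf_level Confidence level for the interval.
#'
#' @return A list with `icc`, `lower`, `upper`, `ms` (mean squares),
#'   `degenerate` (TRUE when there is no between-subject variance, in which
#'   case the ICC is undefined and returned as NA).
#' @export
icc_agreement <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 5L || k < 2L) {
    stop("need at least 5 subjects and 2 raters", call. = FALSE)
  }
  if (any(is.na(ratings))) stop("missing cells are not allowed", call. = FALSE)
  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  ms <- list(msr = msr, msc = msc, mse = mse)

  if (msr <= .Machine$double.eps * max(1, grand^2)) {
    # absolute agreement on constant subjects: no variance to correlate
    return(list(icc = NA_real_, lower = NA_real_, upper = NA_real_,
                ms = ms, degenerate = TRUE))
  }
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  if (mse == 0 && msc == 0) {
    return(list(icc = 1, lower = 1, upper = 1, ms = ms, degenerate = FALSE))
  }
  a <- 1 - conf_level
  if (mse == 0) {
    # rater offsets without residual error: Satterthwaite df reach the
    # fj -> Inf limit of the expression below
    vn <- k - 1
  } else {
    fj <- msc / mse
    num <- (k - 1) * (n - 1) *
      (k * icc * fj + n * (1 + (k - 1) * icc) - k * icc)^2
    den <- (n - 1) * k^2 * icc^2 * fj^2 +
      (n * (1 + (k - 1) * icc) - k * icc)^2
    vn <- num / den
  }
  fl <- stats::qf(1 - a / 2, n - 1, vn)
  fu <- stats::qf(1 - a / 2, vn, n - 1)
  lower <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  list(icc = icc, lower = lower, upper = upper, ms = ms, degenerate = FALSE)
}

#' Simulate independent raters for reliability analysis
#'
#' Emulates independent observers re-measuring every radiograph: each rater
#' (and repeat) receives an independent noise draw on top of the record's
#' stored measurement values. The resulting per-variable rating matrices feed
#' [icc_agreement()].
#'
#' @param records A `study_records` list (typically noiseless).
#' @param nm A [noise_model()]; its seed makes the raters reproducible.
#' @param n_raters Number of raters.
#' @param n_repeats Independent repeats per rater (columns are
#'   rater-by-repeat combinations).
#'
#' @return A named list of matrices, one per measurement variable: lateral
#'   variables over the lateral exposures, AP variables over the AP
#'   exposures.
#' @export
simulate_raters <- function(records, nm = noise_model(), n_raters = 2,
                            n_repeats = 1) {
  stopifnot(inherits(records, "study_records"))
  if (!is.null(nm$seed)) set.seed(nm$seed)
  nm0 <- noise_model(nm$sd_distance_mm, nm$sd_axis_mm, seed = NULL)
  lat_vars <- c("a", "b", "c", "d")
  ap_vars <- c("h", "i", "k", "m", "n", "o", "p")
  aps <- Filter(function(r) r$view == "ap", records)
  lats <- Filter(function(r) r$view == "lateral", records)
  n_cols <- n_raters * n_repeats
  out <- list()
  fill <- function(recs, vars) {
    mats <- lapply(vars, function(v) matrix(NA_real_, length(recs), n_cols))
    names(mats) <- vars
    for (j in seq_len(n_cols)) {
      for (s in seq_along(recs)) {
        noisy <- apply_noise(recs[[s]]$measurements, nm0)
        for (v in vars) mats[[v]][s, j] <- noisy[[v]]
      }
    }
    mats
  }
  c(fill(lats, lat_vars), fill(aps, ap_vars))
}
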