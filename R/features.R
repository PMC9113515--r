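# The digital pen feature bank: 176 features in five provenance-tagged
# families. Each family function is a pure function of an ink sample (a
# single-stroke sample for stroke-level evaluation) returning a named numeric
# vector in registry order. Degenerate inputs (single points, zero duration)
# fall back to the registry default so no NaN or Inf ever leaves a feature
# function.
#
# Families intentionally keep their own copies of overlapping quantities
# (e.g. path length appears under more than one namespace): the five family
# cardinalities 13 + 89 + 49 + 14 + 11 = 176 are part of the contract.

.rubine_names <- paste0("rubine.", c(
  "cos_initial", "sin_initial", "bbox_diag_len", "bbox_diag_angle",
  "endpoint_dist", "cos_endpoint", "sin_endpoint", "path_length",
  "total_angle", "total_abs_angle", "total_sq_angle", "max_speed_sq",
  "duration"))

.willems_names <- paste0("willems.", c(
  "n_points", "n_strokes", "duration", "path_length", "avg_stroke_length",
  "speed_mean", "speed_sd", "speed_max", "speed_min", "speed_median",
  "vx_mean", "vx_sd", "vx_max", "vx_min", "vx_median",
  "vy_mean", "vy_sd", "vy_max", "vy_min", "vy_median",
  "accel_mean", "accel_sd", "accel_max", "accel_min", "accel_median",
  "pressure_mean", "pressure_sd", "pressure_max", "pressure_min",
  "pressure_median", "pressure_first", "pressure_last", "pressure_range",
  "angle_sum", "abs_angle_sum", "abs_angle_mean", "abs_angle_max",
  "sq_angle_sum", "perpendicularity", "perpendicularity_mean",
  "hull_area", "hull_perimeter", "hull_compactness",
  "bbox_width", "bbox_height", "bbox_area", "bbox_aspect", "bbox_diag",
  "bbox_diag_angle", "centroid_offset_x", "centroid_offset_y",
  "radius_mean", "radius_sd",
  paste0("dir_hist_", 1:8), paste0("curv_hist_", 1:4),
  "straight_ratio", "n_straight_lines", "n_crossings",
  "n_connected_strokes", "endpoint_dist", "closure",
  "initial_cos", "initial_sin", "final_cos", "final_sin",
  "mean_direction", "circular_variance",
  "air_time", "air_ratio", "pen_down_mean",
  "jerk_mean", "jerk_max", "n_speed_inversions", "pressure_speed_corr",
  "length_diag_ratio", "hull_bbox_ratio", "eccentricity", "n_sharp_points",
  "sample_dt_mean"))

.hbf49_names <- paste0("hbf49.", c(
  "start_ux", "start_uy", "end_ux", "end_uy", "fl_cos", "fl_sin", "fl_dist",
  "closure", "init_cos", "init_sin", "n_strokes", "pen_up_ratio",
  "aspect", "norm_length", "line_deviation", "center_dist_mean",
  "diag_angle", "curvature_total", "perpendicularity", "k_perpendicularity",
  "angle_max", paste0("zone_", 1:9), paste0("dirhist_", 1:8),
  "mu11", "mu20", "mu02", "mu21", "mu12", "mu30", "mu03",
  "compactness", "eccentricity", "rectangularity", "circular_variance"))

.sonntag_names <- paste0("sonntag.", c(
  "compactness", "eccentricity", "closure", "length", "hull_area",
  "hull_perimeter", "width", "height", "aspect", "mean_abs_curvature",
  "initial_angle", "principal_angle", "n_strokes", "avg_stroke_length"))

.cognitive_names <- paste0("cog.", c(
  "n_strokes", "sketching_time", "stroke_distance", "duration",
  "avg_pressure", "avg_velocity", "velocity_cv", "n_pauses",
  "avg_pause_duration", "sketch_pause_ratio", "avg_lift_duration"))

#' The digital pen feature registry
#'
#' All 176 feature definitions in a fixed deterministic order: the 13
#' stroke-appearance features of the classic gesture-recognition set, the 89
#' formally defined trajectory features (kinematics, curvature, hull,
#' histogram, pressure and meta features), the 49 heterogeneous baseline
#' features for symbol recognition, 14 mode-detection shape descriptors
#' (compactness, eccentricity, closure, ...), and 11 features collected from
#' the cognitive-assessment literature (pauses, lifts, pressure, velocity,
#' sketching time). Family order follows the order in which the sets are
#' introduced; within a family the order follows the source publication's
#' grouping and is fixed by this registry.
#'
#' @return A `data.frame` with columns `name`, `family`,
#'   `granularity_support` and `default_on_degenerate`; exactly 176 rows.
#' @export
#' @examples
#' table(feature_registry()$family)
feature_registry <- function() {
  fam <- c(rep("rubine", length(.rubine_names)),
           rep("willems", length(.willems_names)),
           rep("hbf49", length(.hbf49_names)),
           rep("sonntag", length(.sonntag_names)),
           rep("cognitive", length(.cognitive_names)))
  data.frame(
    name = c(.rubine_names, .willems_names, .hbf49_names, .sonntag_names,
             .cognitive_names),
    family = fam,
    granularity_support = "both",
    default_on_degenerate = 0,
    stringsAsFactors = FALSE
  )
}

#' Feature subset identifiers
#'
#' `all176` is the full registry, `lit165` drops the cognitive family (the
#' four literature feature sets), `cog11` is the cognitive family alone.
#'
#' @param subset_id One of `"all176"`, `"lit165"`, `"cog11"`.
#' @return Character vector of feature names in registry order.
#' @export
feature_subset <- function(subset_id) {
  reg <- feature_registry()
  switch(subset_id,
    all176 = reg$name,
    lit165 = reg$name[reg$family != "cognitive"],
    cog11 = reg$name[reg$family == "cognitive"],
    stop("unknown subset '", subset_id,
         "'; valid ids: all176, lit165, cog11", call. = FALSE)
  )
}

# --- family implementations -------------------------------------------------

#' Stroke-appearance features (13)
#'
#' The classic 13-dimensional gesture feature vector: initial-angle cosine
#' and sine, bounding-box diagonal length and angle, start-to-end distance
#' and angle, path length, total signed / absolute / squared turning angle
#' (sharpness), maximum squared speed and duration. Applied to a whole
#' sample the trajectory is the time-ordered concatenation of its strokes,
#' with turning angles accumulated within strokes only.
#'
#' @param sample An [ink_sample()] (typically a single stroke).
#' @param g Optional precomputed geometry (internal).
#' @return Named numeric vector of length 13.
#' @export
rubine_features <- function(sample, g = ink_geometry(sample)) {
  v <- numeric(13)
  if (g$n_pts > 0L) {
    p <- g$pts
    k <- min(3L, g$n_pts)
    d0 <- pt_dist(p$x[1L], p$y[1L], p$x[k], p$y[k])
    if (d0 > 0) {
      v[1] <- (p$x[k] - p$x[1L]) / d0
      v[2] <- (p$y[k] - p$y[1L]) / d0
    }
    v[3] <- sqrt(g$width^2 + g$height^2)
    v[4] <- atan2(g$height, g$width)
    ed <- pt_dist(g$first_pt[1], g$first_pt[2], g$last_pt[1], g$last_pt[2])
    v[5] <- ed
    if (ed > 0) {
      v[6] <- (g$last_pt[1] - g$first_pt[1]) / ed
      v[7] <- (g$last_pt[2] - g$first_pt[2]) / ed
    }
    v[8] <- g$path_length
    v[9] <- sum(g$angles)
    v[10] <- sum(abs(g$angles))
    v[11] <- sum(g$angles^2)
    v[12] <- if (length(g$speed)) max(g$speed)^2 else 0
    v[13] <- g$duration_s
  }
  names(v) <- .rubine_names
  sanitize_features(v)
}

stat5 <- function(x) {
  if (length(x) == 0L) return(rep(0, 5))
  c(mean(x), if (length(x) > 1L) stats::sd(x) else 0, max(x), min(x),
    stats::median(x))
}

#' Trajectory features (89)
#'
#' The 89 formally defined handwriting features: point/stroke counts,
#' kinematics (velocity, acceleration, jerk statistics), pressure statistics,
#' curvature and perpendicularity sums, convex-hull and bounding-box
#' properties, direction and curvature histograms, and meta features
#' (crossings, straight lines, connected strokes, pen-up behaviour).
#'
#' @inheritParams rubine_features
#' @return Named numeric vector of length 89.
#' @export
willems_features <- function(sample, g = ink_geometry(sample)) {
  v <- numeric(89)
  if (g$n_pts > 0L) {
    p <- g$pts
    v[1] <- g$n_pts
    v[2] <- g$n_strokes
    v[3] <- g$duration_s
    v[4] <- g$path_length
    v[5] <- g$path_length / max(1L, g$n_strokes)
    v[6:10] <- stat5(g$speed)
    v[11:15] <- stat5(g$vx)
    v[16:20] <- stat5(g$vy)
    v[21:25] <- stat5(g$accel)
    v[26:30] <- stat5(p$pressure)
    v[31] <- p$pressure[1L]
    v[32] <- p$pressure[g$n_pts]
    v[33] <- max(p$pressure) - min(p$pressure)
    a <- g$angles
    v[34] <- sum(a)
    v[35] <- sum(abs(a))
    v[36] <- if (length(a)) mean(abs(a)) else 0
    v[37] <- if (length(a)) max(abs(a)) else 0
    v[38] <- sum(a^2)
    v[39] <- sum(sin(a)^2)
    v[40] <- if (length(a)) mean(sin(a)^2) else 0
    v[41] <- g$hull$area
    v[42] <- g$hull$perimeter
    v[43] <- if (g$hull$area > 0) g$hull$perimeter^2 / g$hull$area else 0
    v[44] <- g$width
    v[45] <- g$height
    v[46] <- g$width * g$height
    v[47] <- if (g$width > 0) g$height / g$width else 0
    v[48] <- sqrt(g$width^2 + g$height^2)
    v[49] <- atan2(g$height, g$width)
    v[50] <- if (g$width > 0) (g$centroid[1] - g$xmin) / g$width else 0.5
    v[51] <- if (g$height > 0) (g$centroid[2] - g$ymin) / g$height else 0.5
    radii <- sqrt((p$x - g$centroid[1])^2 + (p$y - g$centroid[2])^2)
    v[52] <- mean(radii)
    v[53] <- if (g$n_pts > 1L) stats::sd(radii) else 0
    v[54:61] <- direction_histogram(g$seg_dx, g$seg_dy, g$seg_len)
    if (length(a)) {
      edges <- c(0, pi / 8, pi / 4, pi / 2, pi + 1e-9)
      cb <- findInterval(abs(a), edges, rightmost.closed = TRUE)
      v[62:65] <- vapply(1:4, function(b) mean(cb == b), 0)
    }
    straight <- abs(a) < 0.05
    v[66] <- if (length(a)) mean(straight) else 0
    if (length(a)) {
      r <- rle(straight)
      v[67] <- sum(r$values & r$lengths >= 2L)
    }
    v[68] <- count_crossings(g$rs_x, g$rs_y, g$rs_breaks)
    if (g$n_strokes > 1L) {
      conn <- 0L
      for (i in seq_len(g$n_strokes - 1L)) {
        s1 <- g$strokes[[i]]; s2 <- g$strokes[[i + 1L]]
        d <- pt_dist(s1$x[nrow(s1)], s1$y[nrow(s1)], s2$x[1L], s2$y[1L])
        if (d <= 2) conn <- conn + 1L
      }
      v[69] <- conn
    }
    ed <- pt_dist(g$first_pt[1], g$first_pt[2], g$last_pt[1], g$last_pt[2])
    v[70] <- ed
    v[71] <- if (g$path_length > 0) ed / g$path_length else 0
    if (length(g$seg_len) && g$seg_len[1L] > 0) {
      v[72] <- g$seg_dx[1L] / g$seg_len[1L]
      v[73] <- g$seg_dy[1L] / g$seg_len[1L]
    }
    m <- length(g$seg_len)
    if (m > 0L && g$seg_len[m] > 0) {
      v[74] <- g$seg_dx[m] / g$seg_len[m]
      v[75] <- g$seg_dy[m] / g$seg_len[m]
    }
    if (sum(g$seg_len) > 0) {
      sw <- sum(g$seg_len * sin(atan2(g$seg_dy, g$seg_dx)))
      cw <- sum(g$seg_len * cos(atan2(g$seg_dy, g$seg_dx)))
      v[76] <- atan2(sw, cw)
      v[77] <- 1 - sqrt(sw^2 + cw^2) / sum(g$seg_len)
    }
    air <- sum(g$lifts) / 1000
    v[78] <- air
    v[79] <- if (g$duration_s > 0) air / g$duration_s else 0
    v[80] <- g$sketch_time_s / max(1L, g$n_strokes)
    v[81] <- if (length(g$jerk)) mean(g$jerk) else 0
    v[82] <- if (length(g$jerk)) max(g$jerk) else 0
    if (length(g$speed) > 2L) {
      ds <- diff(g$speed)
      v[83] <- sum(diff(sign(ds)) != 0)
    }
    if (g$n_pts > 2L && stats::sd(p$pressure) > 0 && stats::sd(g$speed) > 0) {
      v[84] <- stats::cor(p$pressure, g$speed)
    }
    diag <- sqrt(g$width^2 + g$height^2)
    v[85] <- if (diag > 0) g$path_length / diag else 0
    v[86] <- if (g$width * g$height > 0) g$hull$area / (g$width * g$height) else 0
    v[87] <- cloud_eccentricity(p$x, p$y)
    v[88] <- sum(abs(a) > pi / 4)
    v[89] <- if (length(g$seg_dt)) mean(g$seg_dt) else 0
  }
  names(v) <- .willems_names
  sanitize_features(v)
}

#' Heterogeneous baseline features (49)
#'
#' The 49-dimensional reference representation for hand-drawn symbol
#' recognition: first/last point attributes in box-normalized coordinates,
#' pen-up statistics, global geometry, a 3x3 zoning histogram and an 8-bin
#' direction histogram over the resampled path, scale-normalized central
#' moments, and shape descriptors (compactness, eccentricity,
#' rectangularity, circular variance).
#'
#' @inheritParams rubine_features
#' @return Named numeric vector of length 49.
#' @export
hbf49_features <- function(sample, g = ink_geometry(sample)) {
  v <- numeric(49)
  if (g$n_pts > 0L) {
    p <- g$pts
    side <- max(g$width, g$height)
    cx <- (g$xmin + g$xmax) / 2
    cy <- (g$ymin + g$ymax) / 2
    u <- function(px, py) {
      if (side > 0) c((px - cx) / side, (py - cy) / side) else c(0, 0)
    }
    v[1:2] <- u(g$first_pt[1], g$first_pt[2])
    v[3:4] <- u(g$last_pt[1], g$last_pt[2])
    ed <- pt_dist(g$first_pt[1], g$first_pt[2], g$last_pt[1], g$last_pt[2])
    if (ed > 0) {
      v[5] <- (g$last_pt[1] - g$first_pt[1]) / ed
      v[6] <- (g$last_pt[2] - g$first_pt[2]) / ed
    }
    diag <- sqrt(g$width^2 + g$height^2)
    v[7] <- if (diag > 0) ed / diag else 0
    v[8] <- if (g$path_length > 0) ed / g$path_length else 0
    if (length(g$rs_x) >= 3L) {
      d0 <- pt_dist(g$rs_x[1L], g$rs_y[1L], g$rs_x[3L], g$rs_y[3L])
      if (d0 > 0) {
        v[9] <- (g$rs_x[3L] - g$rs_x[1L]) / d0
        v[10] <- (g$rs_y[3L] - g$rs_y[1L]) / d0
      }
    }
    v[11] <- g$n_strokes
    v[12] <- if (g$duration_s > 0) (sum(g$lifts) / 1000) / g$duration_s else 0
    v[13] <- if (g$width > 0) g$height / g$width else 0
    v[14] <- if (diag > 0) g$path_length / diag else 0
    # mean distance of points to the first-last chord, box-normalized
    if (ed > 0 && side > 0) {
      nxv <- (g$last_pt[2] - g$first_pt[2]) / ed
      nyv <- -(g$last_pt[1] - g$first_pt[1]) / ed
      v[15] <- mean(abs((p$x - g$first_pt[1]) * nxv +
                        (p$y - g$first_pt[2]) * nyv)) / side
    }
    if (side > 0) {
      v[16] <- mean(sqrt((p$x - cx)^2 + (p$y - cy)^2)) / side
    }
    v[17] <- atan2(g$height, g$width)
    a <- g$angles
    v[18] <- sum(abs(a))
    v[19] <- sum(sin(a)^2)
    if (length(a)) {
      s2 <- sin(a)^2
      if (length(s2) >= 3L) {
        win <- s2[1:(length(s2) - 2L)] + s2[2:(length(s2) - 1L)] +
          s2[3:length(s2)]
        v[20] <- max(win)
      } else {
        v[20] <- max(s2)
      }
      v[21] <- max(abs(a))
    }
    # 3x3 zoning of the resampled path over the bounding box
    if (length(g$rs_x) > 0L) {
      zx <- if (g$width > 0) pmin(2L, floor(3 * (g$rs_x - g$xmin) / g$width)) else 0L
      zy <- if (g$height > 0) pmin(2L, floor(3 * (g$rs_y - g$ymin) / g$height)) else 0L
      zone <- 3L * zy + zx + 1L
      v[22:30] <- vapply(1:9, function(z) mean(zone == z), 0)
      rdx <- diff(g$rs_x); rdy <- diff(g$rs_y)
      if (length(g$rs_breaks)) {
        rdx <- rdx[-g$rs_breaks]; rdy <- rdy[-g$rs_breaks]
      }
      rlen <- sqrt(rdx^2 + rdy^2)
      v[31:38] <- direction_histogram(rdx, rdy, rlen)
    }
    # scale-normalized central moments
    mx <- p$x - mean(p$x); my <- p$y - mean(p$y)
    n <- g$n_pts
    mom <- function(pp, qq) {
      mu <- sum(mx^pp * my^qq)
      mu / n^(1 + (pp + qq) / 2)
    }
    v[39] <- mom(1, 1); v[40] <- mom(2, 0); v[41] <- mom(0, 2)
    v[42] <- mom(2, 1); v[43] <- mom(1, 2); v[44] <- mom(3, 0)
    v[45] <- mom(0, 3)
    v[46] <- if (g$hull$area > 0) g$hull$perimeter^2 / g$hull$area else 0
    v[47] <- cloud_eccentricity(p$x, p$y)
    v[48] <- if (g$width * g$height > 0) g$hull$area / (g$width * g$height) else 0
    if (sum(g$seg_len) > 0) {
      phi <- atan2(g$seg_dy, g$seg_dx)
      sw <- sum(g$seg_len * sin(phi)); cw <- sum(g$seg_len * cos(phi))
      v[49] <- 1 - sqrt(sw^2 + cw^2) / sum(g$seg_len)
    }
  }
  names(v) <- .hbf49_names
  sanitize_features(v)
}

#' Mode-detection shape descriptors (14)
#'
#' The 14 descriptors used for pen-input mode detection (handwriting vs.
#' shape vs. gesture): compactness (hull perimeter squared over hull area),
#' principal-axis eccentricity, closure (endpoint gap over path length) and
#' further length, extent and curvature descriptors.
#'
#' @inheritParams rubine_features
#' @return Named numeric vector of length 14.
#' @export
sonntag_features <- function(sample, g = ink_geometry(sample)) {
  v <- numeric(14)
  if (g$n_pts > 0L) {
    p <- g$pts
    v[1] <- if (g$hull$area > 0) g$hull$perimeter^2 / g$hull$area else 0
    v[2] <- cloud_eccentricity(p$x, p$y)
    ed <- pt_dist(g$first_pt[1], g$first_pt[2], g$last_pt[1], g$last_pt[2])
    v[3] <- if (g$path_length > 0) ed / g$path_length else 0
    v[4] <- g$path_length
    v[5] <- g$hull$area
    v[6] <- g$hull$perimeter
    v[7] <- g$width
    v[8] <- g$height
    v[9] <- if (g$width > 0) g$height / g$width else 0
    v[10] <- if (length(g$angles)) mean(abs(g$angles)) else 0
    if (length(g$seg_len) && g$seg_len[1L] > 0) {
      v[11] <- atan2(g$seg_dy[1L], g$seg_dx[1L])
    }
    if (g$n_pts >= 3L) {
      cv <- stats::cov(cbind(p$x, p$y))
      ev <- eigen(cv, symmetric = TRUE)
      if (all(is.finite(ev$values))) {
        v[12] <- atan2(ev$vectors[2, 1], ev$vectors[1, 1])
      }
    }
    v[13] <- g$n_strokes
    v[14] <- g$path_length / max(1L, g$n_strokes)
  }
  names(v) <- .sonntag_names
  sanitize_features(v)
}

#' Cognitive-assessment features (11)
#'
#' The 11 features collected from the literature on analysing cognitive
#' tests with digital pens: number of strokes, sketching time (sum of
#' pen-down durations, s), stroke distance (total pen-down path length, mm),
#' duration (completion time, s), average pressure, average velocity (mm/s),
#' variation of velocity (coefficient of variation of point speed), number
#' of pauses, average pause duration (s), the ratio between sketching and
#' pausing, and average lift duration (s).
#'
#' A lift is any pen-up interval between consecutive strokes; a pause is a
#' lift of at least `pause_threshold` milliseconds (default 200 ms). Ratio
#' features with a zero denominator fall back to 0.
#'
#' @inheritParams rubine_features
#' @param pause_threshold Minimum lift duration (ms) counting as a pause.
#' @return Named numeric vector of length 11.
#' @export
cognitive_features <- function(sample, g = NULL, pause_threshold = 200) {
  if (is.null(g)) g <- ink_geometry(sample, pause_threshold = pause_threshold)
  v <- numeric(11)
  if (g$n_pts > 0L) {
    v[1] <- g$n_strokes
    v[2] <- g$sketch_time_s
    v[3] <- g$path_length
    v[4] <- g$duration_s
    v[5] <- mean(g$pts$pressure)
    v[6] <- if (g$sketch_time_s > 0) g$path_length / g$sketch_time_s else 0
    if (length(g$speed) > 1L && mean(g$speed) > 0) {
      v[7] <- stats::sd(g$speed) / mean(g$speed)
    }
    pauses <- g$lifts[g$lifts >= g$pause_threshold]
    v[8] <- length(pauses)
    v[9] <- if (length(pauses)) mean(pauses) / 1000 else 0
    total_pause <- sum(pauses) / 1000
    v[10] <- if (total_pause > 0) g$sketch_time_s / total_pause else 0
    v[11] <- if (length(g$lifts)) mean(g$lifts) / 1000 else 0
  }
  names(v) <- .cognitive_names
  sanitize_features(v)
}

# Compute the named features of `names_needed` for one sample, touching only
# the families actually required.
compute_features <- function(sample, names_needed,
                             pause_threshold = 200) {
  fams <- unique(sub("\\..*$", "", names_needed))
  g <- ink_geometry(sample, pause_threshold = pause_threshold)
  out <- c(
    if ("rubine" %in% fams) rubine_features(sample, g),
    if ("willems" %in% fams) willems_features(sample, g),
    if ("hbf49" %in% fams) hbf49_features(sample, g),
    if ("sonntag" %in% fams) sonntag_features(sample, g),
    if ("cog" %in% fams) cognitive_features(sample, g)
  )
  out[names_needed]
}
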