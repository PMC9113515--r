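# Shared per-sample geometry cache. Every feature family works from these
# derived quantities so they are computed once per sample per extraction.
#
# Velocities are central finite differences on the raw timestamps (one-sided
# at stroke endpoints); no smoothing is applied, matching the convention of
# leaving the recorded trajectory untouched.

ink_geometry <- function(sample, pause_threshold = 200) {
  strokes <- sample$strokes
  pts <- all_points(sample)
  n_pts <- nrow(pts)
  n_strokes <- length(strokes)

  # per-stroke segments ------------------------------------------------------
  seg_dx <- numeric(0); seg_dy <- numeric(0); seg_len <- numeric(0)
  seg_dt <- numeric(0)
  angles <- numeric(0)
  vx <- numeric(0); vy <- numeric(0)
  for (s in strokes) {
    m <- nrow(s)
    if (m >= 2L) {
      dx <- diff(s$x); dy <- diff(s$y)
      seg_dx <- c(seg_dx, dx); seg_dy <- c(seg_dy, dy)
      seg_len <- c(seg_len, sqrt(dx^2 + dy^2))
      seg_dt <- c(seg_dt, diff(s$t))
    }
    angles <- c(angles, turn_angles(s$x, s$y))
    fd <- finite_diff(s$t, s$x, s$y)
    vx <- c(vx, fd$dx); vy <- c(vy, fd$dy)
  }
  speed <- sqrt(vx^2 + vy^2)

  # acceleration / jerk from the velocity signal (same finite-difference rule)
  ax <- numeric(0); ay <- numeric(0); accel <- numeric(0); jerk <- numeric(0)
  off <- 0L
  for (s in strokes) {
    m <- nrow(s)
    idx <- off + seq_len(m)
    fa <- finite_diff(s$t, vx[idx], vy[idx])
    ax <- c(ax, fa$dx); ay <- c(ay, fa$dy)
    amag <- sqrt(fa$dx^2 + fa$dy^2)
    accel <- c(accel, amag)
    fj <- finite_diff(s$t, amag, rep(0, m))
    jerk <- c(jerk, abs(fj$dx))
    off <- off + m
  }

  L <- sum(seg_len)
  xr <- if (n_pts > 0L) range(pts$x) else c(0, 0)
  yr <- if (n_pts > 0L) range(pts$y) else c(0, 0)
  w <- diff(xr); h <- diff(yr)
  duration_s <- if (n_pts > 0L) (max(pts$t) - min(pts$t)) / 1000 else 0

  stroke_first <- vapply(strokes, function(s) s$t[1L], 0)
  stroke_last <- vapply(strokes, function(s) s$t[nrow(s)], 0)
  lifts <- if (n_strokes > 1L) {
    pmax(0, stroke_first[-1L] - stroke_last[-n_strokes])
  } else numeric(0)

  hull <- hull_stats(pts$x, pts$y)

  # resampled pen-down path (64 points over the whole sample, allocated to
  # strokes proportionally to their length) used by histogram features and
  # the crossing counter
  rs_x <- numeric(0); rs_y <- numeric(0); rs_breaks <- integer(0)
  if (n_pts > 0L) {
    stroke_lens <- vapply(strokes, function(s) {
      if (nrow(s) < 2L) 0 else sum(arc_lengths(s$x, s$y))
    }, 0)
    total <- sum(stroke_lens)
    for (i in seq_along(strokes)) {
      s <- strokes[[i]]
      ni <- if (total > 0) max(2L, round(64 * stroke_lens[i] / total)) else 2L
      if (nrow(s) == 1L) ni <- 1L
      r <- resample_polyline(s$x, s$y, ni)
      if (length(rs_x) > 0L) rs_breaks <- c(rs_breaks, length(rs_x))
      rs_x <- c(rs_x, r[, 1]); rs_y <- c(rs_y, r[, 2])
    }
  }

  list(
    strokes = strokes, pts = pts, n_pts = n_pts, n_strokes = n_strokes,
    seg_dx = seg_dx, seg_dy = seg_dy, seg_len = seg_len, seg_dt = seg_dt,
    angles = angles, vx = vx, vy = vy, speed = speed, accel = accel,
    jerk = jerk, path_length = L,
    xmin = xr[1], xmax = xr[2], ymin = yr[1], ymax = yr[2],
    width = w, height = h, duration_s = duration_s,
    centroid = if (n_pts > 0L) c(mean(pts$x), mean(pts$y)) else c(0, 0),
    lifts = lifts, pause_threshold = pause_threshold,
    sketch_time_s = sum(stroke_last - stroke_first) / 1000,
    hull = hull,
    rs_x = rs_x, rs_y = rs_y, rs_breaks = rs_breaks,
    first_pt = if (n_pts) c(pts$x[1L], pts$y[1L]) else c(0, 0),
    last_pt = if (n_pts) c(pts$x[n_pts], pts$y[n_pts]) else c(0, 0)
  )
}

# Direction histogram over segments (length-weighted, 8 bins centred on the
# compass directions), normalized to sum 1.
direction_histogram <- function(dx, dy, len, bins = 8L) {
  if (length(dx) == 0L || sum(len) <= 0) return(rep(0, bins))
  phi <- atan2(dy, dx) %% (2 * pi)
  bin <- floor(((phi + pi / bins) %% (2 * pi)) / (2 * pi / bins)) + 1L
  out <- vapply(seq_len(bins), function(b) sum(len[bin == b]), 0)
  out / sum(len)
}

# Principal-axis eccentricity sqrt(1 - lambda2/lambda1) of a point cloud.
cloud_eccentricity <- function(x, y) {
  if (length(x) < 3L) return(0)
  cv <- stats::cov(cbind(x, y))
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (!all(is.finite(ev)) || ev[1L] <= 0) return(0)
  sqrt(max(0, 1 - ev[2L] / ev[1L]))
}
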