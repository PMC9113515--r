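# Internal geometry / numerics helpers shared by the feature bank and scorers.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
fmt_num <- function(v) {
  # exact decimal text round-trip for doubles
  sprintf("%.17g", as.numeric(v))
}

# Euclidean distance between two points (x1,y1)-(x2,y2)
pt_dist <- function(x1, y1, x2, y2) sqrt((x2 - x1)^2 + (y2 - y1)^2)

# Cumulative arc length of a polyline given coordinate vectors
arc_lengths <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(numeric(0))
  sqrt(diff(x)^2 + diff(y)^2)
}

# Resample a polyline to n points equidistant in arc length.
# Degenerate polylines (single point / zero length) are replicated.
resample_polyline <- function(x, y, n = 64L) {
  m <- length(x)
  if (m == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  seg <- if (m > 1L) arc_lengths(x, y) else numeric(0)
  L <- sum(seg)
  if (m == 1L || L <= 0) {
    return(cbind(x = rep(x[1L], n), y = rep(y[1L], n)))
  }
  s <- c(0, cumsum(seg))
  target <- seq(0, L, length.out = n)
  xi <- stats::approx(s, x, xout = target, ties = "ordered")$y
  yi <- stats::approx(s, y, xout = target, ties = "ordered")$y
  cbind(x = xi, y = yi)
}

# Central finite-difference derivative of (x, y) with respect to t (ms),
# one-sided at the endpoints; returns per-point rates in units/second.
finite_diff <- function(t, x, y) {
  n <- length(t)
  if (n < 2L) {
    return(list(dx = rep(0, n), dy = rep(0, n)))
  }
  ip <- pmin(n, seq_len(n) + 1L)
  im <- pmax(1L, seq_len(n) - 1L)
  dt <- (t[ip] - t[im]) / 1000  # ms -> s
  dt[dt <= 0] <- Inf            # duplicate timestamps -> zero rate
  list(dx = (x[ip] - x[im]) / dt, dy = (y[ip] - y[im]) / dt)
}

# Signed turning angles between successive segments of a polyline (radians).
turn_angles <- function(x, y) {
  n <- length(x)
  if (n < 3L) return(numeric(0))
  dx <- diff(x); dy <- diff(y)
  keep <- (dx != 0 | dy != 0)
  dx <- dx[keep]; dy <- dy[keep]
  m <- length(dx)
  if (m < 2L) return(numeric(0))
  cross <- dx[-m] * dy[-1L] - dy[-m] * dx[-1L]
  dot <- dx[-m] * dx[-1L] + dy[-m] * dy[-1L]
  atan2(cross, dot)
}

# Convex hull (area, perimeter) of a point cloud via grDevices::chull.
hull_stats <- function(x, y) {
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 3L) {
    per <- if (nrow(pts) == 2L) 2 * pt_dist(pts[1, 1], pts[1, 2], pts[2, 1], pts[2, 2]) else 0
    return(list(area = 0, perimeter = per, idx = seq_len(nrow(pts))))
  }
  h <- grDevices::chull(pts[, 1], pts[, 2])
  hx <- pts[h, 1]; hy <- pts[h, 2]
  area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  perimeter <- sum(sqrt(diff(c(hx, hx[1]))^2 + diff(c(hy, hy[1]))^2))
  list(area = area, perimeter = perimeter, idx = h)
}

# Symmetric mean nearest-neighbour (Chamfer) distance between two point sets.
chamfer_distance <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(Inf)
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  (mean(sqrt(apply(d2, 1, min))) + mean(sqrt(apply(d2, 2, min)))) / 2
}

# Count self-intersections among non-adjacent segments of a polyline.
count_crossings <- function(x, y, breaks = integer(0)) {
  n <- length(x) - 1L
  if (n < 3L) return(0L)
  x1 <- x[-length(x)]; y1 <- y[-length(y)]
  x2 <- x[-1L]; y2 <- y[-1L]
  # segments that bridge two strokes are not part of the pen-down path
  valid <- rep(TRUE, n)
  valid[breaks[breaks >= 1L & breaks <= n]] <- FALSE
  cross <- 0L
  orient <- function(ax, ay, bx, by, cx, cy) {
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  }
  for (i in seq_len(n - 2L)) {
    if (!valid[i]) next
    js <- seq.int(i + 2L, n)
    js <- js[valid[js]]
    if (length(js) == 0L) next
    d1 <- orient(x1[i], y1[i], x2[i], y2[i], x1[js], y1[js])
    d2 <- orient(x1[i], y1[i], x2[i], y2[i], x2[js], y2[js])
    d3 <- orient(x1[js], y1[js], x2[js], y2[js], x1[i], y1[i])
    d4 <- orient(x1[js], y1[js], x2[js], y2[js], x2[i], y2[i])
    hit <- (d1 * d2 < 0) & (d3 * d4 < 0)
    cross <- cross + sum(hit)
  }
  as.integer(cross)
}

# Replace non-finite values by per-feature fallbacks (never lets NaN/Inf out).
sanitize_features <- function(v, fallback = 0) {
  bad <- !is.finite(v)
  if (any(bad)) v[bad] <- fallback
  v
}

# Minimal absolute angular difference in degrees, result in [0, 180].
ang_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}
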