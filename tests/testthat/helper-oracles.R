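# Independent oracles and fixture builders used across the suite. The
# oracles deliberately re-derive quantities from first principles (gift
# wrapping, plain finite differences, timestamp arithmetic) so they share no
# code with the implementation paths they check.

mk_stroke <- function(t, x, y, pressure = 0.5) {
  ink_stroke(t = t, x = x, y = y, pressure = pressure)
}

mk_sample <- function(..., test_type = "OTHER") {
  ink_sample(list(...), test_type = test_type)
}

# A small random multi-stroke sample with plausible timestamps.
random_sample <- function(n_strokes = 3, n_pts = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t0 <- 0
  strokes <- lapply(seq_len(n_strokes), function(i) {
    n <- base::sample(2:n_pts, 1)
    tt <- t0 + cumsum(c(0, stats::runif(n - 1, 5, 30)))
    s <- mk_stroke(tt, stats::runif(n, 0, 100), stats::runif(n, 0, 100),
                   stats::runif(n, 0.1, 0.9))
    t0 <<- max(tt) + stats::runif(1, 50, 500)
    s
  })
  ink_sample(strokes)
}

# Gift-wrapping (Jarvis march) convex hull oracle: returns hull area and
# perimeter by direct enumeration, independent of grDevices::chull.
oracle_hull <- function(x, y) {
  pts <- unique(cbind(x, y))
  n <- nrow(pts)
  if (n < 3) {
    per <- if (n == 2) 2 * sqrt(sum((pts[1, ] - pts[2, ])^2)) else 0
    return(list(area = 0, perimeter = per))
  }
  start <- which.min(pts[, 1] + 1e-9 * pts[, 2])
  hull <- start
  repeat {
    p <- hull[length(hull)]
    cand <- setdiff(seq_len(n), p)
    q <- cand[1]
    for (r in cand[-1]) {
      cr <- (pts[q, 1] - pts[p, 1]) * (pts[r, 2] - pts[p, 2]) -
        (pts[q, 2] - pts[p, 2]) * (pts[r, 1] - pts[p, 1])
      d_q <- sum((pts[q, ] - pts[p, ])^2)
      d_r <- sum((pts[r, ] - pts[p, ])^2)
      if (cr < 0 || (abs(cr) < 1e-12 && d_r > d_q)) q <- r
    }
    if (q == start) break
    hull <- c(hull, q)
    if (length(hull) > n) stop("hull oracle failed to terminate")
  }
  hx <- pts[hull, 1]; hy <- pts[hull, 2]
  area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  per <- sum(sqrt(diff(c(hx, hx[1]))^2 + diff(c(hy, hy[1]))^2))
  list(area = area, perimeter = per)
}

# Plain central finite-difference speed oracle (mm/s) for a single stroke.
oracle_speeds <- function(s) {
  n <- nrow(s)
  if (n < 2) return(rep(0, n))
  v <- numeric(n)
  for (i in seq_len(n)) {
    a <- max(1, i - 1); b <- min(n, i + 1)
    dt <- (s$t[b] - s$t[a]) / 1000
    v[i] <- if (dt > 0) {
      sqrt((s$x[b] - s$x[a])^2 + (s$y[b] - s$y[a])^2) / dt
    } else 0
  }
  v
}

# Full pairwise distance matrix of all points of a sample.
distance_matrix <- function(sample) {
  pts <- do.call(rbind, lapply(sample$strokes, function(s) cbind(s$x, s$y)))
  as.matrix(stats::dist(pts))
}
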