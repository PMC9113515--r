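# Clock Drawing Test: semantic segmentation and 20-item CDIS scoring.

#' Clock stroke segmentation
#'
#' @param classes Character vector, one semantic class per stroke:
#'   `"circle"`, `"digit_1"` ... `"digit_12"`, `"hour_hand"`,
#'   `"minute_hand"`, `"center_point"`, `"helper_line"` or `"other"`.
#' @return An object of class `clock_segmentation`.
#' @export
clock_segmentation <- function(classes) {
  valid <- c("circle", paste0("digit_", 1:12), "hour_hand", "minute_hand",
             "center_point", "helper_line", "other")
  bad <- setdiff(unique(classes), valid)
  if (length(bad)) stop("unknown clock classes: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  structure(as.character(classes), class = "clock_segmentation")
}

#' Segment clock strokes into semantic classes
#'
#' With ground-truth `hints` (from the synthetic generator or a human
#' annotator) the hints are returned verbatim. Otherwise a geometric
#' heuristic is applied: the longest nearly-closed large contour becomes the
#' clock face circle, strokes anchored near the estimated centre become the
#' hands (the longer one the minute hand), a tiny mark at the centre the
#' centre point, small clusters near the rim become digits identified by
#' their angular sector, and everything else `other`.
#'
#' @param sample An [ink_sample()].
#' @param hints Optional [clock_segmentation()] to pass through.
#' @return A [clock_segmentation()] covering every stroke.
#' @export
segment_clock <- function(sample, hints = NULL) {
  n <- length(sample$strokes)
  if (!is.null(hints)) {
    if (length(hints) != n) stop("hints must cover every stroke",
                                 call. = FALSE)
    return(clock_segmentation(hints))
  }
  classes <- rep("other", n)
  if (n == 0L) return(clock_segmentation(classes))
  info <- lapply(sample$strokes, function(s) {
    L <- if (nrow(s) > 1L) sum(arc_lengths(s$x, s$y)) else 0
    gap <- pt_dist(s$x[1L], s$y[1L], s$x[nrow(s)], s$y[nrow(s)])
    list(len = L, closure = if (L > 0) gap / L else 1,
         cx = mean(s$x), cy = mean(s$y))
  })
  lens <- vapply(info, `[[`, 0, "len")
  closures <- vapply(info, `[[`, 0, "closure")
  circ_cand <- which(closures <= 0.2 & lens >= 10)
  circle_idx <- if (length(circ_cand)) circ_cand[which.max(lens[circ_cand])] else NA_integer_
  if (is.na(circle_idx)) return(clock_segmentation(classes))
  classes[circle_idx] <- "circle"
  cs <- sample$strokes[[circle_idx]]
  cx <- mean(cs$x); cy <- mean(cs$y)
  r <- mean(sqrt((cs$x - cx)^2 + (cs$y - cy)^2))
  for (i in seq_len(n)) {
    if (i == circle_idx) next
    s <- sample$strokes[[i]]
    d_end <- min(pt_dist(s$x[1L], s$y[1L], cx, cy),
                 pt_dist(s$x[nrow(s)], s$y[nrow(s)], cx, cy))
    cen_r <- pt_dist(info[[i]]$cx, info[[i]]$cy, cx, cy)
    if (info[[i]]$len < 0.07 * r && cen_r <= 0.15 * r) {
      classes[i] <- "center_point"
    } else if (d_end <= 0.25 * r && info[[i]]$len >= 0.2 * r &&
               info[[i]]$len <= 1.2 * r) {
      classes[i] <- "hand"
    } else if (cen_r >= 0.5 * r && cen_r <= 1.15 * r &&
               info[[i]]$len < 0.6 * r) {
      ang <- (atan2(info[[i]]$cy - cy, info[[i]]$cx - cx) * 180 / pi) %% 360
      d <- round((ang + 90) / 30) %% 12
      if (d == 0) d <- 12
      classes[i] <- paste0("digit_", d)
    }
  }
  hands <- which(classes == "hand")
  if (length(hands)) {
    hl <- lens[hands]
    ord <- hands[order(hl, decreasing = TRUE)]
    classes[classes == "hand"] <- "other"
    classes[ord[1L]] <- "minute_hand"
    if (length(ord) > 1L) classes[ord[2L]] <- "hour_hand"
  }
  clock_segmentation(classes)
}

# Scoring parameters for the 20 CDIS items (all configurable).
#' @rdname score_cdt
#' @export
cdis_params <- function(digit_angle_tol = 15, hand_angle_tol = 15,
                        closure_frac = 0.10, target_time = "11:10") {
  list(digit_angle_tol = digit_angle_tol, hand_angle_tol = hand_angle_tol,
       closure_frac = closure_frac, target_time = target_time)
}

# Geometric context shared by the item predicates.
cdt_context <- function(sample, seg, params) {
  n <- length(sample$strokes)
  cls <- as.character(seg)
  ctx <- list(n_strokes = n, classes = cls, params = params)
  circle_idx <- which(cls == "circle")
  if (length(circle_idx)) {
    cs <- do.call(rbind, sample$strokes[circle_idx])
    ctx$center <- c(mean(cs$x), mean(cs$y))
    radii <- sqrt((cs$x - ctx$center[1])^2 + (cs$y - ctx$center[2])^2)
    ctx$radius <- mean(radii)
    ctx$radial_cv <- if (mean(radii) > 0) stats::sd(radii) / mean(radii) else 1
    first_idx <- circle_idx[1L]
    s <- sample$strokes[[first_idx]]
    gap <- pt_dist(s$x[1L], s$y[1L], s$x[nrow(s)], s$y[nrow(s)])
    per <- sum(arc_lengths(s$x, s$y))
    ctx$circle_gap_frac <- if (per > 0) gap / per else 1
    ctx$has_circle <- TRUE
  } else {
    pts <- all_points(sample)
    if (nrow(pts)) {
      ctx$center <- c(mean(range(pts$x)), mean(range(pts$y)))
      ctx$radius <- max(diff(range(pts$x)), diff(range(pts$y)), 1) / 2
    } else {
      ctx$center <- c(0, 0); ctx$radius <- 1
    }
    ctx$has_circle <- FALSE
  }
  digits <- list()
  for (d in 1:12) {
    idx <- which(cls == paste0("digit_", d))
    if (!length(idx)) next
    ps <- do.call(rbind, sample$strokes[idx])
    cxy <- c(mean(ps$x), mean(ps$y))
    rel <- cxy - ctx$center
    digits[[length(digits) + 1L]] <- list(
      id = d, centroid = cxy,
      r = sqrt(sum(rel^2)) / ctx$radius,
      angle = (atan2(rel[2], rel[1]) * 180 / pi) %% 360,
      nominal = (d * 30 - 90) %% 360)
  }
  ctx$digits <- digits
  hand_info <- function(class) {
    idx <- which(cls == class)
    if (!length(idx)) return(NULL)
    ps <- do.call(rbind, sample$strokes[idx])
    dists <- sqrt((ps$x - ctx$center[1])^2 + (ps$y - ctx$center[2])^2)
    tip <- c(ps$x[which.max(dists)], ps$y[which.max(dists)])
    rel <- tip - ctx$center
    list(tip = tip, length = max(dists), anchor = min(dists),
         angle = (atan2(rel[2], rel[1]) * 180 / pi) %% 360)
  }
  ctx$hour <- hand_info("hour_hand")
  ctx$minute <- hand_info("minute_hand")
  ctx$has_center_point <- any(cls == "center_point")
  ctx$n_other <- sum(cls == "other")
  tm <- as.numeric(strsplit(params$target_time, ":", fixed = TRUE)[[1L]])
  ctx$target_hour_angle <- (((tm[1L] %% 12) + tm[2L] / 60) * 30 - 90) %% 360
  ctx$target_minute_angle <- (tm[2L] * 6 - 90) %% 360
  ctx
}

# The 20 binary CDIS items as declarative predicates over the context.
cdis_items <- function() {
  digit_ok <- function(ctx, f) length(ctx$digits) > 0 &&
    all(vapply(ctx$digits, f, TRUE))
  list(
    anything_drawn = function(ctx) ctx$n_strokes > 0,
    circle_present = function(ctx) ctx$has_circle,
    circle_closed = function(ctx) ctx$has_circle &&
      ctx$circle_gap_frac <= ctx$params$closure_frac,
    circle_round = function(ctx) ctx$has_circle && ctx$radial_cv <= 0.15,
    any_digit_present = function(ctx) length(ctx$digits) > 0,
    all_digits_present = function(ctx) {
      length(unique(vapply(ctx$digits, `[[`, 0, "id"))) == 12
    },
    only_digits_1_to_12 = function(ctx) {
      ids <- vapply(ctx$digits, `[[`, 0, "id")
      length(ctx$digits) > 0 && !any(duplicated(ids))
    },
    digits_inside_clock = function(ctx) digit_ok(ctx, function(d) d$r <= 1.1),
    digits_near_rim = function(ctx) digit_ok(ctx, function(d)
      d$r >= 0.5 && d$r <= 1.1),
    digits_in_order = function(ctx) {
      if (length(ctx$digits) < 2L) return(length(ctx$digits) == 1L)
      o <- order(vapply(ctx$digits, `[[`, 0, "id"))
      ang <- vapply(ctx$digits, `[[`, 0, "angle")[o]
      gaps <- diff(c(ang, ang[1L] + 360)) %% 360
      all(gaps > 0) && abs(sum(gaps) - 360) < 1e-6
    },
    digits_angular_position = function(ctx) digit_ok(ctx, function(d)
      ang_diff_deg(d$angle, d$nominal) <= ctx$params$digit_angle_tol),
    digits_evenly_spaced = function(ctx) {
      if (length(ctx$digits) != 12L) return(FALSE)
      o <- order(vapply(ctx$digits, `[[`, 0, "id"))
      ang <- vapply(ctx$digits, `[[`, 0, "angle")[o]
      gaps <- diff(c(ang, ang[1L] + 360)) %% 360
      all(abs(gaps - 30) <= ctx$params$digit_angle_tol)
    },
    two_hands_present = function(ctx) !is.null(ctx$hour) && !is.null(ctx$minute),
    hands_anchored_center = function(ctx) {
      !is.null(ctx$hour) && !is.null(ctx$minute) &&
        ctx$hour$anchor <= 0.15 * ctx$radius &&
        ctx$minute$anchor <= 0.15 * ctx$radius
    },
    minute_longer_than_hour = function(ctx) {
      !is.null(ctx$hour) && !is.null(ctx$minute) &&
        ctx$minute$length > ctx$hour$length
    },
    hour_hand_at_target = function(ctx) !is.null(ctx$hour) &&
      ang_diff_deg(ctx$hour$angle, ctx$target_hour_angle) <=
        ctx$params$hand_angle_tol,
    minute_hand_at_target = function(ctx) !is.null(ctx$minute) &&
      ang_diff_deg(ctx$minute$angle, ctx$target_minute_angle) <=
        ctx$params$hand_angle_tol,
    hands_within_clock = function(ctx) {
      !is.null(ctx$hour) && !is.null(ctx$minute) &&
        ctx$hour$length <= 1.05 * ctx$radius &&
        ctx$minute$length <= 1.05 * ctx$radius
    },
    center_marked = function(ctx) ctx$has_center_point,
    no_extraneous_marks = function(ctx) ctx$n_strokes > 0 && ctx$n_other == 0
  )
}

#' Names of CDIS items that require clock hands
#'
#' Convenience accessor for analyses of hand-dependent scoring items.
#' @return Character vector of item names.
#' @export
cdis_hand_items <- function() {
  c("two_hands_present", "hands_anchored_center", "minute_longer_than_hour",
    "hour_hand_at_target", "minute_hand_at_target", "hands_within_clock")
}

#' Score a Clock Drawing Test sample (20-point CDIS scheme)
#'
#' Evaluates 20 binary geometric/semantic item predicates (digit presence,
#' order and placement; hand presence, anchoring, proportion and target
#' time; circle presence, closure and roundness; centre mark; extraneous
#' marks) over a semantic stroke segmentation and sums them to the 0-20
#' CDIS total, where lower totals indicate more severe impairment.
#'
#' @param sample An [ink_sample()].
#' @param seg A [clock_segmentation()] covering the sample (e.g. from
#'   [segment_clock()]).
#' @param params Item tolerances from [cdis_params()].
#' @return An object of class `cdis_result`: list with `items` (named 0/1
#'   integer vector of length 20) and `total` (0-20).
#' @export
score_cdt <- function(sample, seg = segment_clock(sample),
                      params = cdis_params()) {
  if (length(seg) != length(sample$strokes)) {
    stop("segmentation must cover every stroke", call. = FALSE)
  }
  ctx <- cdt_context(sample, seg, params)
  preds <- cdis_items()
  items <- vapply(preds, function(f) as.integer(isTRUE(f(ctx))), 0L)
  structure(list(items = items, total = sum(items)), class = "cdis_result")
}

#' @export
print.cdis_result <- function(x, ...) {
  cat(sprintf("<cdis_result> total %d/20; failed: %s\n", x$total,
              paste(names(x$items)[x$items == 0L], collapse = ", ")))
  invisible(x)
}
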