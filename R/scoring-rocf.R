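# Rey-Osterrieth Complex Figure: 18 sub-figure scoring (0/1/2 each).

#' Assign strokes to complex-figure sub-figures
#'
#' Heuristic assignment used when no ground truth is available: each stroke
#' goes to the sub-figure whose reference points are closest (mean
#' nearest-neighbour distance from the stroke's resampled points), or to
#' `NA` when no sub-figure is within `max_dist`.
#'
#' @param sample An [ink_sample()].
#' @param template A [rocf_template()].
#' @param max_dist Maximum mean distance (mm) for an assignment.
#' @return Integer vector (one entry per stroke) of sub-figure ids 1-18 or
#'   `NA`.
#' @export
segment_rocf <- function(sample, template = rocf_template(), max_dist = 15) {
  refs <- lapply(template, rocf_subfigure_points)
  vapply(sample$strokes, function(s) {
    r <- resample_polyline(s$x, s$y, 24L)
    d <- vapply(refs, function(ref) {
      d2 <- outer(r[, 1], ref[, 1], "-")^2 + outer(r[, 2], ref[, 2], "-")^2
      mean(sqrt(apply(d2, 1, min)))
    }, 0)
    best <- which.min(d)
    if (d[best] <= max_dist) as.integer(best) else NA_integer_
  }, 0L)
}

#' Score a complex-figure sample over its 18 sub-figures
#'
#' Each sub-figure is rated 0 when no strokes are assigned to it, 2 when it
#' is both drawn correctly (shape similarity at least `s_min` after centroid
#' alignment) and placed correctly (centroid within `place_tol` of the
#' reference), and 1 otherwise (present but failing shape or placement).
#' Shape similarity is `1 - chamfer / (0.25 * scale)` where `chamfer` is the
#' symmetric mean nearest-neighbour distance between the aligned drawn and
#' reference point clouds and `scale` the reference sub-figure diagonal.
#' Sub-scores are summed to the 0-36 total; totals of 30 or less are the
#' suspicious range of the binary labeler.
#'
#' @param sample An [ink_sample()].
#' @param assignment Integer vector mapping each stroke to a sub-figure id
#'   1-18 (or `NA` for unassigned strokes), e.g. from [segment_rocf()] or
#'   the generator ground truth.
#' @param template A [rocf_template()].
#' @param s_min Minimum shape similarity for a 2 (default 0.85).
#' @param place_tol Maximum centroid displacement in mm for a 2 (default 10).
#' @return An object of class `rocf_result`: `sub_scores` (integer vector of
#'   length 18, each 0/1/2), `similarity`, `displacement` and `total` (0-36).
#' @export
score_rocf <- function(sample, assignment = segment_rocf(sample, template),
                       template = rocf_template(), s_min = 0.85,
                       place_tol = 10) {
  if (length(assignment) != length(sample$strokes)) {
    stop("assignment must cover every stroke", call. = FALSE)
  }
  bad <- assignment[!is.na(assignment)]
  if (length(bad) && (any(bad < 1L) || any(bad > 18L))) {
    stop("sub-figure ids must be in 1..18", call. = FALSE)
  }
  sub_scores <- integer(18)
  similarity <- rep(NA_real_, 18)
  displacement <- rep(NA_real_, 18)
  for (k in 1:18) {
    idx <- which(!is.na(assignment) & assignment == k)
    if (!length(idx)) next
    drawn <- do.call(rbind, lapply(sample$strokes[idx], function(s) {
      resample_polyline(s$x, s$y, max(8L, min(32L, nrow(s))))
    }))
    ref <- rocf_subfigure_points(template[[k]])
    ref_c <- colMeans(ref)
    drawn_c <- colMeans(drawn)
    disp <- sqrt(sum((drawn_c - ref_c)^2))
    aligned <- sweep(drawn, 2, drawn_c - ref_c)
    scale_k <- max(5, sqrt(diff(range(ref[, 1]))^2 +
                           diff(range(ref[, 2]))^2))
    ch <- chamfer_distance(aligned, ref)
    sim <- max(0, min(1, 1 - ch / (0.25 * scale_k)))
    similarity[k] <- sim
    displacement[k] <- disp
    sub_scores[k] <- if (sim >= s_min && disp <= place_tol) 2L else 1L
  }
  structure(list(sub_scores = sub_scores, similarity = similarity,
                 displacement = displacement, total = sum(sub_scores)),
            class = "rocf_result")
}

#' @export
print.rocf_result <- function(x, ...) {
  cat(sprintf("<rocf_result> total %d/36 (sub-scores: %s)\n", x$total,
              paste(x$sub_scores, collapse = " ")))
  invisible(x)
}

#' Binary screening label from a test result
#'
#' The per-test thresholds used to decide whether to schedule further
#' cognitive testing: clock drawings are suspicious when the CDIS total is
#' 18 or less, complex-figure drawings when the 36-point total is 30 or
#' less, and trails when completion time exceeds one minute (part A) or two
#' minutes (part B); the time boundaries are strict.
#'
#' @param test_type One of the [ink_test_types()] other than `"OTHER"`.
#' @param result CDIS total (CDT), ROCF total (any ROCF variant) or
#'   completion time in seconds (TMT).
#' @return `"healthy"` or `"suspicious"`.
#' @export
#' @examples
#' label_sample("CDT", 18)   # suspicious
#' label_sample("CDT", 19)   # healthy
#' label_sample("TMT_A", 60) # healthy (strictly over a minute)
label_sample <- function(test_type, result) {
  if (!is.numeric(result) || length(result) != 1L || !is.finite(result)) {
    stop("result must be a single finite number", call. = FALSE)
  }
  suspicious <- switch(test_type,
    CDT = result <= 18,
    TMT_A = result > 60,
    TMT_B = result > 120,
    ROCF_COPY = ,
    ROCF_RECALL = ,
    ROCF_DELAYED = result <= 30,
    stop("no labeling rule for test_type '", test_type, "'", call. = FALSE)
  )
  if (suspicious) "suspicious" else "healthy"
}

#' Machine-readable scoring report
#'
#' JSON twin of the clinical scoring report: per-item / per-sub-figure
#' breakdown, total, binary label and per-stroke annotation, plus seed and
#' configuration provenance.
#'
#' @param result A `cdis_result`, `tmt_result` or `rocf_result`.
#' @param sample The scored [ink_sample()].
#' @param path Output JSON path.
#' @param seed Seed recorded as provenance (optional).
#' @return The report list, invisibly; written to `path` when given.
#' @export
scoring_report <- function(result, sample, path = NULL, seed = NULL) {
  test_type <- sample$test_type
  rep_ <- list(subject_id = sample$subject_id, test_type = test_type,
               seed = seed)
  if (inherits(result, "cdis_result")) {
    rep_$scheme <- "CDIS-20"
    rep_$items <- as.list(result$items)
    rep_$total <- result$total
    rep_$label <- label_sample("CDT", result$total)
  } else if (inherits(result, "tmt_result")) {
    rep_$scheme <- paste0("TMT-", result$part)
    rep_$completion_time_s <- result$completion_time
    rep_$hit_nodes <- result$hit_nodes
    rep_$missing_connections <- result$missing_connections
    rep_$error_notes <- result$error_notes
    rep_$stroke_status <- result$stroke_status
    rep_$label <- label_sample(test_type, result$completion_time)
  } else if (inherits(result, "rocf_result")) {
    rep_$scheme <- "ROCF-36"
    rep_$sub_scores <- result$sub_scores
    rep_$total <- result$total
    rep_$label <- label_sample(test_type, result$total)
  } else {
    stop("unknown result type", call. = FALSE)
  }
  if (!is.null(path)) {
    jsonlite::write_json(rep_, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  invisible(rep_)
}
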