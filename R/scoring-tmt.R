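# Trail Making Test: template matching and path analysis.

#' Score a Trail Making Test sample against a node template
#'
#' Reproduces the path taken by the subject: a node counts as hit when any
#' pen point lies within its radius; connections are inferred from the
#' temporal order of node visits along the pen path. The result reports hit
#' nodes, missing connections of the required sequence, transparent error
#' notes (skipped nodes, out-of-order transitions, repeated visits) and a
#' per-stroke annotation (`connects` / `non_connecting`). The completion
#' time is the interval between the first and last recorded timestamp, the
#' main clinical performance indicator.
#'
#' @param sample An [ink_sample()] with `test_type` `"TMT_A"` or `"TMT_B"`.
#' @param template A [tmt_template()] of the matching part.
#' @return An object of class `tmt_result`: `completion_time` (s),
#'   `hit_nodes` (1-based node indices), `visits` (node visit sequence),
#'   `missing_connections` (two-column matrix of required node pairs not
#'   drawn), `error_notes` (character) and `stroke_status`.
#' @export
score_tmt <- function(sample, template) {
  if (!inherits(template, "tmt_template")) stop("not a tmt_template",
                                                call. = FALSE)
  want <- paste0("TMT_", template$part)
  if (sample$test_type != want) {
    stop(sprintf("sample test_type %s does not match template part %s",
                 sample$test_type, template$part), call. = FALSE)
  }
  pts <- all_points(sample)
  if (nrow(pts) == 0L) stop("sample has no points", call. = FALSE)
  nodes <- template$nodes
  d2 <- outer(pts$x, nodes$x, "-")^2 + outer(pts$y, nodes$y, "-")^2
  nearest <- max.col(-d2)
  inside <- d2[cbind(seq_len(nrow(pts)), nearest)] <= template$radius^2
  assigned <- ifelse(inside, nearest, NA_integer_)

  keep <- !is.na(assigned)
  visits <- integer(0); visit_pt <- integer(0)
  if (any(keep)) {
    r <- rle(assigned[keep])
    visits <- r$values
    ends <- cumsum(r$lengths)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    visit_pt <- which(keep)[starts]
  }
  hit_nodes <- sort(unique(visits))

  required <- cbind(from = 1:24, to = 2:25)
  made <- logical(24)
  conn_pt <- rep(NA_integer_, 24)
  if (length(visits) > 1L) {
    for (k in seq_len(length(visits) - 1L)) {
      a <- visits[k]; b <- visits[k + 1L]
      if (b == a + 1L && !made[a]) {
        made[a] <- TRUE
        conn_pt[a] <- visit_pt[k + 1L]
      }
    }
  }
  missing <- required[!made, , drop = FALSE]

  notes <- character(0)
  never_hit <- setdiff(1:25, hit_nodes)
  for (nd in never_hit) {
    notes <- c(notes, sprintf("node %d (%s) never hit", nd,
                              nodes$symbol[nd]))
  }
  if (length(visits) > 1L) {
    for (k in seq_len(length(visits) - 1L)) {
      a <- visits[k]; b <- visits[k + 1L]
      if (b != a + 1L) {
        notes <- c(notes, sprintf("out-of-order transition %s -> %s",
                                  nodes$symbol[a], nodes$symbol[b]))
      }
    }
  }
  dup <- table(visits)
  for (nd in names(dup[dup > 1L])) {
    notes <- c(notes, sprintf("node %s visited %d times",
                              nodes$symbol[as.integer(nd)],
                              dup[[nd]]))
  }

  stroke_of_pt <- pts$stroke
  status <- rep("non_connecting", length(sample$strokes))
  good_pts <- conn_pt[!is.na(conn_pt)]
  if (length(good_pts)) {
    status[unique(stroke_of_pt[good_pts])] <- "connects"
  }

  structure(list(
    completion_time = completion_time(sample),
    hit_nodes = hit_nodes,
    visits = visits,
    missing_connections = missing,
    error_notes = notes,
    stroke_status = status,
    part = template$part
  ), class = "tmt_result")
}

#' @export
print.tmt_result <- function(x, ...) {
  cat(sprintf(
    "<tmt_result> part %s: %.1f s, %d/25 nodes hit, %d missing connections\n",
    x$part, x$completion_time, length(x$hit_nodes),
    nrow(x$missing_connections)))
  invisible(x)
}
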