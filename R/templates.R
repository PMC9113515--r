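# Synthetic assessment templates. The node layout of the trail-making sheet
# and the reference geometry of the complex figure are constructed here (the
# published instruments are under copyright and their exact coordinates are
# not part of any deposited dataset): both are deterministic schematic
# stand-ins on an A4 frame (210 x 297 mm, y downward) that preserve the
# structural properties the scorers rely on.

#' Trail Making Test template (synthetic layout)
#'
#' 25 circular nodes on an A4 sheet in the required visit order. Part A
#' carries the numbers 1-25; part B alternates numbers and letters
#' (1, A, 2, B, ... , 13). The layout is a serpentine 5x5 grid with
#' deterministic jitter so consecutive nodes are near each other (typical
#' trail geometry) and nodes never overlap.
#'
#' @param part `"A"` or `"B"`.
#' @param radius Node radius in mm (default 5).
#' @return A list of class `tmt_template` with elements `part`, `radius` and
#'   `nodes` (data.frame: `index`, `x`, `y`, `symbol` in visit order).
#' @export
#' @examples
#' tmt_template("B")$nodes$symbol[1:6]
tmt_template <- function(part = c("A", "B"), radius = 5) {
  part <- match.arg(part)
  idx <- 1:25
  row <- (idx - 1) %/% 5L
  col <- (idx - 1) %% 5L
  col <- ifelse(row %% 2L == 0L, col, 4L - col)  # serpentine
  x <- 25 + col * 40 + 6 * sin(idx * 1.7 + 0.3)
  y <- 30 + row * 59 + 6 * cos(idx * 2.3 + 1.1)
  symbol <- if (part == "A") {
    as.character(idx)
  } else {
    s <- character(25)
    s[seq(1, 25, by = 2)] <- as.character(1:13)
    s[seq(2, 24, by = 2)] <- LETTERS[1:12]
    s
  }
  structure(list(part = part, radius = radius,
                 nodes = data.frame(index = idx, x = x, y = y,
                                    symbol = symbol,
                                    stringsAsFactors = FALSE)),
            class = "tmt_template")
}

#' Complex-figure reference geometry (synthetic)
#'
#' A schematic of the 18 sub-figures of the standard complex figure (large
#' rectangle, diagonal cross, midlines, attached triangles, diamond, circle
#' with dots, parallel-line groups, outer crosses and squares), each given as
#' one or more reference polylines in mm on the A4 frame. Used by the
#' figure scorer for shape and placement checks and by the synthetic ink
#' generator as the drawing plan.
#'
#' @return A list of class `rocf_template`: 18 elements, each with `id`,
#'   `name` and `polylines` (list of two-column matrices).
#' @export
rocf_template <- function() {
  pl <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    colnames(m) <- c("x", "y")
    m
  }
  sub <- list(
    list(name = "cross_upper_left", polylines = list(
      pl(48, 62, 60, 62), pl(54, 56, 54, 68))),
    list(name = "large_rectangle", polylines = list(
      pl(65, 72, 145, 72, 145, 128, 65, 128, 65, 72))),
    list(name = "diagonal_cross", polylines = list(
      pl(65, 72, 145, 128), pl(65, 128, 145, 72))),
    list(name = "horizontal_midline", polylines = list(
      pl(65, 100, 145, 100))),
    list(name = "vertical_midline", polylines = list(
      pl(105, 72, 105, 128))),
    list(name = "small_rectangle", polylines = list(
      pl(65, 86, 85, 86, 85, 114, 65, 114, 65, 86),
      pl(65, 86, 85, 114), pl(65, 114, 85, 86))),
    list(name = "segment_above_small_rectangle", polylines = list(
      pl(70, 81, 80, 81))),
    list(name = "four_parallel_lines", polylines = list(
      pl(88, 84, 96, 78), pl(91, 87, 99, 81),
      pl(94, 90, 102, 84), pl(97, 93, 105, 87))),
    list(name = "triangle_above_right", polylines = list(
      pl(115, 72, 125, 62, 135, 72))),
    list(name = "small_vertical_line", polylines = list(
      pl(118, 78, 118, 88))),
    list(name = "circle_with_dots", polylines = {
      th <- seq(0, 2 * pi, length.out = 25)
      list(cbind(x = 128 + 6 * cos(th), y = 90 + 6 * sin(th)),
           pl(126, 88.5, 126.8, 88.5), pl(129.2, 88.5, 130, 88.5),
           pl(127.6, 92, 128.4, 92))
    }),
    list(name = "five_parallel_lines", polylines = list(
      pl(112, 112, 118, 106), pl(116, 115, 122, 109),
      pl(120, 118, 126, 112), pl(124, 121, 130, 115),
      pl(128, 124, 134, 118))),
    list(name = "triangle_right", polylines = list(
      pl(145, 72, 175, 100), pl(175, 100, 145, 128))),
    list(name = "diamond", polylines = list(
      pl(157, 104, 162, 111, 157, 118, 152, 111, 157, 104))),
    list(name = "vertical_line_in_triangle", polylines = list(
      pl(152, 88, 152, 112))),
    list(name = "horizontal_extension", polylines = list(
      pl(145, 100, 175, 100))),
    list(name = "cross_below", polylines = list(
      pl(105, 128, 105, 142), pl(98, 137, 112, 137))),
    list(name = "square_lower_left", polylines = list(
      pl(65, 128, 65, 144, 81, 144, 81, 128)))
  )
  out <- lapply(seq_along(sub), function(i) {
    c(list(id = i), sub[[i]])
  })
  structure(out, class = "rocf_template")
}

# Reference point cloud + bbox scale of one sub-figure
rocf_subfigure_points <- function(subfig, n = 64L) {
  lens <- vapply(subfig$polylines, function(m) {
    if (nrow(m) < 2L) 0 else sum(arc_lengths(m[, 1], m[, 2]))
  }, 0)
  total <- sum(lens)
  pts <- lapply(seq_along(subfig$polylines), function(i) {
    m <- subfig$polylines[[i]]
    ni <- if (total > 0) max(2L, round(n * lens[i] / total)) else 2L
    resample_polyline(m[, 1], m[, 2], ni)
  })
  do.call(rbind, pts)
}
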