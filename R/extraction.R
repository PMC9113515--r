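#' Extract feature vectors from a sample
#'
#' Applies a feature subset at sketch or stroke granularity. At sketch
#' granularity exactly one vector over the whole drawing is returned; at
#' stroke granularity one vector per stroke (each stroke treated as a
#' one-stroke sketch), in stroke order.
#'
#' @param sample An [ink_sample()].
#' @param subset Subset id: `"all176"`, `"lit165"` or `"cog11"`.
#' @param granularity `"sketch"` or `"stroke"`.
#' @param pause_threshold Pause threshold in ms (see [cognitive_features()]).
#' @return A list of named numeric feature vectors.
#' @export
#' @examples
#' s <- ink_sample(list(ink_stroke(c(0, 100), c(0, 3), c(0, 4))))
#' length(extract_features(s, "cog11", "sketch")[[1]])
extract_features <- function(sample, subset = "all176",
                             granularity = c("sketch", "stroke"),
                             pause_threshold = 200) {
  granularity <- match.arg(granularity)
  wanted <- feature_subset(subset)
  if (granularity == "sketch") {
    return(list(compute_features(sample, wanted, pause_threshold)))
  }
  lapply(sample$strokes, function(s) {
    sub <- ink_sample(list(s), test_type = sample$test_type,
                      subject_id = sample$subject_id)
    compute_features(sub, wanted, pause_threshold)
  })
}

#' Assemble a labeled feature table
#'
#' Builds the flat table the classification benchmark consumes. At stroke
#' granularity every stroke row carries its parent sketch's label (label
#' propagation); at sketch granularity there is one row per sample. Rows
#' whose features are all degenerate fallbacks are kept; only samples with
#' no strokes at all are rejected.
#'
#' @param samples A list of [labeled_sample()] objects or an `ink_cohort`.
#' @param subset Subset id (see [feature_subset()]).
#' @param granularity `"sketch"` or `"stroke"`.
#' @param pause_threshold Pause threshold in ms.
#' @return A `data.frame` of class `feature_table` with columns `sample_id`,
#'   `stroke_index` (-1 at sketch granularity), `label`, then one column per
#'   feature in registry subset order. Attributes `subset_id` and
#'   `granularity` record the configuration.
#' @export
build_feature_table <- function(samples, subset = "all176",
                                granularity = c("sketch", "stroke"),
                                pause_threshold = 200) {
  granularity <- match.arg(granularity)
  if (inherits(samples, "ink_cohort")) samples <- samples$samples
  if (length(samples) == 0L) stop("no samples supplied", call. = FALSE)
  wanted <- feature_subset(subset)
  rows <- vector("list", 0L)
  ids <- character(0); sidx <- integer(0); labels <- character(0)
  for (ls in samples) {
    stopifnot(inherits(ls, "labeled_sample"))
    vecs <- extract_features(ls$sample, subset, granularity, pause_threshold)
    for (k in seq_along(vecs)) {
      rows[[length(rows) + 1L]] <- vecs[[k]]
      ids <- c(ids, ls$sample$subject_id)
      sidx <- c(sidx, if (granularity == "sketch") -1L else k)
      labels <- c(labels, ls$label)
    }
  }
  feats <- do.call(rbind, rows)
  out <- data.frame(sample_id = ids, stroke_index = sidx, label = labels,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(feats))
  names(out) <- c("sample_id", "stroke_index", "label", wanted)
  attr(out, "subset_id") <- subset
  attr(out, "granularity") <- granularity
  class(out) <- c("feature_table", "data.frame")
  out
}

feature_columns <- function(table) {
  setdiff(names(table), c("sample_id", "stroke_index", "label"))
}

#' Write / read a feature table as CSV
#'
#' The header row holds registry feature names preceded by `sample_id`,
#' `stroke_index` and `label`; one row per sample (sketch granularity) or
#' per stroke.
#'
#' @param table A `feature_table`.
#' @param path CSV file path.
#' @param subset,granularity Configuration recorded when reading back (taken
#'   from the column layout when omitted).
#' @return `read_feature_table()` returns a `feature_table`;
#'   `write_feature_table()` returns `path` invisibly.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path, subset = NULL, granularity = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(subset)) {
    nf <- length(feature_columns(df))
    subset <- unname(c(`176` = "all176", `165` = "lit165",
                       `11` = "cog11")[as.character(nf)])
    if (is.na(subset)) stop("cannot infer subset from ", nf, " feature columns",
                            call. = FALSE)
  }
  if (is.null(granularity)) {
    granularity <- if (all(df$stroke_index == -1L)) "sketch" else "stroke"
  }
  attr(df, "subset_id") <- subset
  attr(df, "granularity") <- granularity
  class(df) <- c("feature_table", "data.frame")
  df
}
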