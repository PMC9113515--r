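#' Construct a single pen stroke
#'
#' A stroke is one pen-down to pen-up episode: an ordered run of timestamped
#' points with normalized pressure. Canonical units are milliseconds for time,
#' millimetres for coordinates (x to the right, y downward, the scan
#' convention) and pressure in `[0, 1]`.
#'
#' @param t Numeric vector of timestamps in milliseconds (non-decreasing).
#' @param x,y Numeric coordinate vectors in millimetres.
#' @param pressure Normalized pen force in `[0, 1]`; recycled to the number
#'   of points. Defaults to 0.5 (the neutral value used when a digitizer
#'   reports no force channel).
#' @return A `data.frame` with columns `t`, `x`, `y`, `pressure`.
#' @export
#' @examples
#' ink_stroke(t = c(0, 100), x = c(0, 3), y = c(0, 4))
ink_stroke <- function(t, x, y, pressure = 0.5) {
  n <- length(t)
  if (length(x) != n || length(y) != n) {
    stop("t, x and y must have equal length", call. = FALSE)
  }
  data.frame(
    t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
    pressure = rep_len(as.numeric(pressure), n)
  )
}

#' Construct an ink sample
#'
#' The universal input record: an ordered list of strokes plus the test type
#' it was recorded for. Constructors are permissive (so that invalid objects
#' can be built and inspected); [ink_validate()] reports invariant violations.
#'
#' @param strokes List of stroke data frames (see [ink_stroke()]).
#' @param test_type One of `"CDT"`, `"TMT_A"`, `"TMT_B"`, `"ROCF_COPY"`,
#'   `"ROCF_RECALL"`, `"ROCF_DELAYED"`, `"OTHER"`.
#' @param subject_id Opaque subject identifier.
#' @param metadata Named list of character metadata.
#' @return An object of class `ink_sample`.
#' @export
ink_sample <- function(strokes, test_type = "OTHER", subject_id = "anon",
                       metadata = list()) {
  test_type <- match.arg(test_type, ink_test_types())
  if (is.data.frame(strokes)) strokes <- list(strokes)
  structure(
    list(
      strokes = strokes,
      test_type = test_type,
      subject_id = as.character(subject_id),
      metadata = metadata
    ),
    class = "ink_sample"
  )
}

#' Recognised assessment types
#' @return Character vector of valid `test_type` values.
#' @export
ink_test_types <- function() {
  c("CDT", "TMT_A", "TMT_B", "ROCF_COPY", "ROCF_RECALL", "ROCF_DELAYED",
    "OTHER")
}

#' @export
print.ink_sample <- function(x, ...) {
  np <- sum(vapply(x$strokes, nrow, 0L))
  cat(sprintf("<ink_sample> %s  subject=%s  strokes=%d  points=%d  %.1f s\n",
              x$test_type, x$subject_id, length(x$strokes), np,
              tryCatch(completion_time(x), error = function(e) NA_real_)))
  invisible(x)
}

#' Attach a screening label and score to a sample
#'
#' @param sample An [ink_sample()].
#' @param label `"healthy"` or `"suspicious"`.
#' @param score The numeric test score (CDIS or ROCF total) or completion
#'   time in seconds (TMT).
#' @param truth Optional list of generator ground truth (segmentation,
#'   template, true scoring result).
#' @return An object of class `labeled_sample`.
#' @export
labeled_sample <- function(sample, label, score, truth = NULL) {
  label <- match.arg(label, c("healthy", "suspicious"))
  structure(list(sample = sample, label = label, score = as.numeric(score),
                 truth = truth),
            class = "labeled_sample")
}

# All points of a sample as one data.frame with a stroke index column.
all_points <- function(sample) {
  strokes <- sample$strokes
  if (length(strokes) == 0L) {
    return(data.frame(t = numeric(0), x = numeric(0), y = numeric(0),
                      pressure = numeric(0), stroke = integer(0)))
  }
  out <- do.call(rbind, strokes)
  out$stroke <- rep.int(seq_along(strokes), vapply(strokes, nrow, 0L))
  out
}

#' Validate an ink sample
#'
#' Report-only check of the data-model invariants: at least one stroke with at
#' least one point, non-decreasing timestamps within each stroke, finite
#' coordinates and pressure in `[0, 1]`, and strokes ordered by their first
#' timestamp.
#'
#' @param sample An [ink_sample()].
#' @return A `data.frame` with columns `stroke` (index, `NA` for sample-level
#'   issues) and `violation`; zero rows iff all invariants hold.
#' @export
ink_validate <- function(sample) {
  bad <- list()
  note <- function(stroke, violation) {
    bad[[length(bad) + 1L]] <<- data.frame(stroke = stroke,
                                           violation = violation)
  }
  if (length(sample$strokes) == 0L) {
    note(NA_integer_, "sample has no strokes")
  }
  firsts <- rep(NA_real_, length(sample$strokes))
  for (i in seq_along(sample$strokes)) {
    s <- sample$strokes[[i]]
    if (nrow(s) == 0L) {
      note(i, "empty stroke")
      next
    }
    firsts[i] <- s$t[1L]
    if (any(diff(s$t) < 0)) note(i, "timestamps decrease within stroke")
    if (any(!is.finite(s$t))) note(i, "non-finite timestamp")
    if (any(s$t < 0, na.rm = TRUE)) note(i, "negative timestamp")
    if (any(!is.finite(s$x)) || any(!is.finite(s$y))) {
      note(i, "non-finite coordinate")
    }
    if (any(s$pressure < 0 | s$pressure > 1, na.rm = TRUE)) {
      note(i, "pressure outside [0, 1]")
    }
  }
  if (length(firsts) > 1L && !any(is.na(firsts)) && any(diff(firsts) < 0)) {
    note(NA_integer_, "strokes not ordered by first timestamp")
  }
  if (length(bad) == 0L) {
    data.frame(stroke = integer(0), violation = character(0))
  } else {
    do.call(rbind, bad)
  }
}

#' Translate a sample to the coordinate origin
#'
#' Shifts all stroke coordinates so that `min(x) = 0` and `min(y) = 0` over
#' the whole sample. No scaling or any other normalisation is applied, so all
#' pairwise distances, timestamps and pressures are preserved and the
#' operation is idempotent.
#'
#' @param sample An [ink_sample()] with at least one point.
#' @return The translated `ink_sample`.
#' @export
translate_to_origin <- function(sample) {
  pts <- all_points(sample)
  if (nrow(pts) == 0L) stop("cannot translate an empty sample", call. = FALSE)
  mx <- min(pts$x); my <- min(pts$y)
  sample$strokes <- lapply(sample$strokes, function(s) {
    s$x <- s$x - mx; s$y <- s$y - my; s
  })
  sample
}

#' Completion time of a sample
#'
#' Time between the first recorded pen-stroke point and the last recorded
#' timestamp, in seconds.
#'
#' @param sample An [ink_sample()] with at least one point.
#' @return Duration in seconds (`>= 0`).
#' @export
completion_time <- function(sample) {
  pts <- all_points(sample)
  if (nrow(pts) == 0L) stop("sample has no points", call. = FALSE)
  (max(pts$t) - min(pts$t)) / 1000
}

# ---------------------------------------------------------------------------
# Serialization: InkML and JSON-lines

inkml_ns <- "http://www.w3.org/2003/InkML"

#' Write an ink sample to disk
#'
#' Two dialects are supported: W3C InkML (one `<trace>` per stroke, channel
#' order X Y T F with force already normalized to `[0, 1]`) and a JSON-lines
#' dialect (one sample per line with keys `sample_id`, `test_type`, `strokes`
#' and `metadata`). Output is bit-stable for identical input and round-trips
#' losslessly through [read_ink_sample()].
#'
#' @param sample An [ink_sample()].
#' @param path Output file path.
#' @param format `"inkml"` or `"jsonl"`.
#' @return Invisibly, `path`.
#' @export
write_ink_sample <- function(sample, path, format = c("inkml", "jsonl")) {
  format <- match.arg(format)
  if (format == "jsonl") {
    writeLines(jsonl_encode(sample), path, useBytes = TRUE)
    return(invisible(path))
  }
  lines <- c(
    sprintf("<ink xmlns=\"%s\">", inkml_ns),
    sprintf("  <annotation type=\"testType\">%s</annotation>", sample$test_type),
    sprintf("  <annotation type=\"subjectId\">%s</annotation>",
            xml_escape(sample$subject_id))
  )
  for (key in names(sample$metadata)) {
    lines <- c(lines, sprintf(
      "  <annotation type=\"meta:%s\">%s</annotation>",
      xml_escape(key), xml_escape(as.character(sample$metadata[[key]]))))
  }
  for (s in sample$strokes) {
    tuples <- paste(fmt_num(s$x), fmt_num(s$y), fmt_num(s$t),
                    fmt_num(s$pressure))
    lines <- c(lines, paste0("  <trace>", paste(tuples, collapse = ", "),
                             "</trace>"))
  }
  lines <- c(lines, "</ink>")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

jsonl_encode <- function(sample) {
  rec <- list(
    sample_id = sample$subject_id,
    test_type = sample$test_type,
    strokes = lapply(sample$strokes, function(s) {
      unname(as.matrix(s[, c("t", "x", "y", "pressure")]))
    })
  )
  if (length(sample$metadata) > 0L) rec$metadata <- sample$metadata
  # I(17) significant digits: exact text round-trip for doubles
  as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = I(17)))
}

jsonl_decode <- function(line) {
  rec <- jsonlite::fromJSON(line, simplifyVector = FALSE)
  strokes <- lapply(rec$strokes, function(s) {
    m <- matrix(as.numeric(unlist(s)), ncol = 4L, byrow = TRUE)
    ink_stroke(t = m[, 1], x = m[, 2], y = m[, 3], pressure = m[, 4])
  })
  ink_sample(strokes, test_type = rec$test_type %||% "OTHER",
             subject_id = rec$sample_id %||% "anon",
             metadata = rec$metadata %||% list())
}

#' Read an ink sample from disk
#'
#' Counterpart of [write_ink_sample()]. For JSON-lines files holding several
#' samples the first record is returned; use [read_ink_samples()] for the
#' whole file. InkML traces with three values per tuple (no force channel)
#' receive the default pressure 0.5 with a warning.
#'
#' @param path Input file path.
#' @param format `"inkml"` or `"jsonl"`.
#' @return An [ink_sample()].
#' @export
read_ink_sample <- function(path, format = c("inkml", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) stop("empty jsonl file: ", path, call. = FALSE)
    return(jsonl_decode(lines[[1L]]))
  }
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("malformed InkML in ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  ann <- xml2::xml_find_all(doc, ".//*[local-name()='annotation']")
  types <- xml2::xml_attr(ann, "type")
  vals <- xml2::xml_text(ann)
  meta_idx <- grepl("^meta:", types)
  metadata <- as.list(vals[meta_idx])
  names(metadata) <- sub("^meta:", "", types[meta_idx])
  test_type <- if (any(types == "testType")) vals[types == "testType"][1L] else "OTHER"
  subject_id <- if (any(types == "subjectId")) vals[types == "subjectId"][1L] else "anon"
  traces <- xml2::xml_find_all(doc, ".//*[local-name()='trace']")
  if (length(traces) == 0L) {
    stop("malformed InkML in ", path, ": no <trace> element", call. = FALSE)
  }
  default_pressure_used <- FALSE
  strokes <- lapply(seq_along(traces), function(i) {
    txt <- xml2::xml_text(traces[[i]])
    tuples <- strsplit(trimws(strsplit(txt, ",", fixed = TRUE)[[1L]]), "\\s+")
    tuples <- tuples[vapply(tuples, function(v) any(nzchar(v)), TRUE)]
    nv <- vapply(tuples, length, 0L)
    if (any(nv != nv[1L]) || !(nv[1L] %in% c(3L, 4L))) {
      stop(sprintf("malformed InkML in %s: trace %d has inconsistent tuples",
                   path, i), call. = FALSE)
    }
    m <- do.call(rbind, lapply(tuples, as.numeric))
    if (any(!is.finite(m))) {
      stop(sprintf("malformed InkML in %s: non-numeric value in trace %d",
                   path, i), call. = FALSE)
    }
    if (ncol(m) == 3L) {
      default_pressure_used <<- TRUE
      ink_stroke(t = m[, 3], x = m[, 1], y = m[, 2], pressure = 0.5)
    } else {
      ink_stroke(t = m[, 3], x = m[, 1], y = m[, 2], pressure = m[, 4])
    }
  })
  if (default_pressure_used) {
    warning("pressure channel missing; defaulting to 0.5", call. = FALSE)
  }
  ink_sample(strokes, test_type = test_type, subject_id = subject_id,
             metadata = metadata)
}

#' Read / write several samples as JSON-lines
#'
#' @param samples List of [ink_sample()] objects.
#' @param path File path.
#' @return `read_ink_samples()` returns a list of `ink_sample` objects;
#'   `write_ink_samples()` returns `path` invisibly.
#' @export
write_ink_samples <- function(samples, path) {
  writeLines(vapply(samples, jsonl_encode, ""), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_ink_samples
#' @export
read_ink_samples <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lapply(lines[nzchar(lines)], jsonl_decode)
}
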