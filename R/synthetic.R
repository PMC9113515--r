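# Synthetic digital ink: cohorts of clock, trail and complex-figure drawings
# with ground-truth segmentation and labels, emulating the qualitative
# motor signature of cognitive impairment reported for elderly writers --
# slower, less regular movement, lower pen pressure, more and longer pauses,
# tremor, and omitted figure elements. Effect magnitudes are this package's
# own calibration (no quantitative elderly pen kinematics are deposited);
# all are configurable through the behaviour profile.

#' Behaviour profile of a synthetic writer
#'
#' @param mean_velocity Mean pen-down drawing speed (mm/s).
#' @param velocity_cv Coefficient of variation of per-stroke speed
#'   (movement regularity; higher in impairment).
#' @param mean_pressure Mean normalized pen force in `[0, 1]`.
#' @param pause_rate Expected pauses per minute.
#' @param mean_pause Mean pause duration (ms).
#' @param tremor_amplitude Gaussian jitter added to every point (mm).
#' @param omission_prob Probability of omitting each clock element, trail
#'   node or figure sub-figure.
#' @return An object of class `behavior_profile`.
#' @export
behavior_profile <- function(mean_velocity = 25, velocity_cv = 0.2,
                             mean_pressure = 0.6, pause_rate = 2,
                             mean_pause = 400, tremor_amplitude = 0.15,
                             omission_prob = 0) {
  stopifnot(mean_velocity > 0, velocity_cv >= 0,
            mean_pressure >= 0, mean_pressure <= 1,
            pause_rate >= 0, mean_pause >= 0, tremor_amplitude >= 0,
            omission_prob >= 0, omission_prob <= 1)
  structure(as.list(environment()), class = "behavior_profile")
}

#' Default cohort profiles
#'
#' `healthy_profile()` models an unimpaired elderly writer;
#' `impaired_profile()` realizes the impairment directions reported in the
#' clinical handwriting literature: roughly halved drawing speed, less
#' regular movement, lower pressure, three times the pause rate with much
#' longer pauses, stronger tremor, and occasional omissions of figure
#' elements.
#'
#' @return A [behavior_profile()].
#' @export
healthy_profile <- function() behavior_profile()

#' @rdname healthy_profile
#' @export
impaired_profile <- function() {
  behavior_profile(mean_velocity = 12, velocity_cv = 0.35,
                   mean_pressure = 0.45, pause_rate = 6, mean_pause = 1500,
                   tremor_amplitude = 0.5, omission_prob = 0.15)
}

.ink_hz <- 100  # digitizer sampling rate (Hz) of the generator

# Draw a per-stroke speed from the profile (truncated normal).
draw_speed <- function(profile) {
  max(0.15 * profile$mean_velocity,
      stats::rnorm(1, profile$mean_velocity,
                   profile$velocity_cv * profile$mean_velocity))
}

# Physiological tremor: a 4-8 Hz oscillation with random phase per stroke
# (independent per-sample noise would inflate the drawn path length and make
# tremulous writers look fast; an oscillatory model keeps kinematics honest).
tremor_offsets <- function(t_ms, amplitude) {
  if (amplitude <= 0 || length(t_ms) == 0L) {
    return(list(dx = rep(0, length(t_ms)), dy = rep(0, length(t_ms))))
  }
  f <- stats::runif(1, 4, 8)
  ph <- stats::runif(2, 0, 2 * pi)
  w <- 2 * pi * f * t_ms / 1000
  list(dx = amplitude * sin(w + ph[1]), dy = amplitude * sin(w + ph[2]))
}

# Trace one polyline as a pen-down stroke starting at time t0 (ms).
trace_stroke <- function(poly, t0, profile, speed = draw_speed(profile)) {
  L <- if (nrow(poly) > 1L) sum(arc_lengths(poly[, 1], poly[, 2])) else 0
  dt <- 1000 / .ink_hz
  n <- max(2L, ceiling(L / speed * .ink_hz))
  r <- resample_polyline(poly[, 1], poly[, 2], n)
  tt <- t0 + (seq_len(n) - 1L) * dt
  tr <- tremor_offsets(tt, profile$tremor_amplitude)
  p <- pmin(1, pmax(0.02, stats::rnorm(n, profile$mean_pressure, 0.05)))
  ink_stroke(t = tt, x = r[, 1] + tr$dx, y = r[, 2] + tr$dy, pressure = p)
}

# Assemble strokes from a list of polylines with lifts and pauses between
# them. Returns a list of stroke data frames.
assemble_strokes <- function(polys, profile) {
  n <- length(polys)
  speeds <- vapply(seq_len(n), function(i) draw_speed(profile), 0)
  lens <- vapply(polys, function(m) {
    if (nrow(m) > 1L) sum(arc_lengths(m[, 1], m[, 2])) else 0
  }, 0)
  durs <- pmax(1000 / .ink_hz,
               ceiling(lens / speeds * .ink_hz) * (1000 / .ink_hz))
  lifts <- if (n > 1L) 120 + stats::rexp(n - 1L, 1 / 80) else numeric(0)
  est_min <- (sum(durs) + sum(lifts)) / 60000
  n_pauses <- stats::rpois(1, profile$pause_rate * est_min)
  if (n_pauses > 0L && length(lifts) > 0L) {
    at <- sample.int(length(lifts), min(n_pauses, length(lifts)))
    lifts[at] <- lifts[at] + profile$mean_pause *
      (0.5 + stats::rexp(length(at), 2))
  }
  strokes <- vector("list", n)
  t0 <- 0
  for (i in seq_len(n)) {
    strokes[[i]] <- trace_stroke(polys[[i]], t0, profile, speeds[i])
    t0 <- strokes[[i]]$t[nrow(strokes[[i]])] +
      if (i < n) lifts[i] else 0
  }
  strokes
}

# Small digit glyph polyline (zig-zag) centred at (cx, cy).
digit_glyph <- function(cx, cy, h = 5) {
  w <- 0.6 * h
  cbind(x = cx + c(-w / 2, -w / 2, w / 2, w / 2),
        y = cy + c(h / 2, -h / 2, h / 2, -h / 2))
}

#' Generate a synthetic clock drawing
#'
#' Emits the clock face circle, twelve digit glyphs at the clock positions,
#' hour and minute hands at the target time and a centre dot, traced at the
#' profile's speed, pressure and tremor. Each element other than the circle
#' is omitted with the profile's `omission_prob`. The ground-truth
#' segmentation and the CDIS result of scoring the emitted ink with it are
#' returned alongside.
#'
#' @param profile A [behavior_profile()].
#' @param seed Optional integer seed (uses the current RNG stream when
#'   `NULL`, as inside [generate_cohort()]).
#' @param target_time Target time as `"H:MM"` (default `"11:10"`).
#' @param center,radius Clock face placement (mm).
#' @return List with `sample` ([ink_sample()]), `segmentation`
#'   ([clock_segmentation()]) and `result` (`cdis_result`).
#' @export
generate_clock <- function(profile, seed = NULL, target_time = "11:10",
                           center = c(105, 120), radius = 30) {
  if (!is.null(seed)) set.seed(seed)
  th <- seq(-87, 267, length.out = 120) * pi / 180
  polys <- list(cbind(x = center[1] + radius * cos(th),
                      y = center[2] + radius * sin(th)))
  classes <- "circle"
  for (d in 1:12) {
    if (stats::runif(1) < profile$omission_prob) next
    a <- (d * 30 - 90) * pi / 180
    polys <- c(polys, list(digit_glyph(center[1] + 0.8 * radius * cos(a),
                                       center[2] + 0.8 * radius * sin(a))))
    classes <- c(classes, paste0("digit_", d))
  }
  tm <- as.numeric(strsplit(target_time, ":", fixed = TRUE)[[1L]])
  hand <- function(angle_deg, frac) {
    a <- angle_deg * pi / 180
    cbind(x = center[1] + c(0.02, frac) * radius * cos(a),
          y = center[2] + c(0.02, frac) * radius * sin(a))
  }
  if (stats::runif(1) >= profile$omission_prob) {
    polys <- c(polys, list(hand(((tm[1] %% 12) + tm[2] / 60) * 30 - 90, 0.5)))
    classes <- c(classes, "hour_hand")
  }
  if (stats::runif(1) >= profile$omission_prob) {
    polys <- c(polys, list(hand(tm[2] * 6 - 90, 0.8)))
    classes <- c(classes, "minute_hand")
  }
  if (stats::runif(1) >= profile$omission_prob) {
    polys <- c(polys, list(cbind(x = center[1] + c(-0.25, 0.25),
                                 y = center[2] + c(0, 0))))
    classes <- c(classes, "center_point")
  }
  strokes <- assemble_strokes(polys, profile)
  sample <- ink_sample(strokes, test_type = "CDT")
  seg <- clock_segmentation(classes)
  list(sample = sample, segmentation = seg,
       result = score_cdt(sample, seg,
                          cdis_params(target_time = target_time)))
}

#' Generate a synthetic trail drawing
#'
#' A single pen-down trail visiting the 25 template nodes in the required
#' order (each intermediate node skipped with `omission_prob`), with a
#' per-node decision dwell (longer for part B's set shifting), profile-driven
#' speed, tremor, pressure and pauses. The template and the path-analysis
#' result of the emitted ink are returned alongside.
#'
#' @param part `"A"` or `"B"`.
#' @param profile A [behavior_profile()].
#' @param seed Optional integer seed.
#' @return List with `sample`, `template` ([tmt_template()]) and `result`
#'   (`tmt_result`).
#' @export
generate_tmt <- function(part = c("A", "B"), profile, seed = NULL) {
  part <- match.arg(part)
  if (!is.null(seed)) set.seed(seed)
  template <- tmt_template(part)
  keep <- c(TRUE, stats::runif(23) >= profile$omission_prob, TRUE)
  nodes <- template$nodes[keep, ]
  dwell_len <- if (part == "A") 8 else 24  # decision dwell as path-equivalent mm
  dt <- 1000 / .ink_hz
  xs <- numeric(0); ys <- numeric(0); ts <- numeric(0)
  t0 <- 0
  for (i in seq_len(nrow(nodes) - 1L)) {
    hop <- cbind(x = c(nodes$x[i], nodes$x[i + 1L]),
                 y = c(nodes$y[i], nodes$y[i + 1L]))
    v <- draw_speed(profile)
    L <- pt_dist(hop[1, 1], hop[1, 2], hop[2, 1], hop[2, 2])
    n <- max(2L, ceiling(L / v * .ink_hz))
    r <- resample_polyline(hop[, 1], hop[, 2], n)
    tt <- t0 + (seq_len(n) - 1L) * dt
    if (i > 1L) { r <- r[-1L, , drop = FALSE]; tt <- tt[-1L] }
    xs <- c(xs, r[, 1]); ys <- c(ys, r[, 2]); ts <- c(ts, tt)
    t0 <- tt[length(tt)] + dwell_len / v * 1000
    if (stats::runif(1) < profile$pause_rate * (L / v) / 60) {
      t0 <- t0 + profile$mean_pause * (0.5 + stats::rexp(1, 2))
    }
  }
  n <- length(xs)
  tr <- tremor_offsets(ts, profile$tremor_amplitude)
  stroke <- ink_stroke(
    t = ts, x = xs + tr$dx, y = ys + tr$dy,
    pressure = pmin(1, pmax(0.02, stats::rnorm(n, profile$mean_pressure,
                                               0.05))))
  sample <- ink_sample(list(stroke), test_type = paste0("TMT_", part))
  list(sample = sample, template = template,
       result = score_tmt(sample, template))
}

#' Generate a synthetic complex-figure drawing
#'
#' Each of the 18 reference sub-figures is drawn (with tremor and a
#' per-sub-figure placement offset scaled by the tremor amplitude) unless
#' omitted with `omission_prob`. If every sub-figure is omitted the sample
#' is rejected as empty, mirroring the discard rule for participants who did
#' not sketch anything.
#'
#' @param profile A [behavior_profile()].
#' @param seed Optional integer seed.
#' @param test_type One of the ROCF test types.
#' @return List with `sample`, `assignment` (ground-truth stroke to
#'   sub-figure map) and `result` (`rocf_result`).
#' @export
generate_rocf <- function(profile, seed = NULL, test_type = "ROCF_COPY") {
  if (!is.null(seed)) set.seed(seed)
  template <- rocf_template()
  keep <- stats::runif(18) >= profile$omission_prob
  if (!any(keep)) {
    stop("empty figure: every sub-figure was omitted", call. = FALSE)
  }
  polys <- list(); assignment <- integer(0)
  for (k in which(keep)) {
    shift <- stats::rnorm(2, 0, 2 * profile$tremor_amplitude)
    for (m in template[[k]]$polylines) {
      polys <- c(polys, list(cbind(x = m[, 1] + shift[1],
                                   y = m[, 2] + shift[2])))
      assignment <- c(assignment, k)
    }
  }
  strokes <- assemble_strokes(polys, profile)
  sample <- ink_sample(strokes, test_type = test_type)
  list(sample = sample, assignment = assignment,
       result = score_rocf(sample, assignment, template))
}

#' Cohort specification
#'
#' @param n Number of subjects (>= 1).
#' @param prevalence Fraction of subjects drawn from the impaired profile
#'   (the labels themselves come from scoring the generated ink, so the
#'   synthetic classification task keeps realistic boundary overlap).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @param tests Character vector of test types generated per subject.
#' @param healthy_profile,impaired_profile The two [behavior_profile()]s.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n, prevalence = 0.35, seed = 1, tests = "CDT",
                        healthy_profile = inkassess::healthy_profile(),
                        impaired_profile = inkassess::impaired_profile()) {
  stopifnot(n >= 1, prevalence >= 0, prevalence <= 1,
            all(tests %in% setdiff(ink_test_types(), "OTHER")))
  structure(list(n = as.integer(n), prevalence = prevalence,
                 seed = as.integer(seed), tests = tests,
                 healthy_profile = healthy_profile,
                 impaired_profile = impaired_profile),
            class = "cohort_spec")
}

#' Generate a labeled synthetic cohort
#'
#' `round(n * prevalence)` subjects are drawn from the impaired profile and
#' the rest from the healthy one; every subject produces one sample per test
#' in `spec$tests`. Each sample's label is derived by applying the binary
#' labeling rules to its true score -- never from the generating profile --
#' so impaired subjects can score in the healthy range and vice versa.
#' Complex-figure draws that come out empty (all sub-figures omitted) are
#' redrawn, mirroring the discard of empty sketches.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `ink_cohort`: list with `samples` (list of
#'   [labeled_sample()], each with truth attached) and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n_imp <- round(spec$n * spec$prevalence)
  impaired <- sample(rep(c(TRUE, FALSE), c(n_imp, spec$n - n_imp)))
  samples <- list()
  for (i in seq_len(spec$n)) {
    profile <- if (impaired[i]) spec$impaired_profile else spec$healthy_profile
    sid <- sprintf("S%04d", i)
    for (tt in spec$tests) {
      gen <- switch(tt,
        CDT = generate_clock(profile),
        TMT_A = generate_tmt("A", profile),
        TMT_B = generate_tmt("B", profile),
        {
          out <- NULL
          for (try in 1:25) {
            out <- tryCatch(generate_rocf(profile, test_type = tt),
                            error = function(e) NULL)
            if (!is.null(out)) break
          }
          if (is.null(out)) stop("could not draw a non-empty figure",
                                 call. = FALSE)
          out
        })
      gen$sample$subject_id <- sid
      score <- if (tt %in% c("TMT_A", "TMT_B")) {
        gen$result$completion_time
      } else {
        gen$result$total
      }
      truth <- c(gen[setdiff(names(gen), "sample")],
                 list(impaired = impaired[i]))
      samples[[length(samples) + 1L]] <-
        labeled_sample(gen$sample, label_sample(tt, score), score, truth)
    }
  }
  structure(list(samples = samples, spec = spec), class = "ink_cohort")
}

#' @export
print.ink_cohort <- function(x, ...) {
  labs <- vapply(x$samples, `[[`, "", "label")
  cat(sprintf("<ink_cohort> %d samples (%d suspicious) from %d subjects\n",
              length(x$samples), sum(labs == "suspicious"), x$spec$n))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Samples go to a JSON-lines file via the ink writers; labels, scores and
#' ground truth summaries go to a JSON sidecar carrying the seed.
#'
#' @param cohort An `ink_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ink_path <- file.path(dir, "cohort.jsonl")
  write_ink_samples(lapply(cohort$samples, `[[`, "sample"), ink_path)
  sidecar <- list(
    seed = cohort$spec$seed, n = cohort$spec$n,
    prevalence = cohort$spec$prevalence, tests = cohort$spec$tests,
    samples = lapply(cohort$samples, function(ls) {
      list(subject_id = ls$sample$subject_id,
           test_type = ls$sample$test_type,
           label = ls$label, score = ls$score,
           impaired_profile = isTRUE(ls$truth$impaired))
    }))
  truth_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(sidecar, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(ink_path, truth_path))
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory holding `cohort.jsonl` and `ground_truth.json`.
#' @return An `ink_cohort` (without generator ground truth beyond labels).
#' @export
read_cohort <- function(dir) {
  inks <- read_ink_samples(file.path(dir, "cohort.jsonl"))
  side <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                              simplifyVector = FALSE)
  stopifnot(length(inks) == length(side$samples))
  samples <- lapply(seq_along(inks), function(i) {
    rec <- side$samples[[i]]
    labeled_sample(inks[[i]], rec$label, rec$score,
                   truth = list(impaired = isTRUE(rec$impaired_profile)))
  })
  spec <- cohort_spec(n = side$n, prevalence = side$prevalence,
                      seed = side$seed, tests = unlist(side$tests))
  structure(list(samples = samples, spec = spec), class = "ink_cohort")
}
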