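test_that("registry has the fixed cardinalities and unique names", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 176L)
  counts <- table(reg$family)
  expect_equal(counts[["rubine"]], 13L)
  expect_equal(counts[["willems"]], 89L)
  expect_equal(counts[["hbf49"]], 49L)
  expect_equal(counts[["sonntag"]], 14L)
  expect_equal(counts[["cognitive"]], 11L)
  expect_false(anyDuplicated(reg$name) > 0)
  expect_length(feature_subset("all176"), 176L)
  expect_length(feature_subset("lit165"), 165L)
  expect_length(feature_subset("cog11"), 11L)
  expect_setequal(feature_subset("lit165"),
                  setdiff(feature_subset("all176"), feature_subset("cog11")))
  expect_error(feature_subset("nope"), "all176")
})

test_that("stroke-appearance features match closed-form values", {
  # horizontal straight stroke, uniform sampling
  h <- mk_sample(mk_stroke(seq(0, 100, by = 25), seq(0, 10, by = 2.5),
                           rep(0, 5)))
  f <- rubine_features(h)
  expect_equal(unname(f["rubine.cos_initial"]), 1)
  expect_equal(unname(f["rubine.sin_initial"]), 0)
  expect_equal(unname(f["rubine.total_angle"]), 0)
  expect_equal(unname(f["rubine.path_length"]), 10)

  # 2-point stroke (0,0)@0ms -> (3,4)@100ms: path 5 mm, speed 50 mm/s
  two <- mk_sample(mk_stroke(c(0, 100), c(0, 3), c(0, 4)))
  f2 <- rubine_features(two)
  expect_equal(unname(f2["rubine.path_length"]), 5)
  expect_equal(unname(f2["rubine.max_speed_sq"]), 50^2)
  expect_equal(unname(f2["rubine.duration"]), 0.1)
  expect_equal(unname(f2["rubine.endpoint_dist"]), 5)
})

test_that("trajectory features: straight lines, hull, pressure stats", {
  line <- mk_sample(mk_stroke(seq(0, 90, by = 10), 0:9, 0:9,
                              pressure = seq(0.1, 1, by = 0.1)))
  f <- willems_features(line)
  expect_equal(unname(f["willems.abs_angle_sum"]), 0)
  expect_equal(unname(f["willems.perpendicularity"]), 0)
  expect_equal(unname(f["willems.n_crossings"]), 0)
  expect_equal(unname(f["willems.pressure_mean"]), mean(seq(0.1, 1, 0.1)))
  expect_equal(unname(f["willems.pressure_first"]), 0.1)
  expect_equal(unname(f["willems.closure"]), 1)  # open straight line

  # closed polyline over the unit-square corners: hull area exactly 1
  sq <- mk_sample(mk_stroke(0:4 * 50, c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0)))
  fs <- willems_features(sq)
  expect_equal(unname(fs["willems.hull_area"]), 1)
  expect_equal(unname(fs["willems.hull_perimeter"]), 4)

  # a figure-eight style crossing is detected
  x8 <- mk_sample(mk_stroke(0:3 * 30, c(0, 10, 0, 10), c(0, 10, 10, 0)))
  expect_gte(unname(willems_features(x8)["willems.n_crossings"]), 1)
})

test_that("baseline-49 features are translation invariant by construction", {
  s <- random_sample(3, 15, seed = 42)
  f0 <- hbf49_features(s)
  shift <- s
  shift$strokes <- lapply(shift$strokes, function(st) {
    st$x <- st$x + 123.4; st$y <- st$y - 77.7; st
  })
  expect_equal(hbf49_features(shift), f0, tolerance = 1e-9)
})

test_that("eccentricity separates a circle from an elongated ellipse", {
  th <- seq(0, 2 * pi, length.out = 80)
  circle <- mk_sample(mk_stroke(seq_along(th) * 10, 10 * cos(th),
                                10 * sin(th)))
  ellipse <- mk_sample(mk_stroke(seq_along(th) * 10, 25 * cos(th),
                                 5 * sin(th)))
  ec <- unname(hbf49_features(circle)["hbf49.eccentricity"])
  ee <- unname(hbf49_features(ellipse)["hbf49.eccentricity"])
  expect_lt(ec, 0.25)
  expect_gt(ee, ec)
  expect_gt(ee, 0.9)
})

test_that("mode-detection descriptors: closure limit and scale freedom", {
  th <- seq(0, 2 * pi * 0.98, length.out = 60)  # nearly closed circle
  circ <- mk_sample(mk_stroke(seq_along(th) * 10, 20 * cos(th),
                              20 * sin(th)))
  f <- sonntag_features(circ)
  expect_lt(unname(f["sonntag.closure"]), 0.05)

  # doubling the scale leaves the closure ratio unchanged
  big <- circ
  big$strokes[[1]]$x <- 2 * big$strokes[[1]]$x
  big$strokes[[1]]$y <- 2 * big$strokes[[1]]$y
  expect_equal(unname(sonntag_features(big)["sonntag.closure"]),
               unname(f["sonntag.closure"]), tolerance = 1e-12)
  expect_equal(unname(sonntag_features(big)["sonntag.length"]),
               2 * unname(f["sonntag.length"]), tolerance = 1e-12)
})

test_that("cognitive features implement the pause/lift arithmetic", {
  single <- mk_sample(mk_stroke(c(0, 500), c(0, 5), c(0, 0)))
  f1 <- cognitive_features(single)
  expect_length(f1, 11L)
  expect_equal(unname(f1["cog.n_strokes"]), 1)
  expect_equal(unname(f1["cog.n_pauses"]), 0)
  expect_equal(unname(f1["cog.avg_lift_duration"]), 0)
  expect_equal(unname(f1["cog.sketch_pause_ratio"]), 0)  # guard value

  # strokes of 1000 and 1500 ms separated by a 500 ms gap
  two <- mk_sample(mk_stroke(c(0, 1000), c(0, 10), c(0, 0)),
                   mk_stroke(c(1500, 3000), c(10, 20), c(0, 0)))
  f2 <- cognitive_features(two)
  expect_equal(unname(f2["cog.sketching_time"]), 2.5)
  expect_equal(unname(f2["cog.n_pauses"]), 1)
  expect_equal(unname(f2["cog.avg_pause_duration"]), 0.5)
  expect_equal(unname(f2["cog.avg_lift_duration"]), 0.5)
  expect_equal(unname(f2["cog.sketch_pause_ratio"]), 5)
  expect_equal(unname(f2["cog.duration"]), 3)

  # a 150 ms gap is a lift but not a pause at the 200 ms threshold
  short <- mk_sample(mk_stroke(c(0, 1000), c(0, 10), c(0, 0)),
                     mk_stroke(c(1150, 2000), c(10, 20), c(0, 0)))
  f3 <- cognitive_features(short)
  expect_equal(unname(f3["cog.n_pauses"]), 0)
  expect_equal(unname(f3["cog.avg_lift_duration"]), 0.15)
})

test_that("no feature family ever emits NaN or Inf on degenerate input", {
  degenerates <- list(
    mk_sample(mk_stroke(0, 5, 5)),                       # single point
    mk_sample(mk_stroke(c(0, 0), c(1, 1), c(2, 2))),     # zero duration
    mk_sample(mk_stroke(c(0, 10, 20), c(3, 3, 3), c(4, 4, 4))),  # no extent
    mk_sample(mk_stroke(0, 1, 1), mk_stroke(10, 2, 2))   # two dots
  )
  for (s in degenerates) {
    v <- extract_features(s, "all176", "sketch")[[1]]
    expect_length(v, 176L)
    expect_true(all(is.finite(v)))
  }
})

test_that("feature vectors are deterministic and translation invariant", {
  s <- random_sample(4, 12, seed = 9)
  v1 <- extract_features(s, "all176", "sketch")[[1]]
  v2 <- extract_features(s, "all176", "sketch")[[1]]
  expect_identical(v1, v2)

  set.seed(33)
  for (rep in 1:20) {
    sr <- random_sample(base::sample(1:4, 1), 10)
    v0 <- extract_features(sr, "all176", "sketch")[[1]]
    shifted <- sr
    dx <- stats::runif(1, -500, 500); dy <- stats::runif(1, -500, 500)
    shifted$strokes <- lapply(shifted$strokes, function(st) {
      st$x <- st$x + dx; st$y <- st$y + dy; st
    })
    vs <- extract_features(shifted, "all176", "sketch")[[1]]
    expect_equal(vs, v0, tolerance = 1e-8)
  }
})

test_that("kinematic features agree with the finite-difference oracle", {
  set.seed(21)
  for (rep in 1:100) {
    n <- base::sample(2:20, 1)
    s <- mk_stroke(cumsum(c(0, stats::runif(n - 1, 5, 40))),
                   stats::runif(n, 0, 50), stats::runif(n, 0, 50))
    sm <- mk_sample(s)
    v <- oracle_speeds(s)
    f <- willems_features(sm)
    expect_equal(unname(f["willems.speed_max"]), max(v), tolerance = 1e-9)
    expect_equal(unname(f["willems.speed_mean"]), mean(v), tolerance = 1e-9)
    expect_equal(unname(rubine_features(sm)["rubine.max_speed_sq"]),
                 max(v)^2, tolerance = 1e-9)
  }
})

test_that("hull features agree with the gift-wrapping oracle", {
  set.seed(8)
  for (rep in 1:60) {
    n <- base::sample(3:15, 1)
    x <- stats::runif(n, 0, 30); y <- stats::runif(n, 0, 30)
    s <- mk_sample(mk_stroke(seq_len(n) * 10, x, y))
    f <- willems_features(s)
    o <- oracle_hull(x, y)
    expect_equal(unname(f["willems.hull_area"]), o$area, tolerance = 1e-9)
    expect_equal(unname(f["willems.hull_perimeter"]), o$perimeter,
                 tolerance = 1e-9)
  }
})
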