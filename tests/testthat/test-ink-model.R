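test_that("InkML and JSON-lines round-trips are field-exact", {
  s <- random_sample(4, 12, seed = 101)
  s$test_type <- "CDT"
  s$subject_id <- "S0042"
  s$metadata <- list(device = "pen-1", note = "a<b&c")
  for (fmt in c("inkml", "jsonl")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_ink_sample(s, path, fmt)
    r <- read_ink_sample(path, fmt)
    expect_identical(lapply(r$strokes, as.matrix),
                     lapply(s$strokes, as.matrix))
    expect_identical(r$test_type, s$test_type)
    expect_identical(r$subject_id, s$subject_id)
    expect_identical(r$metadata, s$metadata)
    # bit-stable output for identical input
    path2 <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_ink_sample(s, path2, fmt)
    expect_identical(readLines(path), readLines(path2))
  }
})

test_that("InkML structural mapping and pressure defaulting work", {
  path <- withr::local_tempfile(fileext = ".inkml")
  writeLines(c(
    '<ink xmlns="http://www.w3.org/2003/InkML">',
    "  <trace>1 2 0 0.5, 3 4 10 0.6, 5 6 20 0.7</trace>",
    "</ink>"), path)
  s <- read_ink_sample(path, "inkml")
  expect_length(s$strokes, 1L)
  expect_equal(nrow(s$strokes[[1]]), 3L)
  expect_equal(s$strokes[[1]]$x, c(1, 3, 5))
  expect_equal(s$strokes[[1]]$t, c(0, 10, 20))

  # three-value tuples: missing force channel -> default 0.5 with warning
  writeLines(c(
    '<ink xmlns="http://www.w3.org/2003/InkML">',
    "  <trace>1 2 0, 3 4 10</trace>",
    "</ink>"), path)
  expect_warning(s2 <- read_ink_sample(path, "inkml"), "pressure")
  expect_equal(s2$strokes[[1]]$pressure, c(0.5, 0.5))

  writeLines("<ink><trace>not numbers</trace></ink>", path)
  expect_error(read_ink_sample(path, "inkml"), "malformed|trace")
})

test_that("a sample without metadata round-trips and serializes pressure", {
  s <- mk_sample(mk_stroke(c(0, 10), c(0, 1), c(0, 1), pressure = 1))
  path <- withr::local_tempfile(fileext = ".inkml")
  write_ink_sample(s, path, "inkml")
  expect_false(any(grepl("meta:", readLines(path))))
  expect_true(any(grepl("\\b1\\b", readLines(path))))
  r <- read_ink_sample(path, "inkml")
  expect_equal(r$strokes[[1]]$pressure, c(1, 1))
})

test_that("multi-sample JSON-lines files preserve count and ids", {
  cohort <- generate_cohort(cohort_spec(8, 0.5, seed = 7, tests = "CDT"))
  inks <- lapply(cohort$samples, `[[`, "sample")
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_ink_samples(inks, path)
  back <- read_ink_samples(path)
  expect_length(back, 8L)
  expect_identical(vapply(back, `[[`, "", "subject_id"),
                   vapply(inks, `[[`, "", "subject_id"))
  expect_identical(lapply(back, function(s) lapply(s$strokes, as.matrix)),
                   lapply(inks, function(s) lapply(s$strokes, as.matrix)))
})

test_that("translate_to_origin zeroes minima, preserves geometry, idempotent", {
  s <- mk_sample(mk_stroke(c(0, 10), c(5, 9), c(7, 7)))
  tr <- translate_to_origin(s)
  expect_equal(tr$strokes[[1]]$x, c(0, 4))
  expect_equal(tr$strokes[[1]]$y, c(0, 0))
  expect_identical(translate_to_origin(tr), tr)

  big <- random_sample(5, 40, seed = 77)
  trb <- translate_to_origin(big)
  pts <- do.call(rbind, lapply(trb$strokes, function(st) cbind(st$x, st$y)))
  expect_equal(min(pts[, 1]), 0)
  expect_equal(min(pts[, 2]), 0)
  expect_equal(distance_matrix(trb), distance_matrix(big), tolerance = 1e-12)
  # timestamps and pressures untouched
  expect_identical(lapply(trb$strokes, `[[`, "t"),
                   lapply(big$strokes, `[[`, "t"))
  expect_identical(lapply(trb$strokes, `[[`, "pressure"),
                   lapply(big$strokes, `[[`, "pressure"))
  expect_equal(completion_time(trb), completion_time(big))
  expect_error(translate_to_origin(ink_sample(list())), "empty")
})

test_that("completion_time is last minus first timestamp in seconds", {
  expect_equal(completion_time(mk_sample(mk_stroke(5, 1, 1))), 0)
  expect_equal(completion_time(mk_sample(mk_stroke(c(0, 61000), 0:1, 0:1))),
               61)
  s <- mk_sample(mk_stroke(c(1200, 30000), 0:1, 0:1),
                 mk_stroke(c(60000, 154700), 0:1, 0:1))
  expect_equal(completion_time(s), 153.5)
})

test_that("ink_validate reports exactly the violated invariants", {
  good <- random_sample(3, 8, seed = 5)
  expect_equal(nrow(ink_validate(good)), 0L)

  bad_t <- mk_sample(mk_stroke(c(10, 5), c(0, 1), c(0, 1)))
  rep1 <- ink_validate(bad_t)
  expect_true(any(rep1$stroke == 1 & grepl("decrease", rep1$violation)))

  bad_p <- mk_sample(mk_stroke(c(0, 1), c(0, 1), c(0, 1), pressure = 1.3))
  expect_true(any(grepl("pressure", ink_validate(bad_p)$violation)))

  expect_true(any(grepl("no strokes", ink_validate(ink_sample(list()))$violation)))
})
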