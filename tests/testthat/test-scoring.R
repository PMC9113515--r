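quiet_profile <- function() {
  behavior_profile(tremor_amplitude = 0, omission_prob = 0)
}

test_that("a perfect synthetic clock scores the CDIS maximum", {
  g <- generate_clock(quiet_profile(), seed = 1)
  expect_equal(g$result$total, 20L)
  expect_length(g$result$items, 20L)
  expect_equal(sum(g$result$items), g$result$total)
})

test_that("an empty sketch scores zero CDIS points", {
  empty <- ink_sample(list())
  r <- score_cdt(empty, clock_segmentation(character(0)))
  expect_equal(r$total, 0L)
})

test_that("deleting the hands drops exactly the hand-dependent items", {
  g <- generate_clock(quiet_profile(), seed = 2)
  keep <- !(as.character(g$segmentation) %in% c("hour_hand", "minute_hand"))
  nohands <- ink_sample(g$sample$strokes[keep], test_type = "CDT")
  seg <- clock_segmentation(as.character(g$segmentation)[keep])
  r <- score_cdt(nohands, seg)
  # item-wise oracle: every hand item fails, every other item is unchanged
  hand <- cdis_hand_items()
  expect_true(all(r$items[hand] == 0L))
  expect_identical(r$items[setdiff(names(r$items), hand)],
                   g$result$items[setdiff(names(g$result$items), hand)])
  expect_equal(r$total, 20L - length(hand))
})

test_that("scoring is invariant to stroke order permutation within classes", {
  g <- generate_clock(quiet_profile(), seed = 6)
  set.seed(1)
  perm <- base::sample(seq_along(g$sample$strokes))
  shuffled <- ink_sample(g$sample$strokes[perm], test_type = "CDT")
  seg <- clock_segmentation(as.character(g$segmentation)[perm])
  expect_equal(score_cdt(shuffled, seg)$items, g$result$items)
})

test_that("segment_clock passes hints through and handles degenerate input", {
  g <- generate_clock(quiet_profile(), seed = 3)
  expect_identical(as.character(segment_clock(g$sample, g$segmentation)),
                   as.character(g$segmentation))
  # heuristic finds the clock face on a clean drawing
  heur <- segment_clock(g$sample)
  expect_equal(which(as.character(heur) == "circle"),
               which(as.character(g$segmentation) == "circle"))
  # single dot with no hints: nothing to anchor on -> other
  dot <- mk_sample(mk_stroke(0, 5, 5))
  expect_equal(as.character(segment_clock(dot)), "other")
})

test_that("perfect trails hit all 25 nodes with no missing connections", {
  for (part in c("A", "B")) {
    g <- generate_tmt(part, quiet_profile(), seed = 4)
    expect_equal(g$result$hit_nodes, 1:25)
    expect_equal(nrow(g$result$missing_connections), 0L)
    expect_equal(g$result$visits, 1:25)
    expect_true(all(g$result$stroke_status == "connects"))
  }
})

test_that("part B template alternates numbers and letters", {
  tpl <- tmt_template("B")
  expect_equal(nrow(tpl$nodes), 25L)
  expect_equal(tpl$nodes$symbol[1:6], c("1", "A", "2", "B", "3", "C"))
  expect_equal(tpl$nodes$symbol[25], "13")
  expect_equal(tmt_template("A")$nodes$symbol, as.character(1:25))
})

test_that("a deleted approach into node 13 is reported as missing", {
  g <- generate_tmt("A", quiet_profile(), seed = 5)
  tpl <- g$template
  s <- g$sample$strokes[[1]]
  near13 <- sqrt((s$x - tpl$nodes$x[13])^2 + (s$y - tpl$nodes$y[13])^2) <=
    tpl$radius
  cut <- ink_sample(list(s[!near13, ]), test_type = "TMT_A")
  r <- score_tmt(cut, tpl)
  expect_false(13 %in% r$hit_nodes)
  expect_true(any(r$missing_connections[, "from"] == 12 &
                  r$missing_connections[, "to"] == 13))
  expect_true(any(grepl("13", r$error_notes)))
})

test_that("trail completion time is plain timestamp arithmetic", {
  tpl <- tmt_template("A")
  s <- mk_stroke(seq(0, 61000, length.out = nrow(tpl$nodes)),
                 tpl$nodes$x, tpl$nodes$y)
  r <- score_tmt(ink_sample(list(s), test_type = "TMT_A"), tpl)
  expect_equal(r$completion_time, 61)
  expect_error(score_tmt(ink_sample(list(s), test_type = "TMT_B"), tpl),
               "part")
})

test_that("a perfect figure scores 36 and omissions subtract their points", {
  g <- generate_rocf(quiet_profile(), seed = 7)
  expect_equal(g$result$total, 36L)
  expect_equal(g$result$sub_scores, rep(2L, 18))

  # remove the strokes of sub-figure 7: total drops by exactly 2
  keep <- g$assignment != 7
  cut <- ink_sample(g$sample$strokes[keep], test_type = "ROCF_COPY")
  r <- score_rocf(cut, g$assignment[keep])
  expect_equal(r$sub_scores[7], 0L)
  expect_equal(r$total, 34L)

  # displacing sub-figure 7 beyond the placement tolerance scores it 1
  moved <- g$sample
  moved$strokes <- lapply(seq_along(moved$strokes), function(i) {
    st <- moved$strokes[[i]]
    if (g$assignment[i] == 7) { st$x <- st$x + 25; st$y <- st$y + 25 }
    st
  })
  r2 <- score_rocf(moved, g$assignment)
  expect_equal(r2$sub_scores[7], 1L)
  expect_equal(r2$total, 35L)

  empty <- score_rocf(ink_sample(list()), integer(0))
  expect_equal(empty$total, 0L)
})

test_that("labeling thresholds match the screening rules exactly", {
  expect_equal(label_sample("CDT", 18), "suspicious")
  expect_equal(label_sample("CDT", 19), "healthy")
  expect_equal(label_sample("TMT_A", 60), "healthy")
  expect_equal(label_sample("TMT_A", 60.001), "suspicious")
  expect_equal(label_sample("TMT_B", 120), "healthy")
  expect_equal(label_sample("TMT_B", 121), "suspicious")
  for (score in 0:36) {
    expect_equal(label_sample("ROCF_COPY", score),
                 if (score <= 30) "suspicious" else "healthy")
    expect_equal(label_sample("ROCF_RECALL", score),
                 label_sample("ROCF_DELAYED", score))
  }
  expect_error(label_sample("OTHER", 1), "labeling rule")
})

test_that("the labeler is monotone in score and time", {
  to_num <- function(l) as.integer(l == "suspicious")
  cdt <- vapply(0:20, function(s) to_num(label_sample("CDT", s)), 0L)
  expect_true(all(diff(cdt) <= 0))  # raising the score never turns suspicious
  tmt <- vapply(seq(0, 200, by = 5),
                function(t) to_num(label_sample("TMT_A", t)), 0L)
  expect_true(all(diff(tmt) >= 0))  # raising the time never turns healthy
})

test_that("scoring reports carry label, breakdown and seed provenance", {
  g <- generate_tmt("A", quiet_profile(), seed = 8)
  path <- withr::local_tempfile(fileext = ".json")
  rep_ <- scoring_report(g$result, g$sample, path = path, seed = 8)
  expect_equal(rep_$label, label_sample("TMT_A", g$result$completion_time))
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$seed, 8L)
  expect_equal(parsed$scheme, "TMT-A")
  expect_length(parsed$hit_nodes, 25L)
})
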