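test_that("merge_speech_units applies the 200 ms rule at both sides", {
  iv <- speech_intervals(data.frame(
    speaker = "A", start = c(0, 1.15), end = c(1.0, 2.0)))  # 150 ms silence
  u <- merge_speech_units(iv, 0.2)
  expect_equal(nrow(u), 1)
  expect_equal(c(u$start, u$end), c(0, 2.0))
  expect_equal(u$source_intervals[[1]], c(1, 2))
  iv2 <- speech_intervals(data.frame(
    speaker = "A", start = c(0, 1.25), end = c(1.0, 2.0)))  # 250 ms silence
  expect_equal(nrow(merge_speech_units(iv2, 0.2)), 2)
  # exact 200 ms boundary separates (non-merge side of the convention)
  iv3 <- speech_intervals(data.frame(
    speaker = "A", start = c(0, 1.2), end = c(1.0, 2.0)))
  expect_equal(nrow(merge_speech_units(iv3, 0.2)), 2)
  one <- merge_speech_units(speech_intervals(
    data.frame(speaker = "B", start = 3, end = 4.5)), 0.2)
  expect_equal(nrow(one), 1)
  expect_equal(c(one$start, one$end), c(3, 4.5))
  expect_error(
    merge_speech_units(speech_intervals(
      data.frame(speaker = "A", start = c(0, 0.5), end = c(1, 1.5)))),
    "overlapping")
})

test_that("merging is idempotent and monotone in the threshold", {
  set.seed(31)
  for (rep in 1:25) {
    iv <- speech_intervals(random_interval_set(40))
    u1 <- merge_speech_units(iv, 0.2)
    u2 <- merge_speech_units(
      speech_intervals(u1[, c("speaker", "start", "end")]), 0.2)
    expect_equal(u1$start, u2$start)
    expect_equal(u1$end, u2$end)
    for (th in c(0.1, 0.3, 0.6))
      expect_lte(nrow(merge_speech_units(iv, th + 0.1)),
                 nrow(merge_speech_units(iv, th)))
  }
})

test_that("classify_silences distinguishes pauses from gaps", {
  u <- merge_speech_units(speech_intervals(data.frame(
    speaker = c("A", "A"), start = c(0, 2.5), end = c(2.0, 4.0))))
  s <- classify_silences(u)
  expect_equal(s$kind, "pause")
  expect_equal(c(s$start, s$end), c(2.0, 2.5))
  u2 <- merge_speech_units(speech_intervals(data.frame(
    speaker = c("A", "B"), start = c(0, 2.4), end = c(2.0, 4.0))))
  s2 <- classify_silences(u2)
  expect_equal(s2$kind, "gap")
  expect_equal(c(s2$start, s2$end), c(2.0, 2.4))
  # seamless alternation: no silences
  u3 <- merge_speech_units(speech_intervals(data.frame(
    speaker = c("A", "B", "A"), start = c(0, 2, 4), end = c(2, 4, 6))))
  expect_equal(nrow(classify_silences(u3)), 0)
})

test_that("build_turns joins across uninterrupted pauses only", {
  mk <- function(df) merge_speech_units(speech_intervals(df))
  # B silent: one A turn spanning the pause
  t1 <- build_turns(mk(data.frame(speaker = c("A", "A"),
                                  start = c(0, 2.5), end = c(2, 4))))
  expect_equal(nrow(t1), 1)
  expect_equal(c(t1$start, t1$end), c(0, 4))
  # B backchannel inside the pause splits A's turn
  t2 <- build_turns(mk(data.frame(speaker = c("A", "B", "A"),
                                  start = c(0, 2.1, 2.5),
                                  end = c(2, 2.3, 4))))
  expect_equal(nrow(t2), 3)
  expect_equal(t2$speaker, c("A", "B", "A"))
  # strict alternation: one turn per unit
  ab <- data.frame(speaker = rep(c("A", "B"), 5),
                   start = seq(0, 18, 2), end = seq(1.5, 19.5, 2))
  expect_equal(nrow(build_turns(mk(ab))), 10)
})

test_that("overlaps and switches follow the onset conventions", {
  mk <- function(df) merge_speech_units(speech_intervals(df))
  u <- mk(data.frame(speaker = c("A", "B"), start = c(0, 1.5),
                     end = c(2, 3)))
  os <- detect_overlaps_and_switches(u, build_turns(u))
  expect_equal(nrow(os$overlaps), 1)
  expect_equal(c(os$overlaps$start, os$overlaps$end), c(1.5, 2))
  expect_equal(os$switches$time, 1.5)
  expect_equal(os$switches$kind, "overlap_onset")
  expect_equal(os$switches$incoming_speaker, "B")
  # contained backchannel counts as an overlap (no distinction made)
  u2 <- mk(data.frame(speaker = c("A", "B"), start = c(0, 2),
                      end = c(5, 2.4)))
  os2 <- detect_overlaps_and_switches(u2, build_turns(u2))
  expect_equal(c(os2$overlaps$start, os2$overlaps$end), c(2, 2.4))
  # no intersections: switches are speaker-change turn onsets only
  u3 <- mk(data.frame(speaker = c("A", "B", "A"), start = c(0, 3, 6),
                      end = c(2, 5, 8)))
  os3 <- detect_overlaps_and_switches(u3, build_turns(u3))
  expect_equal(nrow(os3$overlaps), 0)
  expect_equal(os3$switches$time, c(3, 6))
  expect_true(all(os3$switches$kind == "turn_onset"))
})

test_that("turn_statistics reports the documented bins and shares", {
  iv <- speech_intervals(data.frame(
    speaker = rep(c("A", "B"), 2),
    start = c(0, 6, 15, 31), end = c(5, 14, 30, 56)))
  st <- turn_statistics(conversation_structure(iv))
  expect_equal(unname(st$duration_bins), c(0.5, 0.25, 0.25, 0))
  expect_equal(st$n_turns, 4)
  # 7 overlap switches, 3 turn-onset switches -> share 0.7
  sw <- data.frame(kind = c(rep("overlap_onset", 7), rep("turn_onset", 3)),
                   time = 1:10, incoming_speaker = "B")
  cs <- conversation_structure(iv)
  cs$switches <- sw
  expect_equal(turn_statistics(cs)$overlap_switch_share, 0.7)
  # empty structure: proportions are missing, not zero
  empty <- conversation_structure(
    speech_intervals(data.frame(speaker = "A", start = 0, end = 1)))
  empty$turns <- empty$turns[0, ]
  st0 <- turn_statistics(empty)
  expect_true(st0$empty)
  expect_true(all(is.na(st0$duration_bins)))
})

test_that("segmentation matches the mask-sweep oracle on random sessions", {
  set.seed(99)
  for (rep in 1:120) {
    iv <- random_interval_set(50)
    cs <- conversation_structure(speech_intervals(iv), 0.2)
    want <- oracle_conversation(iv, 0.2)
    expect_equal(cs$units$start, want$units$start, tolerance = 1e-9)
    expect_equal(cs$units$end, want$units$end, tolerance = 1e-9)
    expect_identical(cs$units$speaker, want$units$speaker)
    expect_equal(cs$turns$start, want$turns$start, tolerance = 1e-9)
    expect_equal(cs$turns$end, want$turns$end, tolerance = 1e-9)
    expect_identical(cs$turns$speaker, want$turns$speaker)
    expect_equal(cs$overlaps$start, want$overlaps$start, tolerance = 1e-9)
    expect_equal(cs$overlaps$end, want$overlaps$end, tolerance = 1e-9)
    expect_identical(cs$overlaps$incoming_speaker,
                     want$overlaps$incoming_speaker)
    expect_equal(cs$silences$start, want$silences$start, tolerance = 1e-9)
    expect_identical(cs$silences$kind, want$silences$kind)
    expect_equal(cs$switches$time, want$switches$time, tolerance = 1e-9)
    expect_identical(cs$switches$kind, want$switches$kind)
    # partition properties
    expect_equal(sum(lengths(cs$turns$unit_indices)), nrow(cs$units))
    for (sp in c("A", "B")) {
      tu <- cs$turns[cs$turns$speaker == sp, ]
      un <- cs$units[cs$units$speaker == sp, ]
      expect_gte(sum(tu$end - tu$start) + 1e-12, sum(un$end - un$start))
    }
  }
})

test_that("turn statistics equal a literal recount on random sessions", {
  set.seed(123)
  for (rep in 1:40) {
    iv <- random_interval_set(60)
    cs <- conversation_structure(speech_intervals(iv))
    st <- turn_statistics(cs)
    d <- cs$turns$end - cs$turns$start
    expect_equal(st$n_turns, length(d))
    expect_equal(unname(st$duration_bins),
                 c(sum(d <= 10), sum(d > 10 & d <= 20),
                   sum(d > 20 & d <= 30), sum(d > 30)) / length(d))
    expect_equal(st$mean_turn_s, sum(d) / length(d))
    if (nrow(cs$switches) > 0)
      expect_equal(st$overlap_switch_share,
                   sum(cs$switches$kind == "overlap_onset") /
                     nrow(cs$switches))
  }
})

test_that("structure JSON serialization is stable and complete", {
  iv <- speech_intervals(data.frame(speaker = c("A", "B"),
                                    start = c(0, 1.5), end = c(2, 3)))
  cs <- conversation_structure(iv)
  p <- withr::local_tempfile(fileext = ".json")
  write_structure_json(cs, p)
  obj <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(obj$min_silence, 0.2)
  expect_equal(nrow(obj$units), 2)
  expect_equal(obj$switches$time, 1.5)
})
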