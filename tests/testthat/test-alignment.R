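# Score-to-performance alignment, error classification and cleaning.

test_that("identity alignment yields all matches and zero distance", {
  sc <- score_from_pitches(c(60, 62, 64, 65, 67))
  al <- align(perf_from_pitches(c(60, 62, 64, 65, 67)), sc)
  expect_equal(nrow(al$pairs), 5L)
  expect_equal(al$edit_distance, 0L)
  expect_equal(nrow(al$errors), 0L)
})

test_that("a skipped tone is classified as missing at its score index", {
  sc <- score_from_pitches(c(60, 62, 64, 65, 67))
  al <- align(perf_from_pitches(c(60, 62, 65, 67)), sc)
  expect_equal(al$edit_distance, 1L)
  expect_equal(al$errors$category, "missing")
  expect_equal(al$errors$score_index, 2L)
})

test_that("a wrong tone is classified as substituted, matching brute force", {
  sc <- score_from_pitches(c(60, 62, 64, 65, 67))
  al <- align(perf_from_pitches(c(60, 62, 63, 65, 67)), sc)
  expect_equal(al$edit_distance,
               brute_edit_distance(c(60, 62, 64, 65, 67),
                                   c(60, 62, 63, 65, 67)))
  expect_equal(al$errors$category, "substituted")
  expect_equal(al$errors$score_index, 2L)
  expect_equal(al$errors$perf_index, 2L)
})

test_that("a doubled tone is an extra; the tie-break picks the second", {
  sc <- score_from_pitches(c(60, 62, 64, 65, 67))
  al <- align(perf_from_pitches(c(60, 60, 62, 64, 65, 67)), sc)
  expect_equal(al$edit_distance, 1L)
  expect_equal(al$errors$category, "extra")
  # match-first, left-to-right: the first 60 matches, the second is extra
  expect_equal(al$errors$perf_index, 1L)
})

test_that("degenerate cases: empty performance, empty score", {
  sc <- score_from_pitches(c(60, 62, 64))
  al <- align(perf_from_pitches(integer(0)), sc)
  expect_equal(al$edit_distance, 3L)
  expect_true(all(al$errors$category == "missing"))
  expect_error(align(perf_from_pitches(60), sc[0, ]), "empty score")
})

test_that("edit distance equals the brute-force minimum on random pairs", {
  set.seed(101)
  for (k in 1:200) {
    a <- sample(60:67, sample(1:8, 1L), replace = TRUE)
    b <- sample(60:67, sample(0:8, 1L), replace = TRUE)
    al <- align(perf_from_pitches(b), score_from_pitches(a))
    expect_equal(al$edit_distance, brute_edit_distance(a, b),
                 label = paste("score", paste(a, collapse = ","),
                               "perf", paste(b, collapse = ",")))
    expect_equal(al$edit_distance, nrow(al$errors))
    # matched pairs strictly increasing in both indices, equal pitch
    if (nrow(al$pairs) > 1L) {
      expect_true(all(diff(al$pairs$score_index) > 0))
      expect_true(all(diff(al$pairs$perf_index) > 0))
    }
    if (nrow(al$pairs) > 0L) {
      expect_equal(a[al$pairs$score_index + 1L],
                   b[al$pairs$perf_index + 1L])
    }
  }
})

test_that("offset-order anomalies follow the rank-comparison rule", {
  sc <- score_from_pitches(c(60, 62, 64))
  # offsets in onset order: none flagged
  p <- performance(tibble::tibble(pitch = c(60, 62, 64),
                                  onset_ms = c(0, 200, 400),
                                  offset_ms = c(150, 380, 560),
                                  velocity = 80))
  expect_length(detect_offset_anomalies(p, align(p, sc)), 0L)
  # a long-held first note: both rank-discordant notes flagged
  sc2 <- score_from_pitches(c(60, 62))
  p2 <- performance(tibble::tibble(pitch = c(60, 62),
                                   onset_ms = c(0, 200),
                                   offset_ms = c(900, 400),
                                   velocity = 80))
  expect_equal(detect_offset_anomalies(p2, align(p2, sc2)), c(0L, 1L))
  # ordinary legato overlap preserves ranks: no anomaly
  p3 <- performance(tibble::tibble(pitch = c(60, 62),
                                   onset_ms = c(0, 200),
                                   offset_ms = c(210, 400),
                                   velocity = 80))
  expect_length(detect_offset_anomalies(p3, align(p3, sc2)), 0L)
})

test_that("cleaning removes erroneous notes and flags bad trials", {
  sc <- make_fixture_score("exp1", "articulation")
  p <- clean_perf_of(sc)
  cl <- clean_performance(p, sc)
  expect_true(cl$valid)
  expect_equal(cl$n_removed, 0L)
  expect_identical(cl$cleaned$pitch, sc$pitch)

  # one extra note in the performance: cleaned back to score length
  inj <- p
  inj$notes <- rbind(inj$notes[1L, ], inj$notes)
  inj$notes$offset_ms[1L] <- 90
  inj <- performance(inj$notes, cued_tempo_qbpm = 80)
  cl2 <- clean_performance(inj, sc)
  expect_true(cl2$valid)
  expect_equal(nrow(cl2$cleaned), nrow(sc))

  # matching only half the score: invalid
  half <- perf_from_pitches(sc$pitch[seq_len(nrow(sc) / 2L)])
  cl3 <- clean_performance(half, sc)
  expect_false(cl3$valid)
})

test_that("cleaning is idempotent", {
  sc <- make_fixture_score("exp1", "articulation")
  set.seed(11)
  for (k in 1:10) {
    p <- clean_perf_of(sc, kot = sample(c(-120, 15), 1L))
    out <- inject_pitch_errors(p, c(extra = 0.8, missing = 0.8,
                                    substituted = 0.8))
    cl1 <- clean_performance(out$performance, sc)
    p2 <- performance(tibble::tibble(
      pitch = cl1$cleaned$pitch, onset_ms = cl1$cleaned$onset_ms,
      offset_ms = cl1$cleaned$offset_ms, velocity = cl1$cleaned$velocity))
    cl2 <- clean_performance(p2, sc)
    expect_equal(cl2$n_removed, 0L)
    expect_equal(cl2$cleaned, cl1$cleaned)
  }
})

test_that("injected errors are recovered category-for-category", {
  sc <- make_fixture_score("exp1", "articulation")
  base <- clean_perf_of(sc)
  # substitution at a known position, to a pitch outside the scale
  notes <- base$notes
  notes$pitch[10L] <- notes$pitch[10L] + 1L
  al <- align(performance(notes, cued_tempo_qbpm = 80), sc)
  expect_equal(al$errors$category, "substituted")
  expect_equal(al$errors$score_index, 9L)
  # deletion at a known position
  al2 <- align(performance(base$notes[-20L, ], cued_tempo_qbpm = 80), sc)
  expect_equal(al2$errors$category, "missing")
  expect_equal(al2$errors$score_index, 19L)
})

test_that("error rates count trials once per category", {
  sc <- score_from_pitches(c(60, 62, 64, 65))
  clean <- align(perf_from_pitches(c(60, 62, 64, 65)), sc)
  extra2 <- align(perf_from_pitches(c(60, 61, 62, 63, 64, 65)), sc)
  cohort <- c(replicate(9, clean, simplify = FALSE), list(extra2))
  er <- error_rates(cohort)
  expect_equal(er$pct_trials[er$category == "extra"], 10)
  expect_equal(er$pct_trials[er$category == "missing"], 0)
  er0 <- error_rates(replicate(5, clean, simplify = FALSE))
  expect_true(all(er0$pct_trials == 0))
  expect_error(error_rates(list()), "empty")
})
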