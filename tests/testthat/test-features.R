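# Expressive feature extraction: IOI, KOT, KOR, KV, transition diffs.

cleaned_tbl <- function(score_index, onset, offset, velocity = 80) {
  tibble::tibble(score_index = as.integer(score_index),
                 pitch = 60L + as.integer(score_index),
                 onset_ms = onset, offset_ms = offset,
                 velocity = as.integer(velocity))
}

test_that("IOIs are onsets differences over score-adjacent matched pairs", {
  cl <- cleaned_tbl(0:2, c(0, 190, 380), c(150, 340, 530))
  res <- compute_iois(cl)
  expect_equal(res$ioi$ioi_ms, c(190, 190))
  expect_equal(res$mean_ioi_ms, 190)
  # a missing middle note: no IOI across the gap
  cl2 <- cleaned_tbl(c(0, 2), c(0, 190), c(150, 340))
  res2 <- compute_iois(cl2)
  expect_equal(nrow(res2$ioi), 0L)
  # exact 80 qbpm sixteenths
  cl3 <- cleaned_tbl(0:4, (0:4) * 187.5, (0:4) * 187.5 + 100)
  expect_true(all(compute_iois(cl3)$ioi$ioi_ms == 187.5))
})

test_that("IOI normalization is 1 at each nominal tempo", {
  expect_equal(normalize_ioi(300, 100, 2), 1.0)
  expect_equal(normalize_ioi(250, 120, 2), 1.0)
  expect_equal(normalize_ioi(60000 / 110 / 2, 110, 2), 1.0)
  expect_equal(normalize_ioi(291, 100, 2), 0.97)
  expect_equal(normalize_ioi(187.5, 80, 4), 1.0)
  expect_error(normalize_ioi(300, 0, 2), "positive")
})

test_that("KOT is offset minus next onset, with the sign convention", {
  cl <- cleaned_tbl(0:1, c(0, 985), c(1000, 1400))
  expect_equal(compute_kot(cl)$kot_ms, 15)          # overlap: legato-like
  cl2 <- cleaned_tbl(0:1, c(0, 500), c(500, 900))
  expect_equal(compute_kot(cl2)$kot_ms, 0)
  cl3 <- cleaned_tbl(0:1, c(0, 633), c(500, 900))
  expect_equal(compute_kot(cl3)$kot_ms, -133)       # separation: staccato
})

test_that("KOR is KOT over the trial mean IOI", {
  expect_equal(compute_kor(-222, 300), -0.74)
  expect_equal(compute_kor(0, 300), 0)
  expect_equal(compute_kor(36, 300), 0.12)
  expect_error(compute_kor(10, 0), "positive")
  # exact inverse identity on random values
  set.seed(3)
  kot <- rnorm(50, -100, 40); mioi <- 187.5
  expect_equal(compute_kor(kot, mioi) * mioi, kot)
})

test_that("interval labels follow the notation spans", {
  sc <- make_fixture_score("exp1", "dynamics")
  iv <- compute_kot(cleaned_tbl(0:31, (0:31) * 187.5, (0:31) * 187.5 + 150))
  iv <- label_subcomponents(iv, sc)
  # within the first measure: forte; the measure boundary: transition
  expect_equal(iv$subcomponent[1L], "forte")
  expect_equal(iv$subcomponent[16L], "transition")
  expect_equal(iv$transition_type[16L], "FtoP")
  sc2 <- make_fixture_score("exp1", "articulation")
  iv2 <- label_subcomponents(compute_kot(
    cleaned_tbl(16:33, (16:33) * 187.5, (16:33) * 187.5 + 150)), sc2)
  expect_equal(iv2$subcomponent[1L], "staccato")
  expect_equal(iv2$transition_type[nrow(iv2)], "none")
})

test_that("the unlabelled note is excluded from every dependent variable", {
  sc <- make_fixture_score("exp2", "articulation")
  none_idx <- sc$index[sc$notation == "none"]
  cl <- cleaned_tbl(sc$index, sc$index * 300, sc$index * 300 + 250)
  tf <- trial_features(cl, sc, cued_tempo_qbpm = 100)
  expect_false(none_idx %in% tf$notes$score_index)
  expect_false(any(tf$intervals$from_score_index %in%
                     c(none_idx - 1L, none_idx)))
})

test_that("KV transition differences are next minus current at boundaries", {
  sc <- make_fixture_score("exp1", "dynamics")[1:4, ]
  sc$notation <- c("forte", "forte", "piano", "piano")
  sc$analyzed <- TRUE
  cl <- cleaned_tbl(0:3, (0:3) * 187.5, (0:3) * 187.5 + 150,
                    velocity = c(82, 80, 61, 60))
  d <- kv_transition_diffs(cl, sc)
  expect_equal(nrow(d), 1L)
  expect_equal(d$transition_type, "FtoP")
  expect_equal(d$kv_diff, 61 - 80)
  # piano-to-forte positive
  sc$notation <- c("piano", "piano", "forte", "forte")
  cl2 <- cleaned_tbl(0:3, (0:3) * 187.5, (0:3) * 187.5 + 150,
                     velocity = c(60, 60, 84, 84))
  d2 <- kv_transition_diffs(cl2, sc)
  expect_equal(d2$kv_diff, 24)
  expect_equal(d2$transition_type, "PtoF")
  # a removed flanking note yields no difference
  cl3 <- cl2[-1L, ]                                      # boundary intact
  expect_equal(nrow(kv_transition_diffs(cl3, sc)), 1L)
  cl4 <- cl2[-3L, ]                                      # flank removed
  expect_equal(nrow(kv_transition_diffs(cl4, sc)), 0L)
})

test_that("feature count never exceeds matched notes minus one", {
  sc <- make_fixture_score("exp1", "articulation")
  set.seed(21)
  for (k in 1:10) {
    keep <- sort(sample(nrow(sc), sample(50:96, 1L)))
    cl <- cleaned_tbl(sc$index[keep], (keep - 1L) * 187.5,
                      (keep - 1L) * 187.5 + 120)
    tf <- trial_features(cl, sc, 80)
    expect_lte(nrow(tf$intervals), nrow(cl) - 1L)
  }
})

test_that("cohort summaries aggregate participant means", {
  vals <- tibble::tibble(
    participant = rep(c("P1", "P2"), each = 4L),
    condition = "teaching",
    subcomponent = "staccato",
    value = c(8, 12, 10, 10, 18, 22, 20, 20))
  s <- summarize_features(vals)
  expect_equal(s$cohort$M, 15)
  expect_equal(s$cohort$SD, sd(c(10, 20)))
  expect_equal(s$cohort$Mdn, 15)
  s1 <- expect_warning(
    summarize_features(vals[vals$participant == "P1", ]), "single")
})
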