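# Synthetic cohort generation: calibration, reproducibility, recovery.

test_that("default calibration carries the documented condition targets", {
  cfg <- default_config("exp1")
  expect_equal(unname(cfg$kot_base["staccato"]), -128.34)
  expect_equal(unname(cfg$kot_teaching_shift["staccato"]), -5.45)
  expect_equal(unname(cfg$kot_base["legato"]), 14.01)
  expect_false(cfg$kot_shift_applied[["legato"]])   # non-significant shift
  expect_equal(cfg$n_participants, 31L)
  expect_equal(cfg$trials_per_cell, 8L)
  expect_equal(unname(cfg$error_rates),
               c(0.0628, 0.0507, 0.0030))
  cfg2 <- default_config("exp2")
  expect_equal(unname(cfg2$kv_base["piano"]), 62.43)
  expect_equal(unname(cfg2$kv_teaching_shift["piano"]), -1.89)
  expect_equal(unname(cfg2$kot_base["staccato"]), -0.74)
  expect_equal(cfg2$n_participants, 20L)
  expect_error(default_config("exp3"))
})

test_that("cohorts are reproducible and stable under n changes", {
  cfg <- default_config("exp1")
  cfg$n_participants <- 3L
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$trials, c2$trials)
  cfg$n_participants <- 5L
  c3 <- generate_cohort(cfg)
  expect_identical(c1$trials[1:32], c3$trials[1:32])  # participant 1 stable
})

test_that("the factorial design is complete: 32 trials per participant", {
  cfg <- default_config("exp1")
  cfg$n_participants <- 3L
  co <- generate_cohort(cfg)
  counts <- table(co$manifest$participant)
  expect_true(all(counts == 32L))
  cells <- table(co$manifest$condition, co$manifest$technique)
  expect_true(all(cells == 3L * 8L))
})

test_that("zero noise and zero error rates recover targets exactly", {
  cfg <- default_config("exp1")
  cfg$n_participants <- 6L
  cfg$techniques <- "articulation"
  cfg$participant_sd <- list(tempo_factor = 0, kot = 0, kv = 0)
  cfg$note_noise_sd <- list(onset = 0, kot = 0, kv = 0)
  cfg$error_rates[] <- 0
  cfg$outlier_rate <- 0
  co <- generate_cohort(cfg)
  rep <- run_pipeline(co)
  kp <- rep$stats$articulation$kot_anova$cell_means
  expect_equal(unname(kp["performing.staccato"]), -128.34,
               tolerance = 1e-9)
  expect_equal(unname(kp["teaching.staccato"]), -128.34 - 5.45,
               tolerance = 1e-9)
  expect_equal(unname(kp["performing.legato"]), 14.01, tolerance = 1e-9)
  expect_equal(unname(kp["teaching.legato"]), 14.01, tolerance = 1e-9)
  # velocities are integer MIDI values: targets recovered to rounding
  kv <- rep$stats$articulation$kv_anova$cell_means
  expect_equal(unname(kv["performing.legato"]), 70.68, tolerance = 0.5)
  # IOIs at the cued tempo, scaled by the teaching tempo factor
  ioi <- rep$stats$articulation$ioi_test$descriptives
  expect_equal(ioi$M[ioi$condition == "performing"], 187.5,
               tolerance = 1e-9)
  expect_equal(ioi$M[ioi$condition == "teaching"], 187.5 * 1.023,
               tolerance = 1e-9)
})

test_that("teaching and performing are exchangeable under the null", {
  cfg <- null_config(experiment_profile = "exp1")
  cfg$n_participants <- 6L
  cfg$techniques <- "articulation"
  cfg$error_rates[] <- 0
  co <- generate_cohort(cfg)
  rep <- run_pipeline(co)
  ph <- rep$stats$articulation$kot_posthoc
  expect_true(all(abs(ph$estimate[ph$highlight]) < 5))
})

test_that("error injection respects the configured rates", {
  sc <- make_fixture_score("exp1", "articulation")
  p <- clean_perf_of(sc)
  set.seed(1)
  out0 <- inject_pitch_errors(p, c(extra = 0, missing = 0,
                                   substituted = 0))
  expect_equal(out0$performance$notes, p$notes)
  expect_equal(nrow(out0$records), 0L)
  set.seed(2)
  out1 <- inject_pitch_errors(p, c(extra = 1, missing = 0,
                                   substituted = 0))
  expect_equal(nrow(out1$performance$notes), nrow(p$notes) + 1L)
  expect_equal(out1$records$category, "extra")
})

test_that("injected error rates are recovered by the alignment module", {
  cfg <- default_config("exp1")
  cfg$n_participants <- 16L        # 512 trials
  cfg$techniques <- "articulation"
  cfg$seed <- 20L
  co <- generate_cohort(cfg)
  rep <- run_pipeline(co)
  truth <- co$ground_truth$errors
  n_trials <- nrow(co$manifest)
  for (cat in c("extra", "missing")) {
    injected <- nrow(unique(truth[truth$category == cat,
                                  c("participant", "condition", "trial")]))
    recovered <- rep$error_rates$pct_trials[rep$error_rates$category == cat]
    expect_lt(abs(recovered - 100 * injected / n_trials), 1.0)
  }
})

test_that("velocity clipping is negligible at default calibration", {
  cfg <- default_config("exp1")
  cfg$n_participants <- 10L
  co <- generate_cohort(cfg)
  n_notes <- sum(vapply(co$trials, function(t) length(t$pitch), 0L))
  expect_lt(co$ground_truth$n_velocity_clipped / n_notes, 0.001)
})

test_that("cohort SMF round trip preserves the notes to tick precision", {
  cfg <- default_config("exp1")
  cfg$n_participants <- 2L
  cfg$techniques <- "articulation"
  cfg$trials_per_cell <- 2L
  co <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  perfs <- cohort_performances(co)
  q <- read_performance(file.path(dir, sprintf("%s_%s_%s_%02d.mid",
                                               perfs[[1]]$participant_id,
                                               perfs[[1]]$condition,
                                               perfs[[1]]$technique,
                                               perfs[[1]]$trial_index)))
  expect_identical(q$notes$pitch, perfs[[1]]$notes$pitch)
  expect_identical(q$notes$velocity, perfs[[1]]$notes$velocity)
  expect_lt(max(abs(q$notes$onset_ms - perfs[[1]]$notes$onset_ms)),
            60000 / 80 / 480)
})
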