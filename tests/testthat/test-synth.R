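test_that("speaker profiles are deterministic and validated", {
  p1 <- make_speaker_profile("NH", 220, seed = 9)
  p2 <- make_speaker_profile("NH", 220, seed = 9)
  expect_identical(p1, p2)
  expect_false(identical(p1, make_speaker_profile("NH", 220, seed = 10)))
  expect_error(make_speaker_profile("XX"), "NH")
  expect_error(make_speaker_profile("NH", f0_center_hz = 50), "75-600")
})

test_that("group defaults realize the documented production strategies", {
  profs <- lapply(1:30, function(s) make_speaker_profile("NH", 220, seed = s))
  m <- function(f) mean(vapply(profs, `[[`, numeric(1), f))
  expect_within(m("dur_ratio_tone1"), 1.15, 0.05)
  expect_within(m("dur_ratio_tone4"), 1.15, 0.05)
  expect_gt(m("tone1_median_rel_st"), 4)
  expect_within(m("tone4_movement_st"), -4.5, 0.5)

  ci <- lapply(1:30, function(s) make_speaker_profile("CI", 220, seed = s))
  mc <- function(f) mean(vapply(ci, `[[`, numeric(1), f))
  expect_within(mc("dur_ratio_tone1"), 1.3, 0.05)
  expect_within(mc("dur_ratio_tone4"), 1.0, 0.05)
  expect_within(mc("tone1_movement_st"), 0, 0.5)
})

test_that("utterances have the programmed silence, dip and determinism", {
  fix <- test_utterance("Tone4")
  w <- fix$wave
  pad <- w$samples[seq_len(round(0.4 * w$rate))]
  expect_lt(10 * log10(mean(pad^2) + 1e-12), -60)

  ic <- fix$analysis$intensity
  seg <- fix$analysis$windows
  valley_db <- ic$values[seg$valley_index]
  peak_db <- max(seg$win1$peak_level_db, seg$win2$peak_level_db)
  expect_within(peak_db - valley_db, 30, 1)

  w2 <- synthesize_utterance(utterance_spec(fix$profile, "Tone4", jitter = FALSE))
  expect_identical(w$samples, w2$samples)
})

test_that("measured F0 movement matches the generating parameter", {
  fix <- test_utterance("Tone4")
  expect_within(fix$analysis$descriptors[["f0_movement_st"]],
                fix$truth$f0_movement_st, 0.5)
})

test_that("CI duration contrast survives the round trip within 2%", {
  prof <- make_speaker_profile("CI", 220, seed = 21)
  ratio <- vapply(c("Tone1", "Tone4"), function(tn) {
    w <- synthesize_utterance(utterance_spec(prof, tn, jitter = FALSE))
    seg <- segment_syllables(intensity_contour(w))
    duration_ratio(seg$win1, seg$win2)
  }, numeric(1))
  expect_within(ratio[["Tone1"]] / ratio[["Tone4"]],
                prof$dur_ratio_tone1 / prof$dur_ratio_tone4, 0.02)
})

test_that("larger programmed Tone 4 movement yields larger measured movement", {
  meas <- vapply(c(-2, -4.5, -7), function(mv) {
    prof <- make_speaker_profile("CI", 220, seed = 3)
    prof$tone4_movement_st <- mv
    prof$tone4_median_rel_st <- 3 + mv / 2
    w <- synthesize_utterance(utterance_spec(prof, "Tone4", jitter = FALSE))
    analyze_utterance(w)$descriptors[["f0_movement_st"]]
  }, numeric(1))
  expect_true(all(diff(abs(meas)) > 0))
})

test_that("cohort generation has the right size and is byte-deterministic", {
  co <- generate_cohort(1, 1, reps = 1, seed = 3, jitter = FALSE)
  expect_length(co$utterances, 4)
  expect_equal(nrow(co$truth), 4)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_cohort(1, 1, reps = 1, seed = 3, dir = d1)
  generate_cohort(1, 1, reps = 1, seed = 3, dir = d2)
  f1 <- list.files(d1, pattern = "wav$", full.names = TRUE)
  f2 <- list.files(d2, pattern = "wav$", full.names = TRUE)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("listener profiles and response simulation follow the logistic model", {
  expect_error(make_listener_profile("NH", lapse_rate = 0.5), "lapse")
  l0 <- make_listener_profile("NH", seed = 1,
                              overrides = list(beta_intercept = 0,
                                               beta_f0slope = 0,
                                               beta_logdur = 0,
                                               beta_f0height = 0))
  grid <- build_token_grid()
  expect_error(simulate_responses(l0, grid[0, ]), "empty")
  r <- simulate_responses(l0, grid, n_sessions = 30, seed = 2)
  expect_true(all(r$p_tone1 == 0.5))
  expect_within(mean(r$response), 0.5, 0.03)

  lneg <- make_listener_profile("NH", seed = 1,
                                overrides = list(beta_intercept = 10,
                                                 beta_f0slope = -40,
                                                 beta_logdur = 0,
                                                 beta_f0height = 0))
  r <- simulate_responses(lneg, grid, n_sessions = 1, seed = 2)
  expect_lt(max(r$p_tone1[r$f0_slope_oct == -1]), 0.01)
  expect_gt(min(r$p_tone1[r$f0_slope_oct == 0]), 0.99)
})

test_that("descriptor-level simulation mirrors the audio-path jitter seeds", {
  d <- simulate_descriptors(2, 2, reps = 2, seed = 42)
  co <- test_cohort()$cohort
  m <- merge(d, co$truth, by = c("speaker", "group", "tone", "repetition"))
  # same profiles, audio truth is jitter-free here: profile-level agreement
  expect_equal(nrow(d), nrow(co$truth))
  expect_setequal(unique(d$speaker), unique(co$truth$speaker))
})
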