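# Shared fixtures, built once per test run and cached (synthesis + full
# cohort analysis is the expensive part of the suite).

.fixture_env <- new.env(parent = emptyenv())

# jitter-free 2 NH + 2 CI cohort (2 reps) with its full analysis
test_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    co <- generate_cohort(2, 2, reps = 2, seed = 42, jitter = FALSE)
    .fixture_env$cohort <- list(cohort = co, descriptors = analyze_cohort(co))
  }
  .fixture_env$cohort
}

# one analyzed jitter-free utterance per tone (NH speaker)
test_utterance <- function(tone = "Tone4") {
  key <- paste0("utt_", tone)
  if (is.null(.fixture_env[[key]])) {
    prof <- make_speaker_profile("NH", 220, seed = 5)
    wave <- synthesize_utterance(utterance_spec(prof, tone, jitter = FALSE))
    .fixture_env[[key]] <- list(profile = prof, wave = wave,
                                truth = attr(wave, "truth"),
                                analysis = analyze_utterance(wave))
  }
  .fixture_env[[key]]
}

expect_within <- function(object, target, tol) {
  expect_true(all(abs(object - target) <= tol),
              label = sprintf("|%s - %s| <= %s",
                              paste(signif(object, 5), collapse = ","),
                              paste(signif(target, 5), collapse = ","), tol))
}
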