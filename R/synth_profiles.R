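# Speaker and listener profiles: the generating parameters behind the
# synthetic cohorts. Group defaults encode the production strategies the
# analyses are meant to detect: NH children lengthen the second syllable by
# 10-20% for both tones, raise its F0 median by over 4 st for Tone 1 and fall
# by ~4.5 st for Tone 4; CI children lengthen Tone 1 only (~30%), keep Tone 1
# F0 flat about 3 st above the first syllable, and fall similarly for Tone 4.

tone_groups <- c("NH", "CI")
tone_labels <- c("Tone1", "Tone4")

speaker_group_defaults <- function(group) {
  switch(group,
    NH = list(
      dur_ratio_tone1 = 1.15, dur_ratio_tone4 = 1.15,
      tone1_median_rel_st = 4.25, tone1_movement_st = 2.5,
      tone4_movement_st = -4.5,
      int_peak_diff_tone1_db = 1.0, int_peak_diff_tone4_db = 2.0),
    CI = list(
      dur_ratio_tone1 = 1.30, dur_ratio_tone4 = 1.00,
      tone1_median_rel_st = 3.0, tone1_movement_st = 0,
      tone4_movement_st = -4.5,
      int_peak_diff_tone1_db = -0.5, int_peak_diff_tone4_db = 0.5),
    stop("unknown group label: ", group))
}

# between-speaker standard deviations around the group defaults
speaker_between_sd <- list(
  dur_ratio = 0.08, median_st = 0.8, movement_st = 0.8,
  int_db = 0.75, f0_center_st = 2, syl1_dur_rel = 0.10)

#' Create a synthetic speaker profile
#'
#' Draws one speaker's production parameters: group defaults plus seeded
#' between-speaker variation. The profile fully determines the noiseless
#' acoustics of that speaker's utterances; repetition-to-repetition noise is
#' governed by `jitter_sd` and applied at synthesis time.
#'
#' @param group `"NH"` (normal hearing) or `"CI"` (cochlear implant).
#' @param f0_center_hz Center of the speaker's vocal range in Hz (must lie in
#'   the tracker's default 75-600 Hz search range). Default 220.
#' @param seed Integer seed for the between-speaker draw.
#' @param between_sd Per-parameter between-speaker SDs (list; see
#'   `speaker_between_sd` defaults in the source).
#' @param jitter_sd Repetition noise scales: `duration` (relative SD),
#'   `intensity_db` (dB), `f0_st` (semitones). Set all to 0 for jitter-free
#'   cohorts.
#' @return A `speaker_profile`.
#' @export
make_speaker_profile <- function(group, f0_center_hz = 220, seed = 1,
                                 between_sd = speaker_between_sd,
                                 jitter_sd = list(duration = 0.05,
                                                  intensity_db = 1,
                                                  f0_st = 0.5)) {
  group <- match.arg(group, tone_groups)
  d <- speaker_group_defaults(group)
  if (f0_center_hz < 75 || f0_center_hz > 600) {
    stop("f0_center_hz must lie within the default 75-600 Hz search range")
  }
  p <- with_seed(derive_seed(seed, match(group, tone_groups), 1e4 * f0_center_hz), {
    list(
      group = group,
      f0_center_hz = f0_center_hz *
        2^(stats::rnorm(1, 0, between_sd$f0_center_st) / 12),
      dur_ratio_tone1 = d$dur_ratio_tone1 + stats::rnorm(1, 0, between_sd$dur_ratio),
      dur_ratio_tone4 = d$dur_ratio_tone4 + stats::rnorm(1, 0, between_sd$dur_ratio),
      tone1_median_rel_st = d$tone1_median_rel_st +
        stats::rnorm(1, 0, between_sd$median_st),
      tone1_movement_st = d$tone1_movement_st +
        stats::rnorm(1, 0, between_sd$movement_st),
      tone4_movement_st = d$tone4_movement_st +
        stats::rnorm(1, 0, between_sd$movement_st),
      int_peak_diff_tone1_db = d$int_peak_diff_tone1_db +
        stats::rnorm(1, 0, between_sd$int_db),
      int_peak_diff_tone4_db = d$int_peak_diff_tone4_db +
        stats::rnorm(1, 0, between_sd$int_db),
      syl1_duration_ms = 300 * exp(stats::rnorm(1, 0, between_sd$syl1_dur_rel))
    )
  })
  # Tone 4 starts ~3 st above the first syllable in both groups; its median
  # follows from the onset height and the movement.
  p$tone4_median_rel_st <- 3 + p$tone4_movement_st / 2
  p$jitter_sd <- jitter_sd
  p$seed <- as.integer(seed)
  stopifnot(p$dur_ratio_tone1 > 0, p$dur_ratio_tone4 > 0,
            p$syl1_duration_ms > 60)
  structure(p, class = "speaker_profile")
}

#' @export
print.speaker_profile <- function(x, ...) {
  cat(sprintf(paste0(
    "<speaker_profile %s: F0 center %.0f Hz, dur ratios %.2f/%.2f,\n",
    "  T1 median %+.1f st mov %+.1f st, T4 mov %+.1f st, ",
    "int diff %+.1f/%+.1f dB>\n"),
    x$group, x$f0_center_hz, x$dur_ratio_tone1, x$dur_ratio_tone4,
    x$tone1_median_rel_st, x$tone1_movement_st, x$tone4_movement_st,
    x$int_peak_diff_tone1_db, x$int_peak_diff_tone4_db))
  invisible(x)
}

listener_group_defaults <- function(group) {
  switch(group,
    NH = list(beta_intercept = 4.5, beta_f0slope = -20.7,
              beta_logdur = 6.6, beta_f0height = 0,
              sd_intercept = 1, sd_f0slope = 3, sd_logdur = 3,
              sd_f0height = 0.5),
    CI = list(beta_intercept = 2.0, beta_f0slope = -4.3,
              beta_logdur = 6.6, beta_f0height = 0,
              sd_intercept = 1, sd_f0slope = 3, sd_logdur = 3,
              sd_f0height = 0.5),
    stop("unknown group label: ", group))
}

#' Create a synthetic listener profile
#'
#' Draws one listener's cue weights for the Tone 1 / Tone 4 identification
#' model: the probability of a "Tone 1" response is a logistic function of
#' the F0 fall magnitude (octaves), centered log-duration, and F0-height
#' contrast, optionally mixed with a lapse rate. Group defaults place the NH
#' F0-fall coefficient near -20.7 and the CI coefficient near -4.3, with a
#' shared duration coefficient of 6.6.
#'
#' @param group `"NH"` or `"CI"`.
#' @param seed Integer seed for the between-listener draw.
#' @param lapse_rate Probability in \[0, 0.1\] of a stimulus-independent
#'   guess (default 0: the generative twin of the fitted logistic model).
#' @param overrides Named list overriding any drawn coefficient (useful for
#'   constructing listeners with exact weights).
#' @return A `listener_profile` with fields `beta_intercept`,
#'   `beta_f0slope`, `beta_logdur`, `beta_f0height`, `lapse_rate`, `seed`.
#' @export
make_listener_profile <- function(group, seed = 1, lapse_rate = 0,
                                  overrides = list()) {
  group <- match.arg(group, tone_groups)
  if (lapse_rate < 0 || lapse_rate > 0.1) stop("lapse_rate must be in [0, 0.1]")
  d <- listener_group_defaults(group)
  p <- with_seed(derive_seed(seed, match(group, tone_groups), 77), {
    list(group = group,
         beta_intercept = d$beta_intercept + stats::rnorm(1, 0, d$sd_intercept),
         beta_f0slope = d$beta_f0slope + stats::rnorm(1, 0, d$sd_f0slope),
         beta_logdur = d$beta_logdur + stats::rnorm(1, 0, d$sd_logdur),
         beta_f0height = d$beta_f0height + stats::rnorm(1, 0, d$sd_f0height),
         lapse_rate = lapse_rate)
  })
  for (nm in names(overrides)) p[[nm]] <- overrides[[nm]]
  stopifnot(all(is.finite(unlist(p[grep("^beta", names(p))]))))
  p$seed <- as.integer(seed)
  structure(p, class = "listener_profile")
}

#' @export
print.listener_profile <- function(x, ...) {
  cat(sprintf(paste0("<listener_profile %s: intercept %.1f, F0-fall %.1f, ",
                     "log-dur %.1f, height %.1f, lapse %.2f>\n"),
              x$group, x$beta_intercept, x$beta_f0slope, x$beta_logdur,
              x$beta_f0height, x$lapse_rate))
  invisible(x)
}
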