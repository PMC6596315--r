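# Cohort-level generation: seeded sets of speakers and utterances with a
# truth table, plus cohort-level analysis (the per-speaker two-pass F0
# strategy: pool recordings -> fit vocal range -> constrained re-analysis).

#' Generate a synthetic production cohort
#'
#' Creates `n_nh` NH and `n_ci` CI speakers and synthesizes
#' `(n_nh + n_ci) * 2 * reps` disyllabic utterances (two tones, `reps`
#' repetitions) with group-default production strategies. Deterministic
#' under a fixed seed (byte-identical WAV output).
#'
#' @param n_nh,n_ci Numbers of speakers per group (study sizes: 35 NH, 40 CI).
#' @param reps Repetitions per target word (default 3).
#' @param seed Integer master seed.
#' @param dir Optional directory; when given, each utterance is written as
#'   `{group}_{speaker}_{tone}_{rep}.wav` and the truth table as
#'   `truth.csv`.
#' @param f0_center_hz Nominal vocal-range center before between-speaker
#'   variation; children's voices default to 220 Hz.
#' @param ... Passed to [utterance_spec()] (e.g. `jitter = FALSE`,
#'   `shallow_dip = TRUE`).
#' @return List: `utterances` (named list of `tone_wave`, absent when `dir`
#'   is used), `files` (paths, when `dir` is used), `truth` (data frame: one
#'   row per token with speaker, group, tone, repetition and the generating
#'   descriptor values), `profiles`.
#' @export
generate_cohort <- function(n_nh = 35, n_ci = 40, reps = 3, seed = 1,
                            dir = NULL, f0_center_hz = 220, ...) {
  stopifnot(n_nh >= 1, n_ci >= 1, reps >= 1)
  groups <- c(rep("NH", n_nh), rep("CI", n_ci))
  ids <- c(sprintf("NH%02d", seq_len(n_nh)), sprintf("CI%02d", seq_len(n_ci)))
  profiles <- lapply(seq_along(ids), function(i) {
    make_speaker_profile(groups[i], f0_center_hz,
                         seed = derive_seed(seed, i, 5))
  })
  names(profiles) <- ids
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)

  rows <- list(); waves <- list(); files <- character()
  for (i in seq_along(ids)) {
    for (tone in tone_labels) {
      for (r in seq_len(reps)) {
        spec <- utterance_spec(profiles[[i]], tone, repetition = r, ...)
        wave <- synthesize_utterance(spec)
        tr <- attr(wave, "truth")
        key <- sprintf("%s_%s_%s_%d", groups[i], ids[i], tone, r)
        rows[[key]] <- data.frame(
          speaker = ids[i], group = groups[i], tone = tone, repetition = r,
          duration_ratio = tr$duration_ratio,
          intensity_peak_diff_db = tr$intensity_peak_diff_db,
          f0_median_rel_st = tr$f0_median_rel_st,
          f0_movement_st = tr$f0_movement_st,
          f0_center_hz = tr$f0_center_hz,
          stringsAsFactors = FALSE)
        if (is.null(dir)) {
          waves[[key]] <- wave
        } else {
          path <- file.path(dir, paste0(key, ".wav"))
          write_wav(wave, path)
          files <- c(files, path)
        }
      }
    }
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  if (!is.null(dir)) {
    utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  list(utterances = if (is.null(dir)) waves else NULL,
       files = if (is.null(dir)) NULL else files,
       truth = truth, profiles = profiles)
}

#' Analyze a production cohort with the two-pass F0 strategy
#'
#' For each speaker: all recordings are first tracked with the broad default
#' range (75-600 Hz) and pooled; a normal fit to the pooled log-F0
#' distribution gives the vocal-range center; each token is then re-analyzed
#' within +/-6 st of that center (with the automated voicing-threshold and
#' band-expansion fallbacks) and the four descriptors are computed.
#'
#' @param cohort Result of [generate_cohort()], or a named list of
#'   `tone_wave`s whose names follow `{group}_{speaker}_{tone}_{rep}`, or a
#'   character vector of WAV paths with such basenames.
#' @param cutoff_db Window trim depth (default 20).
#' @param ... Passed to [analyze_utterance()].
#' @return Tidy data frame: speaker, group, tone, repetition, cutoff_db, the
#'   four descriptors, availability flags, prominence_used_db, and the
#'   fallback decisions taken.
#' @export
analyze_cohort <- function(cohort, cutoff_db = 20, ...) {
  if (is.list(cohort) && !is.null(cohort$truth)) {
    waves <- cohort$utterances
    if (is.null(waves)) {
      waves <- lapply(cohort$files, read_wav)
      names(waves) <- sub("\\.wav$", "", basename(cohort$files))
    }
  } else if (is.character(cohort)) {
    waves <- lapply(cohort, read_wav)
    names(waves) <- sub("\\.wav$", "", basename(cohort))
  } else waves <- cohort

  meta <- do.call(rbind, lapply(strsplit(names(waves), "_"), function(s) {
    data.frame(group = s[1], speaker = s[2], tone = s[3],
               repetition = as.integer(s[4]), stringsAsFactors = FALSE)
  }))

  out <- vector("list", length(waves))
  for (spk in unique(meta$speaker)) {
    sel <- which(meta$speaker == spk)
    broad <- lapply(sel, function(i) track_f0(waves[[i]]))
    pooled <- unlist(lapply(broad, function(ct) ct$values[ct$voiced]))
    vr <- estimate_vocal_range(pooled, speaker = spk)
    for (i in sel) {
      an <- analyze_utterance(waves[[i]], cutoff_db = cutoff_db,
                              vocal_range = vr, ...)
      dec <- an$decisions
      out[[i]] <- data.frame(
        speaker = spk, group = meta$group[i], tone = meta$tone[i],
        repetition = meta$repetition[i], cutoff_db = cutoff_db,
        t(an$descriptors),
        available = all(an$available),
        prominence_used_db = an$prominence_used_db,
        threshold_lowered = isTRUE(dec$threshold_lowered),
        band_expanded = isTRUE(dec$band_expanded),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a descriptor table directly (no audio)
#'
#' The statistical twin of `generate_cohort() |> analyze_cohort()`: draws
#' per-token descriptor values as profile parameter + repetition jitter,
#' skipping synthesis and re-analysis. Generator/analyzer consistency of the
#' audio path is established separately by the round-trip recovery tests;
#' this fast path makes replicated power and type-I-error studies of the
#' mixed models feasible.
#'
#' @param n_nh,n_ci Speakers per group.
#' @param reps Repetitions (default 3).
#' @param seed Integer seed.
#' @param null_groups If TRUE, CI speakers are generated with the NH
#'   parameter set (no group differences at all): the null world for
#'   type-I-error calibration.
#' @param jitter_sd Passed to [make_speaker_profile()].
#' @return Data frame like [analyze_cohort()]'s (descriptor columns only).
#' @export
simulate_descriptors <- function(n_nh = 35, n_ci = 40, reps = 3, seed = 1,
                                 null_groups = FALSE,
                                 jitter_sd = list(duration = 0.05,
                                                  intensity_db = 1,
                                                  f0_st = 0.5)) {
  groups <- c(rep("NH", n_nh), rep("CI", n_ci))
  ids <- c(sprintf("NH%02d", seq_len(n_nh)), sprintf("CI%02d", seq_len(n_ci)))
  rows <- list()
  for (i in seq_along(ids)) {
    gen_group <- if (null_groups) "NH" else groups[i]
    prof <- make_speaker_profile(gen_group, 220,
                                 seed = derive_seed(seed, i, 5),
                                 jitter_sd = jitter_sd)
    for (tone in tone_labels) {
      t1 <- tone == "Tone1"
      base <- c(
        duration_ratio = if (t1) prof$dur_ratio_tone1 else prof$dur_ratio_tone4,
        intensity_peak_diff_db = if (t1) prof$int_peak_diff_tone1_db
                           else prof$int_peak_diff_tone4_db,
        f0_median_rel_st = if (t1) prof$tone1_median_rel_st
                           else prof$tone4_median_rel_st,
        f0_movement_st = if (t1) prof$tone1_movement_st
                         else prof$tone4_movement_st)
      for (r in seq_len(reps)) {
        jseed <- derive_seed(prof$seed, match(tone, tone_labels), r,
                             match(gen_group, tone_groups))
        jit <- with_seed(jseed, list(
          d1 = exp(stats::rnorm(1, 0, jitter_sd$duration)),
          ratio = exp(stats::rnorm(1, 0, jitter_sd$duration)),
          int = stats::rnorm(1, 0, jitter_sd$intensity_db),
          med = stats::rnorm(1, 0, jitter_sd$f0_st),
          mov = stats::rnorm(1, 0, jitter_sd$f0_st)))
        rows[[length(rows) + 1L]] <- data.frame(
          speaker = ids[i], group = groups[i], tone = tone, repetition = r,
          duration_ratio = base[["duration_ratio"]] * jit$ratio,
          intensity_peak_diff_db = base[["intensity_peak_diff_db"]] + jit$int,
          f0_median_rel_st = base[["f0_median_rel_st"]] + jit$med,
          f0_movement_st = base[["f0_movement_st"]] + jit$mov,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
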