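# The four per-token production descriptors and the 100-point normalized
# contour summaries. All F0 arithmetic is done on log2(Hz); semitones are
# 12 * log2(f / f_ref).

#' Duration ratio between two syllable windows
#'
#' Syllable 2 length over syllable 1 length; using the ratio discards
#' between-speaker speaking-rate differences.
#'
#' @param win1,win2 `syllable_window`s for syllables 1 and 2.
#' @return Dimensionless ratio.
#' @export
duration_ratio <- function(win1, win2) {
  l1 <- win1$offset_ms - win1$onset_ms
  l2 <- win2$offset_ms - win2$onset_ms
  if (l1 <= 0 || l2 <= 0) stop("zero-length syllable window")
  l2 / l1
}

#' Intensity peak difference between two syllable windows
#'
#' @param win1,win2 `syllable_window`s.
#' @return Peak of syllable 2 minus peak of syllable 1, in dB.
#' @export
intensity_peak_difference <- function(win1, win2) {
  win2$peak_level_db - win1$peak_level_db
}

voiced_f0_in_window <- function(f0_contour, window) {
  idx <- frames_in_window(f0_contour, window)
  idx[f0_contour$voiced[idx]]
}

#' F0 median of syllable 2 relative to syllable 1
#'
#' 12 times the difference between the median log2-F0 over voiced frames of
#' syllable 2 and the mean log2-F0 over voiced frames of syllable 1. The
#' median/mean asymmetry follows the normalization used for the contour
#' figures (syllable 1 enters as its mean); both sides are configurable.
#'
#' @param f0_contour A `tone_contour` of kind `"f0"`.
#' @param win1,win2 `syllable_window`s.
#' @param stat2 Summary for syllable 2 (`"median"` default).
#' @return Semitones, or `NA` (with attribute `unavailable`) when a window
#'   has fewer than 2 voiced frames.
#' @export
f0_median_relative <- function(f0_contour, win1, win2,
                               stat2 = c("median", "mean")) {
  stat2 <- match.arg(stat2)
  i1 <- voiced_f0_in_window(f0_contour, win1)
  i2 <- voiced_f0_in_window(f0_contour, win2)
  if (length(i1) < 2L || length(i2) < 2L) {
    return(structure(NA_real_, unavailable = "insufficient voiced frames"))
  }
  ref <- mean(log2(f0_contour$values[i1]))
  s2 <- if (stat2 == "median") stats::median(log2(f0_contour$values[i2]))
        else mean(log2(f0_contour$values[i2]))
  12 * (s2 - ref)
}

#' F0 movement over a syllable window
#'
#' 12 times the difference between the mean log2-F0 over the last and first
#' 30 ms of the syllable's F0 pattern; negative values are falling
#' inflections. By default the 30-ms portions are taken over voiced frames
#' (unvoiced edge frames are skipped inward); `voiced_only = FALSE` instead
#' takes the literal first/last 30 ms of the window and drops unvoiced
#' frames within them.
#'
#' @param f0_contour A `tone_contour` of kind `"f0"`.
#' @param win2 `syllable_window` for the measured syllable.
#' @param edge_ms Length of the edge portions in ms (default 30).
#' @param voiced_only Interpretation of the edge portions (default TRUE).
#' @return Semitones, or `NA` (attribute `unavailable`) when less than
#'   `2 * edge_ms` of voiced material is available.
#' @export
f0_movement <- function(f0_contour, win2, edge_ms = 30, voiced_only = TRUE) {
  step <- f0_contour$step_ms
  k <- max(1L, round(edge_ms / step))
  idx <- voiced_f0_in_window(f0_contour, win2)
  if (length(idx) < 2L * k) {
    return(structure(NA_real_, unavailable = "insufficient voiced frames"))
  }
  if (voiced_only) {
    first <- idx[seq_len(k)]
    last <- idx[seq.int(length(idx) - k + 1L, length(idx))]
  } else {
    t <- f0_contour$times_ms[idx]
    first <- idx[t <= win2$onset_ms + edge_ms]
    last <- idx[t >= win2$offset_ms - edge_ms]
    if (length(first) < 2L || length(last) < 2L) {
      return(structure(NA_real_, unavailable = "unvoiced window edge"))
    }
  }
  12 * (mean(log2(f0_contour$values[last])) -
          mean(log2(f0_contour$values[first])))
}

#' Resample a windowed contour onto 100 normalized time points
#'
#' Linear-interpolation resampling over the syllable window, on a 0-100%
#' normalized time axis. Intensity patterns are expressed in dB relative to
#' the within-window peak; F0 patterns in semitones relative to `ref`
#' (normally the mean log2-F0 of syllable 1).
#'
#' @param contour A `tone_contour`.
#' @param window A `syllable_window`.
#' @param kind `"intensity"` or `"f0"` (defaults to the contour's kind).
#' @param ref For `kind = "f0"`: reference in log2(Hz).
#' @param n_points Number of resampled points (default 100).
#' @return A `normalized_pattern`: list with `kind`, `points` (length 100),
#'   `percent` (0..100). F0 patterns with voiced coverage gaps exceeding 30%
#'   of the window return all-NA points with an `unavailable` attribute.
#' @export
normalize_pattern <- function(contour, window, kind = contour$kind, ref = NULL,
                              n_points = 100) {
  idx <- frames_in_window(contour, window)
  grid <- seq(window$onset_ms, window$offset_ms, length.out = n_points)
  if (kind == "f0") {
    if (is.null(ref)) stop("ref (syllable-1 mean log2-F0) required for f0 patterns")
    vi <- idx[contour$voiced[idx]]
    if (length(vi) < 2L || length(vi) < 0.7 * length(idx)) {
      out <- structure(list(kind = kind, points = rep(NA_real_, n_points),
                            percent = seq(0, 100, length.out = n_points)),
                       class = "normalized_pattern")
      attr(out, "unavailable") <- "voiced coverage below 70% of window"
      return(out)
    }
    y <- 12 * (log2(contour$values[vi]) - ref)
    pts <- stats::approx(contour$times_ms[vi], y, xout = grid, rule = 2)$y
  } else {
    v <- contour$values[idx]
    y <- v - max(v)
    pts <- stats::approx(contour$times_ms[idx], y, xout = grid, rule = 2)$y
  }
  structure(list(kind = kind, points = pts,
                 percent = seq(0, 100, length.out = n_points)),
            class = "normalized_pattern")
}

#' Aggregate normalized patterns across repetitions and speakers
#'
#' Pointwise mean and standard error, averaging repetitions within speaker
#' first, then across speakers (so each speaker contributes one pattern).
#'
#' @param patterns List of `normalized_pattern`s of the same kind.
#' @param speakers Vector of speaker identifiers, one per pattern (defaults
#'   to all-distinct, i.e. plain across-pattern aggregation).
#' @return List with `mean` and `se`, each of length 100, plus `n_speakers`.
#' @export
aggregate_patterns <- function(patterns, speakers = seq_along(patterns)) {
  stopifnot(length(patterns) >= 2L, length(speakers) == length(patterns))
  kinds <- vapply(patterns, `[[`, character(1), "kind")
  if (length(unique(kinds)) != 1L) stop("patterns mix kinds: ", paste(unique(kinds), collapse = ", "))
  mat <- vapply(patterns, `[[`, numeric(length(patterns[[1]]$points)), "points")
  by_spk <- vapply(unique(speakers), function(s) {
    rowMeans(mat[, speakers == s, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(mat)))
  m <- rowMeans(by_spk, na.rm = TRUE)
  n <- ncol(by_spk)
  se <- apply(by_spk, 1, stats::sd, na.rm = TRUE) / sqrt(n)
  list(mean = m, se = se, n_speakers = n)
}

#' Full acoustic analysis of one disyllabic utterance
#'
#' Runs the extraction chain (intensity contour, peak detection with
#' prominence relaxation, cutoff windowing, constrained F0 tracking) and
#' computes the four tone descriptors.
#'
#' @param wave A `tone_wave`.
#' @param cutoff_db Window trim depth in dB (20 default, 10 variant).
#' @param vocal_range Optional `vocal_range`; when supplied, F0 is tracked
#'   with [refine_f0()] (band restriction + fallbacks), otherwise with the
#'   default broad range of [track_f0()].
#' @param voiced_only_movement Passed to [f0_movement()].
#' @return List: `descriptors` (named numeric: duration_ratio,
#'   intensity_peak_diff_db, f0_median_rel_st, f0_movement_st),
#'   `windows`, `intensity`, `f0`, `prominence_used_db`, `decisions`,
#'   `available` (logical per descriptor).
#' @export
analyze_utterance <- function(wave, cutoff_db = 20, vocal_range = NULL,
                              voiced_only_movement = TRUE) {
  ic <- intensity_contour(wave)
  seg <- segment_syllables(ic, cutoff_db = cutoff_db)
  wins <- list(seg$win1, seg$win2)
  f0c <- if (is.null(vocal_range)) {
    track_f0(wave)
  } else {
    refine_f0(wave, vocal_range, windows = wins)
  }
  d <- c(
    duration_ratio = duration_ratio(seg$win1, seg$win2),
    intensity_peak_diff_db = intensity_peak_difference(seg$win1, seg$win2),
    f0_median_rel_st = as.numeric(f0_median_relative(f0c, seg$win1, seg$win2)),
    f0_movement_st = as.numeric(f0_movement(f0c, seg$win2,
                                            voiced_only = voiced_only_movement)))
  list(descriptors = d, windows = seg, intensity = ic, f0 = f0c,
       prominence_used_db = seg$prominence_used_db,
       decisions = attr(f0c, "decisions"),
       available = !is.na(d))
}
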