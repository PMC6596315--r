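# Autocorrelation F0 tracking with a Praat-like two-pass strategy:
# a broad first pass (75-600 Hz) pooled over a speaker's recordings yields a
# vocal-range estimate (normal fit to log-F0); each token is then re-tracked
# inside +/-6 semitones of that center, with two automated fallbacks that
# mirror the manual interventions used on real recordings: a lowered voicing
# threshold (0.45 -> 0.1) for weakly voiced tokens, and a widened band
# (+12/-9 st) when the contour saturates at a band edge.

st_from_ratio <- function(f, ref) 12 * log2(f / ref)

#' Track fundamental frequency with a normalized autocorrelation method
#'
#' Frames of `window_ms` are analyzed every `step_ms`; for each frame the
#' normalized cross-correlation over candidate periods between `1/fmax` and
#' `1/fmin` is maximized (with parabolic interpolation for sub-sample period
#' precision). A frame is voiced when its correlation peak reaches
#' `voicing_threshold` and its level is above a silence gate. Voiced runs are
#' smoothed with a 5-point running median on log-F0 and residual octave jumps
#' (> 6 st against the local median) are marked unvoiced.
#'
#' @param wave A `tone_wave`.
#' @param fmin,fmax F0 search range in Hz (defaults 75 and 600).
#' @param voicing_threshold Minimum normalized autocorrelation peak height
#'   for a voiced frame (default 0.45; 0.1 is the permissive fallback).
#' @param step_ms Frame step in ms (default 5).
#' @param window_ms Analysis window in ms (default 40).
#' @param silence_db Frames with RMS below this level (dBFS) are unvoiced.
#' @param octave_cost Per-octave penalty subtracted from a candidate's
#'   correlation score as its period grows (default 0.05); disambiguates the
#'   subharmonic (double-period) candidate, whose raw correlation can tie
#'   the true one on strongly periodic signals. Voicing strength is judged
#'   on the unpenalized correlation.
#' @return A `tone_contour` of kind `"f0"` (values in Hz, NA when unvoiced,
#'   with `voiced` flags and `strength`).
#' @export
track_f0 <- function(wave, fmin = 75, fmax = 600, voicing_threshold = 0.45,
                     step_ms = 5, window_ms = 40, silence_db = -70,
                     octave_cost = 0.05) {
  stopifnot(inherits(wave, "tone_wave"))
  fs <- wave$rate
  if (!(fmin > 0 && fmin < fmax && fmax < fs / 2)) {
    stop("need 0 < fmin < fmax < rate/2")
  }
  x <- wave$samples
  n <- length(x)
  wlen <- round(window_ms / 1000 * fs)
  hop <- step_ms / 1000 * fs
  half <- wlen %/% 2
  centers <- round(seq(1, n, by = hop))
  nf <- length(centers)

  # AGC pre-whitening: divide by the smoothed amplitude envelope so that
  # steep intensity ramps within an analysis frame do not weight the
  # correlation toward the louder side (which biases F0 on glides); the
  # silence gate below still uses the original energy
  energy <- pmax(fft_smooth(x^2, {
    m <- max(3L, round(0.03 * fs))
    h <- 0.5 - 0.5 * cos(2 * pi * seq_len(m) / (m + 1)); h / sum(h)
  }), 0)
  gate <- max(energy) * 1e-10
  flat <- ifelse(energy > gate, x / sqrt(energy), 0)
  level_db_all <- ifelse(energy > 0, 10 * log10(energy), -200)

  # frame matrix, zero-padded at the edges
  xpad <- c(numeric(half), flat, numeric(wlen))
  idx <- outer(seq_len(wlen), centers, function(i, c) i + c - 1L)
  fr <- matrix(xpad[idx], nrow = wlen)
  fr <- sweep(fr, 2, colMeans(fr))
  # Hann taper: centers each frame's effective weighting so that steep
  # glides and asymmetric amplitude envelopes do not drag the estimate
  # toward the louder side of the frame
  taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(wlen) / (wlen + 1))
  fr <- fr * taper

  lag_min <- max(2L, floor(fs / fmax))
  lag_max <- min(wlen - 2L, ceiling(fs / fmin))
  if (lag_min >= lag_max) stop("search range too narrow for window")

  nfft <- 2^ceiling(log2(2 * wlen))
  frp <- rbind(fr, matrix(0, nfft - wlen, nf))
  spec <- stats::mvfft(frp)
  ac <- Re(stats::mvfft(spec * Conj(spec), inverse = TRUE)) / nfft  # row tau+1

  # normalized autocorrelation of the tapered frame, divided by the taper's
  # own autocorrelation (which decays with lag and would otherwise skew the
  # peak toward shorter lags and bias F0 upward)
  acw <- Re(stats::fft(Mod(stats::fft(c(taper, numeric(nfft - wlen))))^2,
                       inverse = TRUE)) / nfft
  lags <- lag_min:lag_max
  total <- ac[1L, ]
  num <- ac[lags + 1L, , drop = FALSE]
  wfac <- acw[lags + 1L] / acw[1L]
  r <- sweep(sweep(num, 2, pmax(total, 1e-300), `/`), 1, wfac, `/`)
  r[, total <= 0] <- 0

  score <- r - octave_cost * log2(lags / lag_min)
  best <- max.col(t(score), ties.method = "first")
  strength <- r[cbind(best, seq_len(nf))]
  tau <- lags[best]
  # parabolic interpolation around the peak
  can <- best > 1L & best < length(lags)
  delta <- numeric(nf)
  if (any(can)) {
    i <- which(can)
    y0 <- r[cbind(best[i] - 1L, i)]
    y1 <- r[cbind(best[i], i)]
    y2 <- r[cbind(best[i] + 1L, i)]
    d2 <- y0 - 2 * y1 + y2
    delta[i] <- ifelse(abs(d2) > 1e-12, 0.5 * (y0 - y2) / d2, 0)
    delta[i] <- pmax(pmin(delta[i], 0.5), -0.5)
  }
  f0 <- fs / (tau + delta)
  level_db <- level_db_all[centers]
  voiced <- is.finite(strength) & strength >= voicing_threshold &
    level_db > silence_db & f0 >= fmin * 0.99 & f0 <= fmax * 1.01

  f0[!voiced] <- NA_real_
  # median smoothing on log-F0 within voiced runs
  runs <- rle(voiced)
  pos <- cumsum(c(1L, runs$lengths))
  for (k in seq_along(runs$values)) {
    if (!runs$values[k] || runs$lengths[k] < 5L) next
    seg <- pos[k]:(pos[k + 1L] - 1L)
    f0[seg] <- 2^stats::runmed(log2(f0[seg]), 5, endrule = "keep")
  }
  # suppress residual octave jumps: > 6 st against an 11-point local median
  vi <- which(voiced)
  if (length(vi) >= 3L) {
    lf <- log2(f0[vi])
    k <- min(11L, if (length(vi) %% 2L == 0L) length(vi) - 1L else length(vi))
    if (k >= 3L) {
      med <- stats::runmed(lf, k, endrule = "median")
      bad <- abs(lf - med) * 12 > 6
      if (any(bad)) {
        voiced[vi[bad]] <- FALSE
        f0[vi[bad]] <- NA_real_
      }
    }
  }
  contour((centers - 1) / fs * 1000, f0, kind = "f0", step_ms = step_ms,
          voiced = voiced, strength = strength)
}

#' Estimate a speaker's vocal range from pooled F0 samples
#'
#' Fits a normal probability density to the pooled F0 distribution on a
#' logarithmic axis; the fitted mean is the center of the vocal range and the
#' working band is `lower_st`/`upper_st` semitones around it (defaults -6 and
#' +6). Octave-jump outliers perturb the fitted mean only in proportion to
#' their share of the data.
#'
#' @param f0_values Pooled voiced F0 samples in Hz (across a speaker's
#'   recordings); NAs dropped.
#' @param lower_st,upper_st Band edges in semitones relative to the center.
#' @param min_n Minimum number of voiced samples required (default 50).
#' @param speaker Optional label used in error messages.
#' @return A `vocal_range`: center_log2hz, center_hz, sd_st, lower_st,
#'   upper_st, voicing_threshold.
#' @export
estimate_vocal_range <- function(f0_values, lower_st = -6, upper_st = 6,
                                 min_n = 50, speaker = NULL) {
  v <- f0_values[is.finite(f0_values) & f0_values > 0]
  if (length(v) < min_n) {
    stop(sprintf("too few voiced F0 samples (%d < %d)%s", length(v), min_n,
                 if (is.null(speaker)) "" else paste0(" for speaker ", speaker)))
  }
  stopifnot(lower_st < 0, upper_st > 0)
  lf <- log2(v)
  structure(list(center_log2hz = mean(lf), center_hz = 2^mean(lf),
                 sd_st = 12 * stats::sd(lf),
                 lower_st = lower_st, upper_st = upper_st,
                 voicing_threshold = 0.45),
            class = "vocal_range")
}

#' @export
print.vocal_range <- function(x, ...) {
  cat(sprintf("<vocal_range: center %.1f Hz, band %+g/%+g st, sd %.2f st>\n",
              x$center_hz, x$lower_st, x$upper_st, x$sd_st))
  invisible(x)
}

#' Hz bounds of a vocal range band
#' @param range A `vocal_range`.
#' @return Numeric `c(fmin, fmax)` in Hz.
#' @export
vocal_range_hz <- function(range) {
  range$center_hz * 2^(c(range$lower_st, range$upper_st) / 12)
}

# >= k consecutive voiced frames within tol_st of a band edge?
band_edge_saturated <- function(contour, fmin, fmax, tol_st = 0.25, k = 3L) {
  f <- contour$values
  near <- !is.na(f) &
    (abs(st_from_ratio(f, fmin)) <= tol_st | abs(st_from_ratio(f, fmax)) <= tol_st)
  r <- rle(near)
  any(r$values & r$lengths >= k)
}

voiced_coverage <- function(contour, window) {
  idx <- frames_in_window(contour, window)
  if (!length(idx)) return(0)
  mean(contour$voiced[idx])
}

#' Re-track F0 inside a speaker's vocal range, with automated fallbacks
#'
#' Tracks F0 constrained to the vocal-range band. Two retries mirror the
#' manual interventions applied to abnormal real tokens: (1) if voiced
#' coverage inside any supplied syllable window falls below
#' `coverage_threshold`, the voicing threshold is lowered to 0.1; (2) if the
#' tracked contour saturates at a band edge, the band is widened to +12/-9
#' semitones around the center. Decisions are recorded in the result's
#' `decisions` attribute. If after all fallbacks a supplied window still has
#' fewer than 2 voiced frames, its index is listed in the
#' `unavailable_windows` attribute (descriptor-unavailable signal).
#'
#' @param wave A `tone_wave`.
#' @param vocal_range A `vocal_range` from [estimate_vocal_range()].
#' @param windows Optional list of `syllable_window`s used to judge coverage.
#' @param coverage_threshold Minimum voiced fraction per window before the
#'   permissive threshold is tried (default 0.6).
#' @param fallback_threshold Permissive voicing threshold (default 0.1).
#' @param expanded_st Widened band in semitones `c(lower, upper)` (default
#'   `c(-9, 12)`).
#' @param ... Passed to [track_f0()].
#' @return A `tone_contour` of kind `"f0"` with attributes `decisions` and
#'   (possibly) `unavailable_windows`.
#' @export
refine_f0 <- function(wave, vocal_range, windows = NULL,
                      coverage_threshold = 0.6, fallback_threshold = 0.1,
                      expanded_st = c(-9, 12), ...) {
  stopifnot(inherits(vocal_range, "vocal_range"))
  band <- vocal_range_hz(vocal_range)
  thr <- vocal_range$voicing_threshold
  decisions <- list(threshold_lowered = FALSE, band_expanded = FALSE,
                    band_hz = band, voicing_threshold = thr)

  ctr <- track_f0(wave, band[1], band[2], voicing_threshold = thr, ...)

  low_coverage <- function(ct) {
    !is.null(windows) &&
      any(vapply(windows, function(w) voiced_coverage(ct, w), numeric(1)) <
            coverage_threshold)
  }
  if (low_coverage(ctr)) {
    thr <- fallback_threshold
    ctr <- track_f0(wave, band[1], band[2], voicing_threshold = thr, ...)
    decisions$threshold_lowered <- TRUE
    decisions$voicing_threshold <- thr
  }
  if (band_edge_saturated(ctr, band[1], band[2])) {
    band <- vocal_range$center_hz * 2^(expanded_st / 12)
    ctr <- track_f0(wave, band[1], band[2], voicing_threshold = thr, ...)
    decisions$band_expanded <- TRUE
    decisions$band_hz <- band
    # widened band may re-expose the coverage problem
    if (thr != fallback_threshold && low_coverage(ctr)) {
      thr <- fallback_threshold
      ctr <- track_f0(wave, band[1], band[2], voicing_threshold = thr, ...)
      decisions$threshold_lowered <- TRUE
      decisions$voicing_threshold <- thr
    }
  }
  if (!is.null(windows)) {
    nv <- vapply(windows, function(w) {
      idx <- frames_in_window(ctr, w)
      sum(ctr$voiced[idx])
    }, numeric(1))
    if (any(nv < 2)) attr(ctr, "unavailable_windows") <- which(nv < 2)
  }
  attr(ctr, "decisions") <- decisions
  ctr
}
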