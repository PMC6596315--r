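# Intensity contour, prominence-based peak picking and syllable windowing.
#
# The segmentation strategy: take the smoothed intensity contour, locate the
# two most prominent peaks (starting at a 20-dB prominence requirement and
# relaxing it only when fewer than two peaks qualify), then trim each syllable
# where the contour falls a fixed cutoff (20 or 10 dB) below its peak.

# linear convolution of x with kernel k via FFT, returning the "same" part
# aligned so that out[i] = sum_j k[j] * x[i + j - center]
fft_smooth <- function(x, k) {
  n <- length(x); m <- length(k)
  nfft <- 2^ceiling(log2(n + m))
  X <- stats::fft(c(x, numeric(nfft - n)))
  K <- stats::fft(c(k, numeric(nfft - m)))
  full <- Re(stats::fft(X * K, inverse = TRUE)) / nfft
  center <- (m + 1) %/% 2
  full[center:(center + n - 1)]
}

#' Intensity contour of a waveform
#'
#' Frame energy (Hann-weighted mean square over a 30-ms window) expressed in
#' dB re full scale, sampled every 5 ms. Silent frames bottom out at
#' `floor_db`; an all-zero signal yields a flat contour at the floor rather
#' than an error.
#'
#' @param wave A `tone_wave`.
#' @param step_ms Frame step in ms (default 5).
#' @param window_ms Analysis window length in ms (default 30).
#' @param floor_db Silence floor in dB (default -100).
#' @return A `tone_contour` of kind `"intensity"`.
#' @export
intensity_contour <- function(wave, step_ms = 5, window_ms = 30,
                              floor_db = -100) {
  stopifnot(inherits(wave, "tone_wave"))
  x <- wave$samples
  if (length(x) == 0L) stop("empty waveform")
  fs <- wave$rate
  wlen <- max(3L, round(window_ms / 1000 * fs))
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(wlen) / (wlen + 1))
  w <- w / sum(w)
  energy <- fft_smooth(x^2, w)
  hop <- step_ms / 1000 * fs
  centers <- seq(1, length(x), by = hop)
  idx <- pmin(pmax(round(centers), 1L), length(x))
  e <- pmax(energy[idx], 0)
  db <- ifelse(e > 0, 10 * log10(e), floor_db)
  db <- pmax(db, floor_db)
  contour((idx - 1) / fs * 1000, db, kind = "intensity", step_ms = step_ms)
}

# All local maxima of v with their topographic prominences.
# A peak's prominence is its height above the higher of the two minima
# separating it from higher terrain (or the signal edge on that side).
peak_prominences <- function(v) {
  n <- length(v)
  if (n < 3L) return(data.frame(index = integer(), value = numeric(),
                                prominence = numeric()))
  peaks <- integer()
  i <- 2L
  while (i <= n - 1L) {
    if (v[i] > v[i - 1L]) {
      j <- i
      while (j < n && v[j + 1L] == v[j]) j <- j + 1L  # plateau
      if (j < n && v[j + 1L] < v[j]) peaks <- c(peaks, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  prom <- vapply(peaks, function(p) {
    lmin <- v[p]
    for (j in seq(p - 1L, 1L)) {
      if (v[j] > v[p]) break
      lmin <- min(lmin, v[j])
    }
    rmin <- v[p]
    for (j in seq(p + 1L, n)) {
      if (v[j] > v[p]) break
      rmin <- min(rmin, v[j])
    }
    v[p] - max(lmin, rmin)
  }, numeric(1))
  data.frame(index = peaks, value = v[peaks], prominence = prom)
}

#' Locate the two syllable peaks of a disyllabic intensity contour
#'
#' Runs prominence-based peak detection with a 20-dB prominence requirement;
#' when fewer than two peaks qualify (a shallow inter-syllable dip), the
#' requirement is relaxed in 2-dB steps down to a floor until two peaks are
#' found. If more than two qualify, the two most prominent are kept and
#' returned in temporal order.
#'
#' @param contour Intensity `tone_contour` with at least 3 frames.
#' @param prominence_db Starting prominence requirement in dB (default 20).
#' @param step_db Relaxation step in dB (default 2).
#' @param floor_db Lowest prominence tried (default 6).
#' @return List with `peaks` (data frame: index, time_ms, value),
#'   `prominence_used_db`, and `all_peaks` (the full prominence table).
#'   Signals a condition of class `tonelab_segmentation_failure` (carrying the
#'   contour) if two peaks cannot be found even at the floor.
#' @export
detect_syllable_peaks <- function(contour, prominence_db = 20, step_db = 2,
                                  floor_db = 6) {
  stopifnot(inherits(contour, "tone_contour"))
  if (length(contour$values) < 3L) stop("contour has fewer than 3 frames")
  tab <- peak_prominences(contour$values)
  for (thr in seq(prominence_db, floor_db, by = -step_db)) {
    ok <- tab[tab$prominence >= thr, , drop = FALSE]
    if (nrow(ok) >= 2L) {
      keep <- ok[order(-ok$prominence, -ok$value)[1:2], , drop = FALSE]
      keep <- keep[order(keep$index), , drop = FALSE]
      peaks <- data.frame(index = keep$index,
                          time_ms = contour$times_ms[keep$index],
                          value = keep$value,
                          prominence = keep$prominence)
      return(list(peaks = peaks, prominence_used_db = thr, all_peaks = tab))
    }
  }
  cond <- structure(
    class = c("tonelab_segmentation_failure", "error", "condition"),
    list(message = sprintf(
      "could not locate two intensity peaks (found %d at prominence >= %g dB)",
      nrow(tab[tab$prominence >= floor_db, ]), floor_db),
      call = sys.call(-1), contour = contour))
  stop(cond)
}

#' Trim a syllable window around an intensity peak
#'
#' The syllable extends from the last crossing of `peak - cutoff_db` before
#' the peak to the first crossing after it, with sub-frame linear
#' interpolation. Search is confined to `limits` (frame indices); when the
#' cutoff is never reached before a limit, the window is clamped there and
#' flagged (`"edge_clamped"` at the signal edge, `"truncated"` at an
#' inter-syllable minimum).
#'
#' @param contour Intensity `tone_contour`.
#' @param peak One row of `detect_syllable_peaks()$peaks` (or any list with
#'   `index` and `value`).
#' @param cutoff_db Trim depth below the peak in dB; the paper's analyses use
#'   20 (full syllable) and 10 (voiced-core focus).
#' @param limits Integer vector `c(lo, hi)` of frame indices confining the
#'   search; defaults to the whole contour.
#' @param limit_kind Character pair naming what each limit is
#'   (`"edge"` or `"valley"`), used only for flagging.
#' @return A `syllable_window`: onset_ms, offset_ms, peak_time_ms,
#'   peak_level_db, cutoff_db, flags.
#' @export
window_syllable <- function(contour, peak, cutoff_db = 20, limits = NULL,
                            limit_kind = c("edge", "edge")) {
  stopifnot(inherits(contour, "tone_contour"))
  v <- contour$values; t <- contour$times_ms
  n <- length(v)
  if (is.null(limits)) limits <- c(1L, n)
  p <- peak$index
  stopifnot(p >= limits[1], p <= limits[2])
  thr <- peak$value - cutoff_db
  flags <- character()

  cross_time <- function(i_out, i_in) {
    # linear interpolation of the threshold crossing between two frames
    t[i_out] + (thr - v[i_out]) / (v[i_in] - v[i_out]) * (t[i_in] - t[i_out])
  }
  below_left <- which(v[limits[1]:p] < thr)
  if (length(below_left)) {
    i <- limits[1] + max(below_left) - 1L
    onset <- cross_time(i, i + 1L)
  } else {
    onset <- t[limits[1]]
    flags <- c(flags, paste0("onset_", limit_kind[1], "_clamped"))
  }
  below_right <- which(v[p:limits[2]] < thr)
  if (length(below_right)) {
    i <- p + min(below_right) - 1L
    offset <- cross_time(i, i - 1L)
  } else {
    offset <- t[limits[2]]
    flags <- c(flags, paste0("offset_", limit_kind[2], "_clamped"))
  }
  structure(list(onset_ms = onset, offset_ms = offset,
                 peak_time_ms = t[p], peak_level_db = peak$value,
                 peak_index = p, cutoff_db = cutoff_db, flags = flags),
            class = "syllable_window")
}

#' @export
print.syllable_window <- function(x, ...) {
  cat(sprintf(
    "<syllable_window: %.1f-%.1f ms (peak %.1f dB @ %.1f ms, cutoff %g dB)%s>\n",
    x$onset_ms, x$offset_ms, x$peak_level_db, x$peak_time_ms, x$cutoff_db,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Segment a disyllabic intensity contour into two syllable windows
#'
#' Combines [detect_syllable_peaks()] and [window_syllable()]: the search for
#' syllable 1's offset and syllable 2's onset is bounded by the
#' inter-syllable intensity minimum, so shallow dips yield abutting windows
#' rather than overlapping ones.
#'
#' @inheritParams detect_syllable_peaks
#' @param cutoff_db Trim depth in dB (20 default, 10 for the conservative
#'   variant).
#' @return List with `win1`, `win2` (syllable windows), `valley_index`,
#'   `prominence_used_db`.
#' @export
segment_syllables <- function(contour, cutoff_db = 20, prominence_db = 20,
                              step_db = 2, floor_db = 6) {
  det <- detect_syllable_peaks(contour, prominence_db, step_db, floor_db)
  p1 <- det$peaks[1, ]; p2 <- det$peaks[2, ]
  seg <- p1$index:p2$index
  valley <- seg[which.min(contour$values[seg])]
  win1 <- window_syllable(contour, p1, cutoff_db,
                          limits = c(1L, valley), limit_kind = c("edge", "valley"))
  win2 <- window_syllable(contour, p2, cutoff_db,
                          limits = c(valley, length(contour$values)),
                          limit_kind = c("valley", "edge"))
  win1$prominence_used_db <- det$prominence_used_db
  win2$prominence_used_db <- det$prominence_used_db
  list(win1 = win1, win2 = win2, valley_index = valley,
       prominence_used_db = det$prominence_used_db)
}
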