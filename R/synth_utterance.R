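# Disyllabic utterance synthesis: a harmonic pulse-train source (-12 dB/oct
# roll-off) shaped by a dB-domain intensity envelope and a piecewise log-F0
# trajectory. Syllable 1 carries a dipping (Tone 3) contour; syllable 2
# carries a level/rising (Tone 1) or falling (Tone 4) contour.
#
# The generator is calibrated against its own analyzer: because a 30-ms RMS
# window blurs the intensity envelope, physical durations and peak gains are
# adjusted (via a cheap envelope-domain prediction of the measured 20-dB
# windows) so that the *measured* duration ratio, intensity peak difference,
# F0 median and F0 movement equal the requested profile parameters. The F0
# ramp of syllable 2 is laid over the predicted window and its span widened
# by L/(L-30) so that the first/last-30-ms averaging recovers the requested
# movement exactly.

# dB shape of one syllable on normalized time [0,1]: linear edges to the
# -20 dB anchors at 3%/97%, and a -20*d^alpha interior with peak `up`.
syllable_shape_db <- function(u, kind, edge_left_db, edge_right_db) {
  par <- switch(kind,
    tone3 = list(up = 1 / 3, alpha = 2),
    tone1 = list(up = 0.45, alpha = 3),
    tone4 = list(up = 0.5, alpha = 1.3),
    stop("unknown syllable shape: ", kind))
  ua <- 0.03; ub <- 0.97
  v <- numeric(length(u))
  left <- u < ua
  right <- u > ub
  mid <- !left & !right
  v[left] <- edge_left_db + (u[left] / ua) * (-20 - edge_left_db)
  v[right] <- -20 + ((u[right] - ub) / (1 - ub)) * (edge_right_db - (-20))
  d <- ifelse(u[mid] < par$up, (par$up - u[mid]) / (par$up - ua),
              (u[mid] - par$up) / (ub - par$up))
  v[mid] <- -20 * pmax(d, 0)^par$alpha
  v
}

# assemble the utterance envelope on a 1-ms grid
# returns t_ms, env_db (NA in the pads), index spans of the two syllables
build_envelope_ms <- function(d1_ms, d2_ms, gap_ms, pad_ms, dip_db,
                              peak1_db, peak2_db, shape2) {
  gl <- max(peak1_db, peak2_db) - dip_db
  total <- 2 * pad_ms + d1_ms + gap_ms + d2_ms
  t <- seq(0, total, by = 1)
  env <- rep(NA_real_, length(t))
  t1 <- c(pad_ms, pad_ms + d1_ms)
  t2 <- c(t1[2] + gap_ms, t1[2] + gap_ms + d2_ms)
  i1 <- which(t >= t1[1] & t <= t1[2])
  i2 <- which(t >= t2[1] & t <= t2[2])
  ig <- which(t > t1[2] & t < t2[1])
  env[i1] <- peak1_db + syllable_shape_db((t[i1] - t1[1]) / d1_ms, "tone3",
                                          -45, gl - peak1_db)
  env[i2] <- peak2_db + syllable_shape_db((t[i2] - t2[1]) / d2_ms, shape2,
                                          gl - peak2_db, -45)
  env[ig] <- gl
  list(t_ms = t, env_db = env, syl1_ms = t1, syl2_ms = t2, gap_db = gl,
       total_ms = total)
}

# predict what intensity_contour() will measure from an envelope: smooth the
# energy with a 30-ms Hann and read off peak levels and 20-dB crossings
predict_measured_windows <- function(envl, cutoff_db = 20, window_ms = 30) {
  e <- ifelse(is.na(envl$env_db), 0, 10^(envl$env_db / 10))
  m <- 2 * (window_ms %/% 2) + 1
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(m) / (m + 1)); w <- w / sum(w)
  sm <- stats::filter(e, w, sides = 2)
  sm[is.na(sm)] <- 0
  db_full <- ifelse(sm > 0, 10 * log10(as.numeric(sm)), -100)
  # emulate the analyzer: 5-ms frames, discrete peak, interpolated crossing
  sub <- seq(1, length(envl$t_ms), by = 5)
  db <- db_full[sub]
  t <- envl$t_ms[sub]
  pk <- function(span_ms) {
    idx <- which(t >= span_ms[1] & t <= span_ms[2])
    idx[which.max(db[idx])]
  }
  p1 <- pk(envl$syl1_ms); p2 <- pk(envl$syl2_ms)
  valley <- (p1:p2)[which.min(db[p1:p2])]
  # crossing search bounded like the analyzer's: at the valley between the
  # syllables (shallow dips truncate there) and at the signal edges
  one <- function(p, lo_lim, hi_lim) {
    thr <- db[p] - cutoff_db
    lo <- which(db[lo_lim:p] < thr)
    on <- if (length(lo)) {
      i <- lo_lim + max(lo) - 1
      t[i] + (thr - db[i]) / (db[i + 1] - db[i]) * (t[i + 1] - t[i])
    } else t[lo_lim]
    hi <- which(db[p:hi_lim] < thr)
    off <- if (length(hi)) {
      i <- p + min(hi) - 1
      t[i] + (thr - db[i]) / (db[i - 1] - db[i]) * (t[i - 1] - t[i])
    } else t[hi_lim]
    c(onset = on, offset = off, peak_db = db[p], peak_ms = t[p])
  }
  list(w1 = one(p1, 1L, valley), w2 = one(p2, valley, length(db)))
}

#' Specify one synthetic utterance
#'
#' @param profile A `speaker_profile`.
#' @param tone `"Tone1"` or `"Tone4"` (the second syllable's tone; the first
#'   syllable always carries the dipping Tone 3).
#' @param repetition Repetition index (1..reps); enters the jitter seed.
#' @param pad_ms Leading/trailing silence in ms (default 400).
#' @param gap_ms Inter-syllable gap in ms (default 80).
#' @param dip_db Depth of the inter-syllable intensity dip below the peaks
#'   (default 30 so the 20-dB windowing succeeds).
#' @param shallow_dip If TRUE, sets the dip to 15 dB to exercise the
#'   prominence-relaxation path of the segmenter.
#' @param jitter Logical or numeric scale for repetition jitter (FALSE/0
#'   disables it; TRUE = 1 uses the profile's `jitter_sd`).
#' @param breathiness Fraction in \[0, 1) of frame energy given to aspiration
#'   noise (lowers periodicity strength; default 0).
#' @param tone3_min_frac Position of the Tone 3 F0 minimum as a fraction of
#'   the first syllable window (default 2/3).
#' @return An `utterance_spec`.
#' @export
utterance_spec <- function(profile, tone = c("Tone1", "Tone4"), repetition = 1,
                           pad_ms = 400, gap_ms = 80, dip_db = 30,
                           shallow_dip = FALSE, jitter = TRUE,
                           breathiness = 0, tone3_min_frac = 2 / 3) {
  stopifnot(inherits(profile, "speaker_profile"), pad_ms >= 0, gap_ms > 0,
            breathiness >= 0, breathiness < 1)
  tone <- match.arg(tone)
  if (shallow_dip) dip_db <- 15
  structure(list(profile = profile, tone = tone,
                 repetition = as.integer(repetition), pad_ms = pad_ms,
                 gap_ms = gap_ms, dip_db = dip_db,
                 jitter = as.numeric(jitter), breathiness = breathiness,
                 tone3_min_frac = tone3_min_frac),
            class = "utterance_spec")
}

#' Synthesize a disyllabic utterance
#'
#' Renders the utterance described by an [utterance_spec()] at 44.1 kHz: a
#' harmonic source with -12 dB/octave roll-off under a dB-domain intensity
#' envelope, with leading/trailing silence and a voiced inter-syllable gap
#' `dip_db` below the peaks. The generating descriptor values (after
#' repetition jitter) are attached as the `truth` attribute; with jitter
#' disabled they equal the profile parameters.
#'
#' @param spec An `utterance_spec`.
#' @param rate Sampling rate in Hz (default 44100).
#' @return A `tone_wave` with attribute `truth` (list: duration_ratio,
#'   intensity_peak_diff_db, f0_median_rel_st, f0_movement_st, syl1/syl2 spans and
#'   predicted 20-dB windows in ms, syl1 mean F0).
#' @export
synthesize_utterance <- function(spec, rate = 44100) {
  stopifnot(inherits(spec, "utterance_spec"))
  p <- spec$profile
  tone1 <- spec$tone == "Tone1"
  seed <- derive_seed(p$seed, match(spec$tone, tone_labels), spec$repetition,
                      match(p$group, tone_groups))

  base <- list(
    ratio = if (tone1) p$dur_ratio_tone1 else p$dur_ratio_tone4,
    int_diff = if (tone1) p$int_peak_diff_tone1_db else p$int_peak_diff_tone4_db,
    median = if (tone1) p$tone1_median_rel_st else p$tone4_median_rel_st,
    movement = if (tone1) p$tone1_movement_st else p$tone4_movement_st)

  j <- spec$jitter
  js <- p$jitter_sd
  jit <- with_seed(seed, list(
    d1 = exp(stats::rnorm(1, 0, j * js$duration)),
    ratio = exp(stats::rnorm(1, 0, j * js$duration)),
    int = stats::rnorm(1, 0, j * js$intensity_db),
    med = stats::rnorm(1, 0, j * js$f0_st),
    mov = stats::rnorm(1, 0, j * js$f0_st)))

  d1 <- p$syl1_duration_ms * jit$d1
  ratio <- base$ratio * jit$ratio
  int_diff <- base$int_diff + jit$int
  med <- base$median + jit$med
  mov <- base$movement + jit$mov
  if (d1 <= 60 || ratio <= 0) stop("parameters produce a non-positive or degenerate duration")

  shape2 <- if (tone1) "tone1" else "tone4"
  g1 <- if (int_diff >= 0) -int_diff else 0
  g2 <- if (int_diff >= 0) 0 else int_diff

  # calibrate physical duration of syllable 2 so the measured 20-dB window
  # ratio equals `ratio`, and the gains so the measured peak diff is exact
  d2 <- ratio * d1
  envl <- build_envelope_ms(d1, d2, spec$gap_ms, spec$pad_ms, spec$dip_db,
                            g1, g2, shape2)
  pw <- predict_measured_windows(envl)
  w1_len <- pw$w1[["offset"]] - pw$w1[["onset"]]
  for (it in 1:3) {
    target_w2 <- ratio * w1_len
    w2_len <- pw$w2[["offset"]] - pw$w2[["onset"]]
    d2 <- d2 * target_w2 / w2_len
    meas_diff <- pw$w2[["peak_db"]] - pw$w1[["peak_db"]]
    g2 <- g2 + (int_diff - meas_diff)
    shift <- max(g1, g2)   # keep the louder peak at 0 dB
    g1 <- g1 - shift; g2 <- g2 - shift
    envl <- build_envelope_ms(d1, d2, spec$gap_ms, spec$pad_ms, spec$dip_db,
                              g1, g2, shape2)
    pw <- predict_measured_windows(envl)
    w1_len <- pw$w1[["offset"]] - pw$w1[["onset"]]
  }

  # ---- F0 design (semitones relative to the profile's vocal-range center)
  a1 <- pw$w1[["onset"]]; b1 <- pw$w1[["offset"]]
  a2 <- pw$w2[["onset"]]; b2 <- pw$w2[["offset"]]
  tmin <- a1 + spec$tone3_min_frac * (b1 - a1)
  syl1_pts <- list(t = c(a1, tmin, b1), st = c(1.0, -1.5, -0.5))
  # mean log-F0 over the window of a piecewise-linear contour
  seg_mean <- function(t, v) {
    sum(diff(t) * (utils::head(v, -1) + utils::tail(v, -1)) / 2) / diff(range(t))
  }
  m1 <- seg_mean(syl1_pts$t, syl1_pts$st)

  l2 <- b2 - a2
  if (l2 <= 60) stop("syllable 2 window too short for a 30-ms movement measure")
  v_ramp <- mov * l2 / (l2 - 30)
  st2_start <- m1 + med - v_ramp / 2
  st2_end <- m1 + med + v_ramp / 2

  # the ramp is extended at constant slope to the physical syllable edges so
  # that 40-ms tracker frames near the window edges average over the
  # continuing ramp (time-symmetric) instead of a held value (biased inward)
  t1 <- envl$syl1_ms; t2 <- envl$syl2_ms
  sl2 <- v_ramp / l2                       # st per ms
  st2_t2s <- st2_start - sl2 * (a2 - t2[1])
  st2_t2e <- st2_end + sl2 * (t2[2] - b2)
  ctrl_t <- c(0, a1, tmin, b1, t2[1], t2[2], envl$total_ms)
  ctrl_st <- c(1.0, 1.0, -1.5, -0.5, st2_t2s, st2_t2e, st2_t2e)
  # monotone time needed for interpolation
  stopifnot(!is.unsorted(ctrl_t))

  # ---- sample-domain synthesis
  n <- round(envl$total_ms / 1000 * rate)
  ts_ms <- (seq_len(n) - 1) / rate * 1000
  st <- stats::approx(ctrl_t, ctrl_st, xout = ts_ms, rule = 2)$y
  f0 <- p$f0_center_hz * 2^(st / 12)
  phase <- 2 * pi * cumsum(f0) / rate
  kmax <- max(3L, min(20L, floor(0.45 * rate / max(f0))))
  amps <- (1 / seq_len(kmax))^2
  harm <- numeric(n)
  for (k in seq_len(kmax)) harm <- harm + amps[k] * sin(k * phase)
  harm <- harm / sqrt(sum(amps^2) / 2)   # unit RMS source

  env_db <- stats::approx(envl$t_ms, ifelse(is.na(envl$env_db), -200,
                                            envl$env_db),
                          xout = ts_ms, rule = 2)$y
  in_pad <- ts_ms < spec$pad_ms | ts_ms >= envl$total_ms - spec$pad_ms
  amp <- 10^(env_db / 20) * 0.1
  amp[in_pad] <- 0

  b <- spec$breathiness
  x <- if (b > 0) {
    noise <- with_seed(derive_seed(seed, 991), stats::rnorm(n))
    amp * (sqrt(1 - b) * harm + sqrt(b) * noise)
  } else amp * harm
  if (max(abs(x)) >= 1) stop("synthesis clipped after normalization")

  wave <- waveform(x, rate)
  attr(wave, "truth") <- list(
    tone = spec$tone, group = p$group, repetition = spec$repetition,
    duration_ratio = ratio, intensity_peak_diff_db = int_diff,
    f0_median_rel_st = med, f0_movement_st = mov,
    f0_center_hz = p$f0_center_hz, syl1_mean_rel_st = m1,
    syl1_span_ms = t1, syl2_span_ms = t2,
    win1_ms = c(a1, b1), win2_ms = c(a2, b2), dip_db = spec$dip_db)
  wave
}
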