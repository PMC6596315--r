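# The Tone 1 - Tone 4 perception continuum: a fully crossed grid of 8 F0
# slopes x 6 durations x 2 F0 heights = 96 tokens per session. Because the
# base stimuli here are synthetic, tokens are regenerated from source
# parameters (exact F0/duration control) rather than resynthesized from
# audio; the amplitude contour is identical across tokens and only the
# overall level is equalized (common RMS).

continuum_slopes <- c(-1, -0.8, -0.6, -0.4, -0.3, -0.2, -0.1, 0)
continuum_durations <- c(40, 60, 80, 100, 120, 140)
continuum_heights <- c(120, 220)

# centering constant for the log-duration covariate: mean log over the grid
logdur_center <- function() mean(log(continuum_durations / 100))

#' Build the full 96-token continuum grid
#'
#' Fully crossed specs: F0 slope of the second syllable in octaves
#' (-1 ... 0, 8 levels), duration as percent of the base duration (40 ... 140,
#' 6 levels), and F0 height 120 Hz (male-typical) or 220 Hz (female-typical).
#'
#' @param session Session index stamped on every spec (default 1).
#' @return Data frame of 96 unique `ContinuumTokenSpec` rows: token_id,
#'   f0_slope_oct, duration_pct, f0_height_hz, session.
#' @export
build_token_grid <- function(session = 1) {
  g <- expand.grid(f0_slope_oct = continuum_slopes,
                   duration_pct = continuum_durations,
                   f0_height_hz = continuum_heights,
                   KEEP.OUT.ATTRS = FALSE)
  g$session <- as.integer(session)
  g$token_id <- sprintf("s%02.0f_d%03d_h%03d",
                        -100 * g$f0_slope_oct, g$duration_pct, g$f0_height_hz)
  g[, c("token_id", "f0_slope_oct", "duration_pct", "f0_height_hz", "session")]
}

#' Base parameters for continuum token rendering
#'
#' @param syl1_duration_ms,syl2_duration_ms Physical durations of the two
#'   syllables at 100% (defaults 300 and 350 ms).
#' @param gap_ms,pad_ms Inter-syllable gap and edge silence in ms.
#' @param dip_db Inter-syllable intensity dip (default 30).
#' @return A `continuum_base` list.
#' @export
continuum_base <- function(syl1_duration_ms = 300, syl2_duration_ms = 350,
                           gap_ms = 80, pad_ms = 100, dip_db = 30) {
  structure(list(syl1_duration_ms = syl1_duration_ms,
                 syl2_duration_ms = syl2_duration_ms,
                 gap_ms = gap_ms, pad_ms = pad_ms, dip_db = dip_db),
            class = "continuum_base")
}

#' Render one continuum token
#'
#' The second syllable's duration is set so that its measured 20-dB window is
#' `duration_pct`% of the base token's, and its F0 follows a linear
#' trajectory in log2-F0 from `f0_height_hz` at the window onset to
#' `f0_height_hz * 2^f0_slope_oct` at the window offset (onset-anchored
#' height). The first syllable (dipping Tone 3 around the token's F0 height)
#' and the amplitude contour shape are identical across tokens.
#'
#' @param base A `continuum_base`.
#' @param spec One row of [build_token_grid()] (or a list with
#'   `f0_slope_oct`, `duration_pct`, `f0_height_hz`).
#' @param rate Sampling rate (default 44100).
#' @return A `tone_wave` with attribute `truth` (nominal slope, duration
#'   percent, height, predicted windows).
#' @export
render_token <- function(base, spec, rate = 44100) {
  stopifnot(inherits(base, "continuum_base"))
  slope <- spec$f0_slope_oct; pct <- spec$duration_pct; height <- spec$f0_height_hz
  if (!slope %in% continuum_slopes || !pct %in% continuum_durations) {
    warning("off-grid token spec (slope ", slope, ", duration ", pct, "%)")
  }
  d1 <- base$syl1_duration_ms

  # predicted measured window of the 100% base second syllable
  envl0 <- build_envelope_ms(d1, base$syl2_duration_ms, base$gap_ms,
                             base$pad_ms, base$dip_db, 0, 0, "tone1")
  w2_base <- predict_measured_windows(envl0)$w2
  target_w2 <- (pct / 100) * (w2_base[["offset"]] - w2_base[["onset"]])

  render_given_d2 <- function(d2) {
    envl <- build_envelope_ms(d1, d2, base$gap_ms, base$pad_ms, base$dip_db,
                              0, 0, "tone1")
    pw <- predict_measured_windows(envl)
    a1 <- pw$w1[["onset"]]; b1 <- pw$w1[["offset"]]
    a2 <- pw$w2[["onset"]]; b2 <- pw$w2[["offset"]]
    tmin <- a1 + (2 / 3) * (b1 - a1)
    lh <- log2(height)
    # linear log2-F0 ramp anchored at the predicted window (onset = height,
    # offset = height * 2^slope), extended at constant slope to the physical
    # syllable edges to avoid inward tracker bias at the window edges
    sl <- slope / (b2 - a2)                # octaves per ms
    l_t2s <- lh - sl * (a2 - envl$syl2_ms[1])
    l_t2e <- lh + slope + sl * (envl$syl2_ms[2] - b2)
    ctrl_t <- c(0, a1, tmin, b1, envl$syl2_ms[1], envl$syl2_ms[2],
                envl$total_ms)
    ctrl_l2 <- c(lh + 1 / 12, lh + 1 / 12, lh - 1.5 / 12, lh - 0.5 / 12,
                 l_t2s, l_t2e, l_t2e)

    n <- round(envl$total_ms / 1000 * rate)
    ts_ms <- (seq_len(n) - 1) / rate * 1000
    f0 <- 2^stats::approx(ctrl_t, ctrl_l2, xout = ts_ms, rule = 2)$y
    phase <- 2 * pi * cumsum(f0) / rate
    kmax <- max(3L, min(20L, floor(0.45 * rate / max(f0))))
    amps <- (1 / seq_len(kmax))^2
    harm <- numeric(n)
    for (k in seq_len(kmax)) harm <- harm + amps[k] * sin(k * phase)
    harm <- harm / sqrt(sum(amps^2) / 2)

    env_db <- stats::approx(envl$t_ms, ifelse(is.na(envl$env_db), -200,
                                              envl$env_db),
                            xout = ts_ms, rule = 2)$y
    in_pad <- ts_ms < base$pad_ms | ts_ms >= envl$total_ms - base$pad_ms
    amp <- 10^(env_db / 20) * 0.1
    amp[in_pad] <- 0
    x <- amp * harm
    if (max(abs(x)) >= 1) stop("token synthesis clipped")
    wave <- waveform(x, rate)
    attr(wave, "truth") <- list(
      f0_slope_oct = slope, duration_pct = pct, f0_height_hz = height,
      win1_ms = c(a1, b1), win2_ms = c(a2, b2),
      base_win2_len_ms = w2_base[["offset"]] - w2_base[["onset"]])
    wave
  }

  # envelope-domain calibration of the physical duration ...
  d2 <- (pct / 100) * base$syl2_duration_ms
  for (it in 1:3) {
    envl <- build_envelope_ms(d1, d2, base$gap_ms, base$pad_ms, base$dip_db,
                              0, 0, "tone1")
    pw <- predict_measured_windows(envl)
    w2 <- pw$w2[["offset"]] - pw$w2[["onset"]]
    d2 <- d2 * target_w2 / w2
  }
  # ... then an audio-domain refinement: at very low F0 the source is
  # pulse-train-like and its interplay with the steep offset decay shifts
  # the measured crossing by ~1 ms relative to the smooth-envelope
  # prediction, so the last word goes to the analyzer itself
  wave <- render_given_d2(d2)
  for (it in 1:2) {
    seg <- segment_syllables(intensity_contour(wave))
    w2_meas <- seg$win2$offset_ms - seg$win2$onset_ms
    if (abs(w2_meas - target_w2) < 0.1) break
    d2 <- d2 * target_w2 / w2_meas
    wave <- render_given_d2(d2)
  }
  wave
}

#' Equalize the RMS level of a set of tokens
#'
#' Scales every token so that the RMS over its non-silent span equals
#' `target_db` dBFS (within numerical precision); the waveform shape is not
#' otherwise changed.
#'
#' @param tokens List of `tone_wave`s.
#' @param target_db Common RMS level in dBFS (default -26).
#' @param silence_eps Samples with |x| below this are treated as silence
#'   when measuring the span (default 1e-7).
#' @return List of scaled `tone_wave`s (attributes preserved).
#' @export
equalize_rms <- function(tokens, target_db = -26, silence_eps = 1e-7) {
  stopifnot(length(tokens) >= 1L)
  lapply(tokens, function(w) {
    act <- abs(w$samples) > silence_eps
    if (!any(act)) stop("cannot RMS-equalize a silent token")
    rms <- sqrt(mean(w$samples[act]^2))
    gain <- 10^(target_db / 20) / rms
    out <- waveform(w$samples * gain, w$rate)
    attributes(out) <- utils::modifyList(attributes(w), attributes(out))
    out
  })
}

#' Measure a continuum token by round-trip acoustic analysis
#'
#' Re-analyzes a rendered token with the extraction module and returns the
#' measured second-syllable F0 slope and window duration. The slope is the
#' rate of a linear regression of log2-F0 on time over the interior voiced
#' frames (frames within 20 ms of the window edges are excluded: their
#' analysis windows overhang the syllable edge and bias the local estimate),
#' scaled by the window length to give total octaves over the syllable.
#'
#' @param wave A `tone_wave` (rendered token).
#' @param cutoff_db Window trim depth (default 20).
#' @param edge_trim_ms Interior trim for the regression (default 20).
#' @return List: slope_oct, duration_ms, onset_hz, offset_hz, windows.
#' @export
measure_token <- function(wave, cutoff_db = 20, edge_trim_ms = 20) {
  ic <- intensity_contour(wave)
  seg <- segment_syllables(ic, cutoff_db = cutoff_db)
  window_ms <- 40
  f0c <- track_f0(wave, fmin = 55, fmax = 600, window_ms = window_ms)
  idx <- voiced_f0_in_window(f0c, seg$win2)
  l <- seg$win2$offset_ms - seg$win2$onset_ms
  tt <- f0c$times_ms[idx]
  # frames whose period exceeds a third of the analysis window carry too few
  # cycles for an unbiased local estimate and are excluded from the fit
  keep <- tt >= seg$win2$onset_ms + edge_trim_ms &
    tt <= seg$win2$offset_ms - edge_trim_ms &
    f0c$values[idx] >= 3000 / window_ms
  if (sum(keep) < 5L) stop("token second syllable insufficiently voiced")
  y <- log2(f0c$values[idx[keep]]); x <- tt[keep]
  rate <- stats::cov(x, y) / stats::var(x)        # octaves per ms
  list(slope_oct = rate * l, duration_ms = l,
       onset_hz = f0c$values[idx[1L]],
       offset_hz = f0c$values[idx[length(idx)]],
       windows = seg)
}

#' Render a full continuum session
#'
#' Renders all 96 grid tokens at a common RMS, optionally writing WAVs and a
#' manifest CSV, with a seeded random presentation order.
#'
#' @param base A [continuum_base()].
#' @param session Session index.
#' @param seed Seed for the presentation order.
#' @param dir Optional output directory for WAVs + `manifest.csv`.
#' @return List: `tokens` (list of `tone_wave`), `manifest` (data frame with
#'   token parameters, rms_db, presentation order).
#' @export
render_continuum_session <- function(base = continuum_base(), session = 1,
                                     seed = 1, dir = NULL) {
  grid <- build_token_grid(session)
  tokens <- lapply(seq_len(nrow(grid)), function(i) {
    render_token(base, grid[i, ])
  })
  tokens <- equalize_rms(tokens)
  names(tokens) <- grid$token_id
  grid$rms_db <- vapply(tokens, function(w) {
    act <- abs(w$samples) > 1e-7
    10 * log10(mean(w$samples[act]^2))
  }, numeric(1))
  grid$order <- with_seed(derive_seed(seed, session, 313),
                          sample.int(nrow(grid)))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_len(nrow(grid))) {
      write_wav(tokens[[i]], file.path(dir, paste0(grid$token_id[i], ".wav")))
    }
    utils::write.csv(grid, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  list(tokens = tokens, manifest = grid)
}
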