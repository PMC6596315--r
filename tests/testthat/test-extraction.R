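test_that("intensity contour is flat for a stationary sine and scales in dB", {
  t <- seq(0, 0.5, by = 1 / 44100)
  w <- waveform(0.9 * sin(2 * pi * 220 * t))
  ic <- intensity_contour(w)
  interior <- ic$values[ic$times_ms > 50 & ic$times_ms < 450]
  expect_lt(diff(range(interior)), 0.1)

  half <- intensity_contour(waveform(0.45 * sin(2 * pi * 220 * t)))
  ih <- half$values[half$times_ms > 50 & half$times_ms < 450]
  expect_within(mean(interior) - mean(ih), 20 * log10(2), 0.02)
})

test_that("an all-zero signal yields a floored contour, not an error", {
  ic <- intensity_contour(waveform(numeric(44100)))
  expect_true(all(ic$values == -100))
})

test_that("peak detection honors the prominence schedule", {
  # two 35-dB-prominent bumps: found at the initial 20-dB requirement
  t <- seq(0, 1, length.out = 300)
  v <- -40 + 35 * exp(-((t - 0.3) / 0.08)^2) + 33 * exp(-((t - 0.7) / 0.08)^2)
  det <- detect_syllable_peaks(contour(t * 1000, v, "intensity"))
  expect_equal(det$prominence_used_db, 20)
  expect_equal(nrow(det$peaks), 2)
  expect_lt(abs(det$peaks$time_ms[1] - 300), 15)

  # bumps separated by a 15-dB dip: only found after relaxation
  v2 <- c(seq(-40, 0, length.out = 80), seq(0, -15, length.out = 60),
          seq(-15, -1, length.out = 60), seq(-1, -40, length.out = 100))
  v2 <- v2 + seq_along(v2) * 1e-6   # break ties
  det2 <- detect_syllable_peaks(contour(seq_along(v2) * 5, v2, "intensity"))
  expect_lte(det2$prominence_used_db, 15)
  expect_equal(nrow(det2$peaks), 2)

  # a single bump fails with the dedicated condition class
  v3 <- -40 + 30 * exp(-((t - 0.5) / 0.1)^2)
  expect_error(detect_syllable_peaks(contour(t * 1000, v3, "intensity")),
               class = "tonelab_segmentation_failure")
})

test_that("peak prominences equal the exhaustive oracle on random envelopes", {
  for (seed in 1:20) {
    v <- random_envelope(seed)
    got <- tonelab:::peak_prominences(v)
    ora <- oracle_prominences(v)
    expect_equal(got$index, ora$index, info = paste("seed", seed))
    expect_equal(got$prominence, ora$prominence, tolerance = 1e-10,
                 info = paste("seed", seed))
  }
})

test_that("syllable windows span the cutoff geometry exactly", {
  # triangular 40-dB peak: 20-dB cutoff selects the half-height region
  tm <- seq(0, 100, by = 5)
  v <- pmax(-40, 30 - abs(tm - 50) * 0.8) + tm * 1e-9
  ct <- contour(tm, v, "intensity")
  pk <- list(index = which.max(v), value = max(v))
  win20 <- window_syllable(ct, pk, cutoff_db = 20)
  expect_within(c(win20$onset_ms, win20$offset_ms), c(25, 75), 1e-6)

  win10 <- window_syllable(ct, pk, cutoff_db = 10)
  expect_gt(win10$onset_ms, win20$onset_ms)
  expect_lt(win10$offset_ms, win20$offset_ms)

  # cutoff unreachable before the edge: clamped and flagged
  vflat <- 10 - abs(tm - 50) * 0.1
  ctf <- contour(tm, vflat, "intensity")
  winf <- window_syllable(ctf, list(index = which.max(vflat), value = 10),
                          cutoff_db = 20)
  expect_true(any(grepl("clamped", winf$flags)))
  expect_equal(c(winf$onset_ms, winf$offset_ms), c(0, 100))
})

test_that("windows shrink monotonically as the cutoff decreases", {
  fix <- test_utterance("Tone1")
  s20 <- segment_syllables(fix$analysis$intensity, cutoff_db = 20)
  s10 <- segment_syllables(fix$analysis$intensity, cutoff_db = 10)
  for (k in c("win1", "win2")) {
    expect_gte(s10[[k]]$onset_ms, s20[[k]]$onset_ms)
    expect_lte(s10[[k]]$offset_ms, s20[[k]]$offset_ms)
  }
})

test_that("F0 tracking is accurate on tones and glides and rejects noise", {
  fs <- 44100
  t <- seq(0, 0.5, by = 1 / fs)
  w <- waveform(0.5 * sin(2 * pi * 220 * t))
  f0c <- track_f0(w)
  expect_within(median(f0c$values[f0c$voiced]), 220, 1)

  # linear log-F0 glide 220 -> 110 Hz with short holds at the endpoints
  dur <- 0.6; hold <- 0.15
  tg <- seq(0, dur + 2 * hold, by = 1 / fs)
  lf <- log2(220) - pmin(pmax((tg - hold) / dur, 0), 1)
  phase <- 2 * pi * cumsum(2^lf) / fs
  wg <- waveform(0.5 * sin(phase) + 0.15 * sin(2 * phase))
  g <- track_f0(wg)
  vi <- which(g$voiced)
  expect_within(g$values[vi[1]], 220, 2)
  # endpoint read inside the end hold (the very last frame straddles the
  # abrupt signal edge and its half-empty window is unreliable by design)
  last_in <- vi[g$times_ms[vi] <= max(g$times_ms) - 50]
  expect_within(g$values[last_in[length(last_in)]], 110, 2)

  set.seed(99)
  noise <- track_f0(waveform(0.2 * rnorm(fs / 2)))
  expect_gte(mean(!noise$voiced), 0.95)

  silent <- track_f0(waveform(numeric(fs / 4)))
  expect_false(any(silent$voiced))
})

test_that("F0 tracking is unbiased on glides (mean signed error < 0.2 st)", {
  fs <- 44100
  errs <- vapply(1:10, function(s) {
    set.seed(s)
    f1 <- runif(1, 180, 280)
    drop <- runif(1, 0.2, 0.6)
    dur <- runif(1, 0.3, 0.6)
    tg <- seq(0, dur + 0.2, by = 1 / fs)
    lf <- log2(f1) - pmin(pmax((tg - 0.1) / dur, 0), 1) * drop
    phase <- 2 * pi * cumsum(2^lf) / fs
    w <- waveform(0.4 * sin(phase) + 0.1 * sin(2 * phase))
    g <- track_f0(w)
    sel <- which(g$voiced & g$times_ms > 120 & g$times_ms < (0.08 + dur) * 1000)
    des <- log2(f1) - pmin(pmax((g$times_ms[sel] / 1000 - 0.1) / dur, 0), 1) * drop
    mean(12 * (log2(g$values[sel]) - des))
  }, numeric(1))
  expect_lt(mean(abs(errs)), 0.2)
})

test_that("vocal range estimation is a normal fit on the log axis", {
  set.seed(7)
  f <- 250 * 2^(rnorm(950, 0, 1.5 / 12))
  f <- c(f, rep(500, 50))            # 5% octave-jump outliers
  vr <- estimate_vocal_range(f)
  expect_within(12 * (vr$center_log2hz - log2(250)), 0, 1)

  vr200 <- estimate_vocal_range(rep(200, 60))
  expect_equal(vr200$center_log2hz, log2(200))
  expect_equal(vocal_range_hz(vr200), 200 * 2^c(-0.5, 0.5), tolerance = 1e-9)

  vr220 <- estimate_vocal_range(rep(220, 60))
  expect_within(vocal_range_hz(vr220), c(155.6, 311.1), 0.1)

  expect_error(estimate_vocal_range(rep(200, 10), speaker = "NH01"), "NH01")
})

test_that("refine_f0 matches the broad track when no fallback is needed", {
  fix <- test_utterance("Tone4")
  vr <- estimate_vocal_range(fix$analysis$f0$values[fix$analysis$f0$voiced])
  rc <- refine_f0(fix$wave, vr)
  dec <- attr(rc, "decisions")
  expect_false(dec$threshold_lowered)
  expect_false(dec$band_expanded)
  both <- which(rc$voiced & fix$analysis$f0$voiced)
  expect_lt(max(abs(log2(rc$values[both]) -
                      log2(fix$analysis$f0$values[both]))) * 12, 0.1)
})

test_that("refine_f0 fallbacks trigger on band saturation and breathiness", {
  prof <- make_speaker_profile("CI", 220, seed = 4)
  prof$tone1_median_rel_st <- 8           # well outside +/-6 st of center
  prof$tone1_movement_st <- 0
  w <- synthesize_utterance(utterance_spec(prof, "Tone1", jitter = FALSE))
  vr <- structure(list(center_log2hz = log2(prof$f0_center_hz),
                       center_hz = prof$f0_center_hz, sd_st = 1,
                       lower_st = -6, upper_st = 6, voicing_threshold = 0.45),
                  class = "vocal_range")
  seg <- segment_syllables(intensity_contour(w))
  rc <- refine_f0(w, vr, windows = list(seg$win1, seg$win2))
  expect_true(attr(rc, "decisions")$band_expanded)
  med <- f0_median_relative(rc, seg$win1, seg$win2)
  expect_within(med, 8, 0.5)

  wb <- synthesize_utterance(utterance_spec(prof, "Tone4", jitter = FALSE,
                                            breathiness = 0.7))
  segb <- segment_syllables(intensity_contour(wb))
  rcb <- refine_f0(wb, vr, windows = list(segb$win1, segb$win2))
  decb <- attr(rcb, "decisions")
  expect_true(decb$threshold_lowered)
  expect_equal(decb$voicing_threshold, 0.1)
  expect_gt(mean(rcb$voiced[tonelab:::frames_in_window(rcb, segb$win2)]), 0.6)
})
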