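test_that("duration ratio and intensity difference are simple window arithmetic", {
  w1 <- window_of(100, 400, peak_db = -25)   # 300 ms
  w2 <- window_of(500, 890, peak_db = -23)   # 390 ms
  expect_equal(duration_ratio(w1, w2), 1.3)
  expect_equal(duration_ratio(w1, w1), 1)
  expect_error(duration_ratio(window_of(100, 100), w2), "zero-length")
  expect_equal(intensity_peak_difference(w1, w2), 2)
  expect_equal(intensity_peak_difference(w1, w1), 0)
})

test_that("relative F0 median follows the median/mean convention", {
  hz <- c(rep(200, 40), rep(NA, 10), rep(252, 40))
  ct <- f0_contour_from(hz)
  w1 <- window_of(0, 195); w2 <- window_of(250, 445)
  expect_within(f0_median_relative(ct, w1, w2), 12 * log2(252 / 200), 1e-9)
  expect_equal(f0_median_relative(ct, w1, w1), 0)

  sparse <- f0_contour_from(c(200, rep(NA, 50), rep(210, 30)))
  out <- f0_median_relative(sparse, window_of(0, 100), window_of(260, 400))
  expect_true(is.na(out))
  expect_match(attr(out, "unavailable"), "voiced")
})

test_that("F0 movement matches direct edge-mean arithmetic and its flags", {
  lf <- seq(log2(220), log2(155.6), length.out = 101)  # -0.5 octave fall
  ct <- f0_contour_from(2^lf)
  win <- window_of(0, 500)
  expected <- 12 * (mean(tail(lf, 6)) - mean(head(lf, 6)))
  expect_within(f0_movement(ct, win), expected, 1e-9)
  expect_within(f0_movement(ct, win), -6, 0.5)   # attenuated by edge averaging

  flat <- f0_contour_from(rep(200, 101))
  expect_equal(f0_movement(flat, win), 0)

  short <- f0_contour_from(rep(200, 8))
  out <- f0_movement(short, window_of(0, 35))
  expect_true(is.na(out))
})

test_that("F0 movement is antisymmetric under time reversal", {
  for (seed in 1:10) {
    set.seed(seed)
    lf <- cumsum(rnorm(80, 0, 0.02)) + log2(200)
    ct <- f0_contour_from(2^lf)
    rev_ct <- f0_contour_from(2^rev(lf))
    win <- window_of(0, 5 * 79)
    expect_equal(f0_movement(ct, win), -f0_movement(rev_ct, win),
                 tolerance = 1e-9)
  }
})

test_that("normalized patterns have 100 points on a 0-100% axis", {
  fix <- test_utterance("Tone4")
  seg <- fix$analysis$windows
  ip <- normalize_pattern(fix$analysis$intensity, seg$win2)
  expect_length(ip$points, 100)
  expect_equal(range(ip$percent), c(0, 100))
  expect_equal(max(ip$points), 0, tolerance = 0.05)  # dB re window peak

  ref <- mean(log2(fix$analysis$f0$values[
    tonelab:::voiced_f0_in_window(fix$analysis$f0, seg$win1)]))
  fp <- normalize_pattern(fix$analysis$f0, seg$win2, ref = ref)
  expect_length(fp$points, 100)
  # Tone 4: overall falling mean pattern
  expect_lt(mean(fp$points[81:100]) - mean(fp$points[1:20]), -2)

  flat <- f0_contour_from(rep(200, 61))
  z <- normalize_pattern(flat, window_of(0, 300), ref = log2(200))
  expect_true(all(abs(z$points) < 1e-9))

  gappy <- f0_contour_from(c(rep(200, 20), rep(NA, 30), rep(200, 11)))
  g <- normalize_pattern(gappy, window_of(0, 300), ref = log2(200))
  expect_true(all(is.na(g$points)))
  expect_match(attr(g, "unavailable"), "coverage")
})

test_that("pattern aggregation averages repetitions before speakers", {
  mk <- function(vals) structure(list(kind = "f0", points = vals,
                                      percent = seq(0, 100, length.out = length(vals))),
                                 class = "normalized_pattern")
  same <- replicate(4, mk(rep(1, 10)), simplify = FALSE)
  agg <- aggregate_patterns(same)
  expect_true(all(agg$se == 0))

  pm <- aggregate_patterns(list(mk(rep(1, 10)), mk(rep(-1, 10))))
  expect_true(all(abs(pm$mean) < 1e-12))

  set.seed(11)
  mat <- matrix(rnorm(10 * 9), nrow = 10)
  speakers <- rep(c("a", "b", "c"), each = 3)
  pats <- lapply(seq_len(9), function(i) mk(mat[, i]))
  agg2 <- aggregate_patterns(pats, speakers)
  ora <- oracle_two_stage(mat, speakers)
  expect_equal(agg2$mean, ora$mean, tolerance = 1e-12)
  expect_equal(agg2$se, ora$se, tolerance = 1e-12)

  ip <- mk(rep(0, 10)); ip$kind <- "intensity"
  expect_error(aggregate_patterns(list(ip, mk(rep(0, 10)))), "kinds")
})

test_that("10-dB cutoff descriptors are qualitatively concordant with 20-dB", {
  fix <- test_cohort()
  d20 <- fix$descriptors
  d10 <- analyze_cohort(fix$cohort, cutoff_db = 10)
  contrast <- function(d, col) {
    agg <- aggregate(d[[col]] ~ d$group + d$tone, FUN = mean)
    names(agg) <- c("group", "tone", "v")
    sapply(split(agg, agg$group), function(s) {
      s$v[s$tone == "Tone1"] - s$v[s$tone == "Tone4"]
    })
  }
  for (col in c("duration_ratio", "f0_movement_st")) {
    c20 <- contrast(d20, col); c10 <- contrast(d10, col)
    # only contrasts generated to exist (the CI duration contrast, both
    # groups' movement contrasts); near-zero contrasts have no stable sign
    clear <- abs(c20) > 0.15
    expect_true(any(clear) && all(sign(c20[clear]) == sign(c10[clear])),
                info = col)
  }
})
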