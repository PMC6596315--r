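# Independent oracles, implemented naively and kept apart from the package
# code paths they check.

# Exhaustive prominence oracle: for every strict local maximum, scan outward
# on each side to the nearest strictly higher sample (or the edge), take the
# minimum over each scanned stretch, and subtract the larger of the two
# minima from the peak height.
oracle_prominences <- function(v) {
  n <- length(v)
  peaks <- integer(); proms <- numeric()
  for (i in 2:(n - 1)) {
    if (!(v[i] > v[i - 1] && v[i] > v[i + 1])) next
    left <- v[seq_len(i - 1)]
    higher <- which(left > v[i])
    lmin <- min(left[seq.int(if (length(higher)) max(higher) + 1L else 1L,
                             i - 1L)])
    right <- v[seq.int(i + 1L, n)]
    higher <- which(right > v[i])
    rmin <- min(right[seq_len(if (length(higher)) min(higher) - 1L
                              else length(right))])
    peaks <- c(peaks, i)
    proms <- c(proms, v[i] - max(lmin, rmin))
  }
  data.frame(index = peaks, prominence = proms)
}

# random smooth intensity-like envelope (dB), no ties
random_envelope <- function(seed, n = 240) {
  set.seed(seed)
  k <- sample(2:6, 1)
  t <- seq(0, 1, length.out = n)
  v <- rowSums(sapply(seq_len(k), function(i) {
    runif(1, 3, 25) * sin(2 * pi * runif(1, 0.5, 4) * t + runif(1, 0, 2 * pi))
  }))
  v + rnorm(n, 0, 0.01)
}

# naive two-stage (reps-within-speaker, then across-speaker) averaging
oracle_two_stage <- function(mat, speakers) {
  spk <- unique(speakers)
  per <- sapply(spk, function(s) rowMeans(mat[, speakers == s, drop = FALSE]))
  list(mean = rowMeans(per),
       se = apply(per, 1, sd) / sqrt(length(spk)))
}

# build an f0 contour object directly from Hz values (5-ms step)
f0_contour_from <- function(hz, step_ms = 5) {
  contour(seq(0, by = step_ms, length.out = length(hz)), hz, kind = "f0",
          step_ms = step_ms, voiced = !is.na(hz))
}

# a syllable window covering [onset, offset] ms
window_of <- function(onset, offset, peak_db = 0) {
  structure(list(onset_ms = onset, offset_ms = offset,
                 peak_time_ms = (onset + offset) / 2,
                 peak_level_db = peak_db, cutoff_db = 20, flags = character()),
            class = "syllable_window")
}
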