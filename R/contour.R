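#' Construct a contour object
#'
#' A `tone_contour` is a time-stamped series sampled at a fixed step:
#' intensity in dB full scale, or F0 in Hz with per-frame voicing flags.
#'
#' @param times_ms Frame-center times in ms (uniform step).
#' @param values Per-frame measurement (dB or Hz).
#' @param kind `"intensity"` or `"f0"`.
#' @param step_ms Frame step in ms.
#' @param voiced Logical per-frame voicing flags (F0 contours only).
#' @param strength Optional per-frame periodicity strength in \[0, 1\].
#' @return A `tone_contour`.
#' @export
contour <- function(times_ms, values, kind = c("intensity", "f0"),
                    step_ms = 5, voiced = NULL, strength = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(times_ms) == length(values))
  if (kind == "f0" && is.null(voiced)) voiced <- !is.na(values) & values > 0
  structure(list(times_ms = times_ms, values = values, kind = kind,
                 step_ms = step_ms, voiced = voiced, strength = strength),
            class = "tone_contour")
}

#' @export
print.tone_contour <- function(x, ...) {
  cat(sprintf("<tone_contour[%s]: %d frames, step %g ms, span %.0f ms>\n",
              x$kind, length(x$values), x$step_ms,
              diff(range(x$times_ms))))
  invisible(x)
}

# indices of frames whose centers fall inside [onset, offset] of a window
frames_in_window <- function(contour, window) {
  which(contour$times_ms >= window$onset_ms & contour$times_ms <= window$offset_ms)
}
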