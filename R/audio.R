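#' Construct an audio signal
#'
#' A lightweight container for single-channel audio: a numeric sample vector
#' (dimensionless amplitude, nominally in \[-1, 1\]) plus its sampling rate in
#' Hz. All analysis functions in voicemark take this object as input.
#'
#' @param samples Numeric vector of finite sample amplitudes.
#' @param rate Sampling frequency in Hz (a single positive number).
#'
#' @return An object of class `audio_signal`: a list with elements `samples`
#'   and `rate`.
#' @examples
#' x <- audio_signal(sin(2 * pi * 220 * seq(0, 0.1, by = 1 / 8000)), 8000)
#' duration(x)
#' @export
audio_signal <- function(samples, rate) {
  if (!is.numeric(samples)) {
    stop("`samples` must be a numeric vector", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("all samples must be finite", call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1 || !is.finite(rate) || rate <= 0) {
    stop("`rate` must be a single positive number (Hz)", call. = FALSE)
  }
  structure(
    list(samples = as.numeric(samples), rate = as.numeric(rate)),
    class = "audio_signal"
  )
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf(
    "<audio_signal: %d samples @ %g Hz (%.3f s)>\n",
    length(x$samples), x$rate, duration(x)
  ))
  invisible(x)
}

#' Duration of an audio signal in seconds
#'
#' @param x An `audio_signal`.
#' @return Duration in seconds.
#' @export
duration <- function(x) {
  stopifnot(inherits(x, "audio_signal"))
  length(x$samples) / x$rate
}
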