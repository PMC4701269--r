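#' Build a synthetic speech event script
#'
#' A script is a tibble of consecutive events, each `voiced` (harmonic series
#' with a linear F0 contour and optional period-level jitter), `unvoiced`
#' (white noise, emulating fricative/noise stretches) or `silence`. Scripts
#' drive [synth_render()] and carry exact ground truth.
#'
#' @param kind Character vector of event kinds (`"voiced"`, `"unvoiced"`,
#'   `"silence"`).
#' @param dur Event durations in seconds.
#' @param f0_start,f0_end Linear F0 contour endpoints in Hz (voiced events;
#'   ignored otherwise).
#' @param n_harmonics Number of harmonics of the voiced series (amplitudes
#'   decay as 1/k, sawtooth-like; harmonics above Nyquist are dropped at
#'   render time).
#' @param jitter_level Relative standard deviation of the per-period
#'   multiplicative F0 perturbation (0 = none).
#' @param amplitude Peak amplitude scale of the event.
#' @return A `synth_script` tibble, one row per event.
#' @export
synth_script <- function(kind, dur, f0_start = NA_real_, f0_end = NA_real_,
                         n_harmonics = 10L, jitter_level = 0, amplitude = 0.8) {
  kind <- match.arg(kind, c("voiced", "unvoiced", "silence"), several.ok = TRUE)
  if (any(dur <= 0)) stop("event durations must be positive", call. = FALSE)
  if (any(jitter_level < 0)) stop("`jitter_level` must be >= 0", call. = FALSE)
  tbl <- tibble::tibble(
    kind = kind, dur = dur,
    f0_start = f0_start, f0_end = f0_end,
    n_harmonics = as.integer(n_harmonics),
    jitter_level = jitter_level, amplitude = amplitude
  )
  voiced <- tbl$kind == "voiced"
  if (any(voiced & (is.na(tbl$f0_start) | is.na(tbl$f0_end)))) {
    stop("voiced events need `f0_start` and `f0_end`", call. = FALSE)
  }
  if (any(voiced & (tbl$f0_start <= 0 | tbl$f0_end <= 0))) {
    stop("voiced F0 must be positive", call. = FALSE)
  }
  structure(tbl, class = c("synth_script", class(tibble::tibble())))
}

#' A standard running-speech fixture script
#'
#' Builds a script emulating the structure of a read-speech recording:
#' repeating cycles of a voiced stretch (F0 ramping between two values drawn
#' from the adult speech range 110-320 Hz), a weaker unvoiced noise burst and
#' a silent pause, until `dur` seconds are scripted. Event lengths emulate
#' running speech at a natural syllable/pause rhythm (voiced 0.3-0.8 s,
#' noise 0.15-0.35 s, pause 0.2-0.5 s).
#'
#' @param dur Total scripted duration in seconds (default 30 s, the length
#'   of one acquisition task).
#' @param seed Integer seed controlling the drawn event durations and F0
#'   endpoints.
#' @param jitter_level Jitter injected into every voiced event (default 0).
#' @return A `synth_script` tibble.
#' @export
synth_speech_script <- function(dur = 30, seed = 1L, jitter_level = 0) {
  withr::local_seed(seed)
  kinds <- character(0)
  durs <- f0s <- f0e <- numeric(0)
  total <- 0
  while (total < dur) {
    v <- stats::runif(1, 0.3, 0.8)
    u <- stats::runif(1, 0.15, 0.35)
    s <- stats::runif(1, 0.2, 0.5)
    f_a <- stats::runif(1, 110, 320)
    f_b <- f_a * stats::runif(1, 0.85, 1.18)
    f_b <- min(max(f_b, 90), 420)
    kinds <- c(kinds, "voiced", "unvoiced", "silence")
    durs <- c(durs, v, u, s)
    f0s <- c(f0s, f_a, NA, NA)
    f0e <- c(f0e, f_b, NA, NA)
    total <- total + v + u + s
  }
  # trim the script to the requested total duration
  keep <- cumsum(durs) - durs < dur
  durs <- durs[keep]; kinds <- kinds[keep]; f0s <- f0s[keep]; f0e <- f0e[keep]
  durs[length(durs)] <- durs[length(durs)] - (sum(durs) - dur)
  synth_script(kinds, durs,
    f0_start = f0s, f0_end = f0e,
    jitter_level = ifelse(kinds == "voiced", jitter_level, 0),
    amplitude = ifelse(kinds == "unvoiced", 0.1, 0.8)
  )
}

render_voiced <- function(n, rate, f0_start, f0_end, dur,
                          n_harmonics, jitter_level, amplitude) {
  # per-period instantaneous F0: linear contour, each period multiplied by
  # (1 + eps), eps ~ N(0, jitter_level); sample i belongs to the period
  # covering its time, phase integrates the piecewise-constant F0 exactly
  f_at <- function(tt) f0_start + (f0_end - f0_start) * tt / dur
  f_sample <- numeric(n)
  tau <- 0
  i0 <- 1L
  while (i0 <= n) {
    f_i <- f_at(tau)
    if (jitter_level > 0) f_i <- f_i * (1 + stats::rnorm(1, 0, jitter_level))
    f_i <- max(f_i, 1)
    tau_next <- tau + 1 / f_i
    i1 <- min(n, ceiling(tau_next * rate))
    f_sample[i0:i1] <- f_i
    i0 <- i1 + 1L
    tau <- tau_next
  }
  phase <- cumsum(f_sample) / rate
  ks <- seq_len(n_harmonics)
  ks <- ks[ks * max(f0_start, f0_end) * (1 + 4 * jitter_level) < rate / 2]
  if (length(ks) == 0L) stop("all harmonics above Nyquist", call. = FALSE)
  x <- numeric(n)
  for (k in ks) x <- x + sin(2 * pi * k * phase) / k
  x * amplitude / sum(1 / ks)
}

#' Render a synthetic script into audio with ground truth
#'
#' Voiced events are sums of harmonics `sum_k sin(2*pi*k*phi(t))/k` whose
#' phase integrates the instantaneous F0 (the linear `f0_start` to `f0_end`
#' contour); when `jitter_level > 0` every pitch period's F0 is multiplied
#' by `1 + eps` with seeded Gaussian `eps`, injecting controlled
#' cycle-to-cycle perturbation. Unvoiced events are white Gaussian noise,
#' silence is exact zeros. Identical `(script, rate, seed)` give
#' bit-identical output.
#'
#' @param script A `synth_script` tibble.
#' @param rate Sampling rate in Hz (default 48000, the acquisition setting
#'   emulated by the generator).
#' @param seed Integer seed for jitter and noise.
#' @return A `synth_result` list: `audio` (an [audio_signal()]),
#'   `truth_segments` (tibble of the voiced event intervals),
#'   `truth_f0` (tibble of per-event linear contours) and
#'   `truth_features` (from [truth_features()]).
#' @export
synth_render <- function(script, rate = 48000, seed = 1L) {
  stopifnot(inherits(script, "synth_script"))
  fmax_needed <- suppressWarnings(max(0, script$f0_start, script$f0_end, na.rm = TRUE))
  if (is.finite(fmax_needed) && 2 * fmax_needed >= rate) {
    stop("sampling rate too low for the scripted F0 range", call. = FALSE)
  }
  withr::local_seed(seed)
  pieces <- vector("list", nrow(script))
  seg_start <- seg_end <- numeric(0)
  t_cursor <- 0
  contours <- vector("list", nrow(script))
  # event sample counts from the cumulative timeline, so the rendered total
  # is exactly round(rate * total duration) and each event is within 1 sample
  bounds <- round(cumsum(c(0, script$dur)) * rate)
  for (i in seq_len(nrow(script))) {
    ev <- script[i, ]
    n <- as.integer(bounds[i + 1L] - bounds[i])
    x <- switch(ev$kind,
      silence = numeric(n),
      unvoiced = stats::rnorm(n, 0, ev$amplitude / 3),
      voiced = render_voiced(
        n, rate, ev$f0_start, ev$f0_end, ev$dur,
        ev$n_harmonics, ev$jitter_level, ev$amplitude
      )
    )
    if (ev$kind == "voiced") {
      seg_start <- c(seg_start, t_cursor)
      seg_end <- c(seg_end, t_cursor + ev$dur)
      contours[[i]] <- tibble::tibble(
        t_start = t_cursor, t_end = t_cursor + ev$dur,
        f0_start = ev$f0_start, f0_end = ev$f0_end
      )
    }
    pieces[[i]] <- x
    t_cursor <- t_cursor + ev$dur
  }
  structure(
    list(
      audio = audio_signal(unlist(pieces), rate),
      truth_segments = new_segments(seg_start, seg_end),
      truth_f0 = dplyr::bind_rows(contours),
      truth_features = truth_features(script)
    ),
    class = "synth_result"
  )
}

#' @export
print.synth_result <- function(x, ...) {
  cat(sprintf(
    "<synth_result: %.2f s audio @ %g Hz, %d voiced segments>\n",
    duration(x$audio), x$audio$rate, nrow(x$truth_segments)
  ))
  invisible(x)
}

#' Expected per-voiced-event features of a script
#'
#' The expected mean F0 of a voiced event is the time average of its linear
#' contour, `(f0_start + f0_end) / 2`. The expected jitter is reported as
#' the injected `jitter_level` itself: the local-jitter statistic measured
#' downstream recovers the injected relative period perturbation up to
#' tracker smoothing, so comparisons against this column should use a
#' tolerance band rather than equality.
#'
#' @param script A `synth_script` tibble.
#' @return A tibble with one row per voiced event: `event`, `mean_f0`,
#'   `jitter`.
#' @export
truth_features <- function(script) {
  voiced <- which(script$kind == "voiced")
  tibble::tibble(
    event = voiced,
    mean_f0 = (script$f0_start[voiced] + script$f0_end[voiced]) / 2,
    jitter = script$jitter_level[voiced]
  )
}

#' Generate a synthetic longitudinal session cohort
#'
#' Emulates a monitoring case study: `n_sessions` recording sessions, each
#' with a clinician assessment (QIDS/YMRS scores drawn consistently with a
#' scripted mood state) and a per-session feature summary in which the MAD
#' of mean F0 follows a monotone link with the ordinal mood state
#' (hypomania < euthymia < depression) plus session noise. Other summary
#' statistics are drawn without any mood link.
#'
#' Defaults mirror the case-study composition: 15 sessions with 2
#' depressive, 4 hypomanic and 9 euthymic assessments. The link slope (4 Hz
#' of MAD_meanF0 per ordinal step) against 2.5 Hz of session noise encodes
#' a within-patient effect clearly larger than session-to-session
#' variability.
#'
#' @param n_sessions Number of sessions (default 15).
#' @param n_depressive,n_hypomanic Sessions in each symptomatic state
#'   (defaults 2 and 4; the remainder is euthymic).
#' @param mad_base Baseline MAD of mean F0 in Hz (default 12).
#' @param mad_slope Increase of MAD_meanF0 per ordinal step in Hz
#'   (default 4).
#' @param noise_sd Session noise of MAD_meanF0 in Hz (default 2.5).
#' @param seed Integer seed.
#' @return A list with `assessments` (session_id, date, qid, ymrs) and
#'   `summaries` (long per-session summaries as consumed by
#'   [longitudinal_report()]).
#' @export
synth_cohort <- function(n_sessions = 15, n_depressive = 2, n_hypomanic = 4,
                         mad_base = 12, mad_slope = 4, noise_sd = 2.5,
                         seed = 1L) {
  if (n_depressive + n_hypomanic > n_sessions) {
    stop("state counts exceed `n_sessions`", call. = FALSE)
  }
  withr::local_seed(seed)
  states <- sample(c(
    rep("depressive", n_depressive),
    rep("hypomanic", n_hypomanic),
    rep("euthymic", n_sessions - n_depressive - n_hypomanic)
  ))
  qid <- ifelse(states == "depressive",
    sample(8:15, n_sessions, replace = TRUE),
    sample(0:7, n_sessions, replace = TRUE)
  )
  ymrs <- ifelse(states == "hypomanic",
    sample(6:12, n_sessions, replace = TRUE),
    sample(0:5, n_sessions, replace = TRUE)
  )
  ordinal <- mood_ordinal(states)
  assessments <- tibble::tibble(
    session_id = seq_len(n_sessions),
    date = as.Date("2024-01-01") + 7 * (seq_len(n_sessions) - 1),
    qid = as.integer(qid), ymrs = as.integer(ymrs)
  )
  mk_stat <- function(mu, sd) stats::rnorm(n_sessions, mu, sd)
  summaries <- dplyr::bind_rows(
    tibble::tibble(
      session_id = seq_len(n_sessions), feature = "mean_f0",
      median = mk_stat(190, 6),
      mad = pmax(0.5, mad_base + mad_slope * ordinal + stats::rnorm(n_sessions, 0, noise_sd)),
      skewness = mk_stat(0.2, 0.3)
    ),
    tibble::tibble(
      session_id = seq_len(n_sessions), feature = "std_f0",
      median = pmax(0.5, mk_stat(8, 2)),
      mad = pmax(0.2, mk_stat(4, 1)),
      skewness = mk_stat(0.5, 0.4)
    ),
    tibble::tibble(
      session_id = seq_len(n_sessions), feature = "jitter",
      median = pmax(1e-4, mk_stat(0.01, 0.003)),
      mad = pmax(5e-5, mk_stat(0.004, 0.001)),
      skewness = mk_stat(0.8, 0.5)
    )
  )
  list(assessments = assessments, summaries = summaries)
}
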