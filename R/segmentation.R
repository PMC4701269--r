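new_segments <- function(start, end, first_frame = NA_integer_,
                         last_frame = NA_integer_) {
  tibble::tibble(
    segment_id = seq_along(start),
    start = start, end = end,
    first_frame = first_frame, last_frame = last_frame
  )
}

# maximal runs of TRUE in a logical frame labelling -> segment table.
# Frame i (1-based) is centred at (i-1)*hop; a segment spans the centred
# frame intervals, i.e. [t_first - hop/2, t_last + hop/2], clamped to the
# recording. Runs shorter than min_segment are dropped.
runs_to_segments <- function(voiced, hop, min_segment, t0 = 0) {
  r <- rle(voiced)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (length(keep) == 0L) return(new_segments(numeric(0), numeric(0)))
  first <- starts[keep]
  last <- ends[keep]
  seg_start <- pmax(0, t0 + (first - 1L) * hop - hop / 2)
  seg_end <- t0 + (last - 1L) * hop + hop / 2
  len_ok <- (seg_end - seg_start) >= min_segment - 1e-9
  new_segments(seg_start[len_ok], seg_end[len_ok], first[len_ok], last[len_ok])
}

#' Detect voiced segments by pitch-strength thresholding
#'
#' Labels a frame voiced when its pitch strength is strictly greater than the
#' threshold, merges maximal runs of voiced frames into segments, and drops
#' segments shorter than `min_segment`. Segment boundaries extend half a hop
#' beyond the first and last frame centre (frames represent centred
#' intervals), so a run of n frames has length `n * hop`.
#'
#' @param track A `pitch_track` from [estimate_pitch()] or [read_track()].
#' @param threshold Pitch-strength threshold in \[-1, 1\]. Frames must exceed
#'   it strictly to count as voiced.
#' @param min_segment Minimum segment length in seconds (default 0.02 s = two
#'   frames at the default hop, the shortest span on which F0 variability
#'   features exist).
#' @return A tibble of disjoint, sorted segments with columns `segment_id`,
#'   `start`, `end` (seconds) and `first_frame`, `last_frame` (1-based frame
#'   indices into the track).
#' @examples
#' trk <- voicemark:::new_pitch_track(
#'   tibble::tibble(
#'     time = (0:3) / 100,
#'     f0 = c(NA, 200, 210, NA),
#'     strength = c(0.1, 0.5, 0.6, 0.2)
#'   ),
#'   rate = 48000, hop = 0.01
#' )
#' segment_by_strength(trk, threshold = 0.4, min_segment = 0)
#' @export
segment_by_strength <- function(track, threshold = 0.3, min_segment = 0.02) {
  if (nrow(track) == 0L) stop("track is empty", call. = FALSE)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
    threshold < -1 || threshold > 1) {
    stop("`threshold` must be a single value in [-1, 1]", call. = FALSE)
  }
  if (min_segment < 0) stop("`min_segment` must be >= 0", call. = FALSE)
  runs_to_segments(track$strength > threshold, track_hop(track), min_segment)
}

#' Detect voiced segments by short-time intensity and zero-crossing rate
#'
#' The reference (ground-truth style) voicing detector: audio is cut into
#' overlapping frames of length `frame` hopped by `hop`; a frame is voiced
#' when its RMS energy exceeds the `energy_quantile` quantile of all frame
#' energies (strictly) and its zero-crossing rate is below `zcr_threshold`.
#' Voiced runs become segments exactly as in [segment_by_strength()].
#'
#' Voiced speech concentrates energy at low frequencies (ZCR of a few hundred
#' crossings per second), while fricatives and wide-band noise cross zero
#' thousands of times per second, so the two short-time statistics together
#' separate voiced speech from both silence and noise.
#'
#' @param audio An [audio_signal()].
#' @param frame Analysis frame length in seconds (default 0.03 s).
#' @param hop Frame hop in seconds (default 0.01 s).
#' @param energy_quantile Energy threshold quantile in (0, 1) (default 0.5).
#' @param zcr_threshold Maximum zero-crossing rate for a voiced frame, in
#'   crossings per second (default 3000).
#' @param min_segment Minimum segment length in seconds (default 0.02).
#' @return A tibble of segments as in [segment_by_strength()].
#' @export
segment_by_intensity_zcr <- function(audio, frame = 0.03, hop = 0.01,
                                     energy_quantile = 0.5,
                                     zcr_threshold = 3000,
                                     min_segment = 0.02) {
  stopifnot(inherits(audio, "audio_signal"))
  if (!(energy_quantile > 0 && energy_quantile < 1)) {
    stop("`energy_quantile` must be in (0, 1)", call. = FALSE)
  }
  x <- audio$samples
  fs <- audio$rate
  if (length(x) <= frame * fs) stop("audio shorter than one frame", call. = FALSE)
  n_frames <- max(1L, as.integer(floor(length(x) / fs / hop + 1e-9)))
  half <- as.integer(round(frame * fs / 2))
  centers <- as.integer(round((seq_len(n_frames) - 1L) * hop * fs))
  lo <- pmax(0L, centers - half)
  hi <- pmin(length(x), centers + half)

  csum2 <- cumsum(c(0, x^2))
  energy <- sqrt((csum2[hi + 1L] - csum2[lo + 1L]) / pmax(1L, hi - lo))
  sgn_change <- c(0, abs(diff(sign(x))) > 0)
  csum_z <- cumsum(c(0, sgn_change))
  zcr <- (csum_z[hi + 1L] - csum_z[lo + 1L]) / pmax(1L, hi - lo) * fs

  voiced <- energy > stats::quantile(energy, energy_quantile, names = FALSE) &
    zcr < zcr_threshold
  runs_to_segments(voiced, hop, min_segment)
}

#' Sweep the pitch-strength threshold against a reference segmentation
#'
#' For each candidate threshold, segments the track with
#' [segment_by_strength()] and scores the result against a reference
#' segmentation at frame level via [frame_confusion()], yielding the
#' specificity/sensitivity operating curve of the voicing detector.
#'
#' @param track A `pitch_track`.
#' @param reference Reference segment tibble (truth), e.g. from
#'   [segment_by_intensity_zcr()] or synthetic ground truth.
#' @param thresholds Numeric vector of thresholds to evaluate.
#' @param min_segment Passed to [segment_by_strength()].
#' @param grid_step Rasterisation step in seconds for the frame-level
#'   confusion (default 0.001 s).
#' @return A `threshold_curve` tibble with columns `threshold`,
#'   `sensitivity`, `specificity`.
#' @seealso [choose_threshold()], [autoplot.threshold_curve()]
#' @export
sweep_threshold <- function(track, reference, thresholds,
                            min_segment = 0.02, grid_step = 0.001) {
  if (length(thresholds) == 0L) stop("`thresholds` is empty", call. = FALSE)
  if (is.null(reference) || nrow(reference) == 0L) {
    stop("`reference` must contain at least one segment", call. = FALSE)
  }
  dur <- track_duration(track)
  rows <- purrr::map(thresholds, function(th) {
    seg <- segment_by_strength(track, threshold = th, min_segment = min_segment)
    conf <- frame_confusion(seg, reference, duration = dur, grid_step = grid_step)
    tibble::tibble(
      threshold = th,
      sensitivity = conf$sensitivity,
      specificity = conf$specificity
    )
  })
  structure(
    dplyr::arrange(dplyr::bind_rows(rows), .data$threshold),
    class = c("threshold_curve", class(tibble::tibble()))
  )
}

#' Choose an operating threshold from a specificity/sensitivity curve
#'
#' Restricts the curve to thresholds with specificity strictly above
#' `min_spec` and sensitivity strictly above `min_sens` (specificity is
#' favoured: a missed voiced frame is considered less harmful than analysing
#' an unvoiced one), then returns the admissible threshold with maximal
#' sensitivity, breaking ties towards the smallest threshold.
#'
#' @param curve A `threshold_curve` from [sweep_threshold()].
#' @param min_spec Minimum specificity (default 0.9).
#' @param min_sens Minimum sensitivity (default 0.6).
#' @return The chosen threshold (numeric scalar) with the achieved
#'   `sensitivity` and `specificity` attached as attributes.
#' @export
choose_threshold <- function(curve, min_spec = 0.9, min_sens = 0.6) {
  if (nrow(curve) == 0L) stop("`curve` is empty", call. = FALSE)
  ok <- dplyr::filter(
    tibble::as_tibble(curve),
    .data$specificity > min_spec, .data$sensitivity > min_sens
  )
  if (nrow(ok) == 0L) {
    stop("no admissible threshold: no point has specificity > ", min_spec,
      " and sensitivity > ", min_sens,
      call. = FALSE
    )
  }
  best <- dplyr::slice_min(
    dplyr::slice_max(ok, .data$sensitivity, with_ties = TRUE),
    .data$threshold,
    with_ties = FALSE
  )
  structure(best$threshold,
    sensitivity = best$sensitivity,
    specificity = best$specificity
  )
}
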