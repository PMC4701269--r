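moment_skewness <- function(x) {
  n <- length(x)
  if (n < 3) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NA_real_)
  mean((x - m)^3) / m2^1.5
}

# unscaled median absolute deviation (descriptive, no 1.4826 factor)
mad_raw <- function(x) stats::median(abs(x - stats::median(x)))

# f0 values of track frames whose centres fall inside [start, end]
frames_in_interval <- function(track, start, end) {
  track$f0[track$time >= start - 1e-9 & track$time <= end + 1e-9]
}

feature_vector <- function(f0) {
  f0 <- f0[!is.na(f0)]
  n <- length(f0)
  if (n < 1) {
    return(c(mean_f0 = NA_real_, std_f0 = NA_real_, jitter = NA_real_, n_frames = 0))
  }
  periods <- 1 / f0
  c(
    mean_f0 = mean(f0),
    std_f0 = if (n >= 2) stats::sd(f0) else NA_real_,
    jitter = if (n >= 2) mean(abs(diff(periods))) / mean(periods) else NA_real_,
    n_frames = n
  )
}

#' Per-segment prosodic features
#'
#' For each voiced segment, computes from the F0 track:
#' * `mean_f0` — arithmetic mean of the frame F0 values (Hz);
#' * `std_f0` — sample standard deviation of frame F0 (Hz, n-1 denominator);
#' * `jitter` — local relative jitter over the frame-wise pitch periods
#'   `T(i) = 1/f0(i)`: `mean(|T(i+1) - T(i)|) / mean(T(i))`, a dimensionless
#'   fraction measuring cycle-to-cycle period perturbation.
#'
#' `std_f0` and `jitter` need at least two frames and are `NA` otherwise.
#' Frames are attributed to a segment when their centres fall inside it.
#'
#' @param track A `pitch_track`.
#' @param segments Segment tibble from [segment_by_strength()],
#'   [segment_by_intensity_zcr()] or synthetic truth; any tibble with
#'   `start`/`end` columns works.
#' @return A tibble with one row per segment: `segment_id`, `start`, `end`,
#'   `n_frames`, `mean_f0`, `std_f0`, `jitter`. Segments containing no
#'   usable (non-missing) F0 frame are dropped.
#' @export
segment_features <- function(track, segments) {
  if (nrow(segments) == 0L) {
    return(tibble::tibble(
      segment_id = integer(0), start = numeric(0), end = numeric(0),
      n_frames = integer(0), mean_f0 = numeric(0), std_f0 = numeric(0),
      jitter = numeric(0)
    ))
  }
  ids <- if ("segment_id" %in% names(segments)) segments$segment_id else seq_len(nrow(segments))
  rows <- purrr::pmap(
    list(ids, segments$start, segments$end),
    function(id, s, e) {
      fv <- feature_vector(frames_in_interval(track, s, e))
      tibble::tibble(
        segment_id = id, start = s, end = e,
        n_frames = as.integer(fv[["n_frames"]]),
        mean_f0 = fv[["mean_f0"]], std_f0 = fv[["std_f0"]],
        jitter = fv[["jitter"]]
      )
    }
  )
  dplyr::filter(dplyr::bind_rows(rows), .data$n_frames >= 1L)
}

#' Cross-segment summary statistics of prosodic features
#'
#' Summarises the distribution of each per-segment feature across all voiced
#' segments of a recording with robust statistics: the median, the unscaled
#' median absolute deviation (MAD, same units as the feature) and the moment
#' coefficient of skewness `g1 = m3 / m2^1.5` (dimensionless; `NA` below
#' three values). These per-recording summaries are the quantities followed
#' longitudinally across sessions.
#'
#' @param features Per-segment feature tibble from [segment_features()].
#' @return A `feature_summary` tibble in long form: one row per feature
#'   (`mean_f0`, `std_f0`, `jitter`) with columns `median`, `mad`,
#'   `skewness`, `n_segments`. `NA` feature values (e.g. jitter of
#'   single-frame segments) are excluded per feature.
#' @export
summarize_features <- function(features) {
  if (nrow(features) == 0L) stop("no segments to summarise", call. = FALSE)
  long <- tidyr::pivot_longer(
    dplyr::select(features, "segment_id", "mean_f0", "std_f0", "jitter"),
    cols = c("mean_f0", "std_f0", "jitter"),
    names_to = "feature", values_to = "value"
  )
  out <- long |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(
      median = stats::median(.data$value),
      mad = mad_raw(.data$value),
      skewness = moment_skewness(.data$value),
      n_segments = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$feature, c("mean_f0", "std_f0", "jitter")))
  structure(out, class = c("feature_summary", class(tibble::tibble())))
}
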