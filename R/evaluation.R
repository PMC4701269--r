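in_any_segment <- function(t, segments) {
  if (nrow(segments) == 0L) return(rep(FALSE, length(t)))
  out <- rep(FALSE, length(t))
  for (i in seq_len(nrow(segments))) {
    out <- out | (t >= segments$start[i] & t < segments$end[i])
  }
  out
}

#' Frame-level confusion between two segmentations
#'
#' Rasterises both segment lists onto a common grid of
#' `ceil(duration / grid_step)` cells (a cell counts as voiced when its
#' centre lies inside a segment, half-open on the right) and counts
#' agreement with the reference taken as truth. Sensitivity is the fraction
#' of reference-voiced cells detected voiced; specificity the fraction of
#' reference-unvoiced cells detected unvoiced. The default 1-ms grid is
#' finer than any analysis hop, so boundary rounding cannot dominate the
#' counts when chains with different hops are compared.
#'
#' @param test Segment tibble under evaluation.
#' @param reference Segment tibble taken as ground truth.
#' @param duration Total recording duration in seconds.
#' @param grid_step Rasterisation step in seconds (default 0.001).
#' @return A one-row `frame_confusion` tibble: `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `grid_step`.
#' @export
frame_confusion <- function(test, reference, duration, grid_step = 0.001) {
  if (duration <= 0) stop("`duration` must be positive", call. = FALSE)
  if (grid_step <= 0) stop("`grid_step` must be positive", call. = FALSE)
  n_cells <- as.integer(ceiling(duration / grid_step - 1e-9))
  centers <- (seq_len(n_cells) - 0.5) * grid_step
  ref_v <- in_any_segment(centers, reference)
  test_v <- in_any_segment(centers, test)
  tp <- sum(test_v & ref_v)
  fp <- sum(test_v & !ref_v)
  tn <- sum(!test_v & !ref_v)
  fn <- sum(!test_v & ref_v)
  structure(
    tibble::tibble(
      tp = tp, fp = fp, tn = tn, fn = fn,
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      grid_step = grid_step
    ),
    class = c("frame_confusion", class(tibble::tibble()))
  )
}

#' Match segments of two chains by temporal overlap
#'
#' Pairs each reference segment with the test segment it overlaps most,
#' greedily by descending overlap so that every test segment is used at most
#' once, and keeps pairs whose overlap reaches `min_overlap`. The recorded
#' interval is the intersection of the two segments — downstream feature
#' agreement is computed on these overlapping portions only.
#'
#' @param test,reference Sorted, disjoint segment tibbles.
#' @param min_overlap Minimum overlap in seconds for a valid pair (default
#'   0.02 s, two frames at the default hop, the minimum span on which
#'   variability features exist).
#' @return A tibble with one row per matched pair: `ref_id`, `test_id`,
#'   `overlap_start`, `overlap_end`, `overlap`.
#' @export
match_segments <- function(test, reference, min_overlap = 0.02) {
  empty <- tibble::tibble(
    ref_id = integer(0), test_id = integer(0),
    overlap_start = numeric(0), overlap_end = numeric(0), overlap = numeric(0)
  )
  if (nrow(test) == 0L || nrow(reference) == 0L) return(empty)
  cand <- tidyr::expand_grid(
    r = seq_len(nrow(reference)), s = seq_len(nrow(test))
  ) |>
    dplyr::mutate(
      overlap_start = pmax(reference$start[.data$r], test$start[.data$s]),
      overlap_end = pmin(reference$end[.data$r], test$end[.data$s]),
      overlap = .data$overlap_end - .data$overlap_start
    ) |>
    dplyr::filter(.data$overlap >= min_overlap - 1e-12) |>
    dplyr::arrange(dplyr::desc(.data$overlap))
  if (nrow(cand) == 0L) return(empty)
  used_r <- logical(nrow(reference))
  used_s <- logical(nrow(test))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- cand$r[i]; s <- cand$s[i]
    if (!used_r[r] && !used_s[s]) {
      keep[i] <- TRUE
      used_r[r] <- TRUE
      used_s[s] <- TRUE
    }
  }
  cand[keep, ] |>
    dplyr::transmute(
      ref_id = .data$r, test_id = .data$s,
      overlap_start = .data$overlap_start, overlap_end = .data$overlap_end,
      overlap = .data$overlap
    ) |>
    dplyr::arrange(.data$ref_id)
}

#' Feature agreement between two chains on matched segment overlaps
#'
#' For every matched pair, recomputes the requested features on the overlap
#' interval from both F0 tracks (frames whose centres fall inside the
#' intersection) and correlates the two resulting vectors across pairs with
#' Pearson's r; the two-sided p-value comes from the t distribution with
#' n - 2 degrees of freedom. Pairs where a feature is undefined in either
#' track (fewer than the required frames) are dropped for that feature.
#'
#' @param pairs Matched pairs from [match_segments()].
#' @param track_test,track_ref The two `pitch_track`s being compared.
#' @param features Character vector of features to correlate (subset of
#'   `"mean_f0"`, `"std_f0"`, `"jitter"`).
#' @return An `agreement_report` tibble: one row per feature with `rho`,
#'   `p_value`, `n` (number of usable pairs).
#' @export
correlate_matched <- function(pairs, track_test, track_ref,
                              features = c("mean_f0", "std_f0", "jitter")) {
  features <- match.arg(features, several.ok = TRUE)
  if (nrow(pairs) < 3L) {
    stop("need at least 3 matched pairs to correlate", call. = FALSE)
  }
  per_pair <- purrr::map2(
    pairs$overlap_start, pairs$overlap_end,
    function(s, e) {
      list(
        test = feature_vector(frames_in_interval(track_test, s, e)),
        ref = feature_vector(frames_in_interval(track_ref, s, e))
      )
    }
  )
  rows <- purrr::map(features, function(feat) {
    x <- purrr::map_dbl(per_pair, ~ .x$ref[[feat]])
    y <- purrr::map_dbl(per_pair, ~ .x$test[[feat]])
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3L) {
      stop("fewer than 3 pairs carry a defined `", feat, "`", call. = FALSE)
    }
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      stop("correlation undefined: zero variance in `", feat, "`", call. = FALSE)
    }
    ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
    tibble::tibble(
      feature = feat,
      rho = unname(ct$estimate),
      p_value = ct$p.value,
      n = length(x)
    )
  })
  structure(
    dplyr::bind_rows(rows),
    class = c("agreement_report", class(tibble::tibble()))
  )
}

ecdf_sup_diff <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  fa <- stats::ecdf(a)(pts)
  fb <- stats::ecdf(b)(pts)
  max(abs(fa - fb))
}

# survival function of the Kolmogorov distribution: P(K > t)
kolmogorov_sf <- function(t) {
  if (t <= 0) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  min(max(p, 0), 1)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Compares two feature distributions via the KS statistic
#' `D = sup_x |ECDF_a(x) - ECDF_b(x)|`. For small samples
#' (`n_a + n_b <= 12`) the p-value is exact, computed by enumerating all
#' `choose(n_a + n_b, n_a)` reassignments of the pooled values (valid under
#' ties); otherwise it uses the asymptotic Kolmogorov distribution with
#' effective size `n_a * n_b / (n_a + n_b)`.
#'
#' @param a,b Numeric samples (non-empty).
#' @return A one-row `ks_compare` tibble: `statistic` (D), `p_value`,
#'   `n_a`, `n_b`, `method` (`"exact"` or `"asymptotic"`).
#' @export
ks_compare <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  if (anyNA(a) || anyNA(b)) stop("samples must not contain NA", call. = FALSE)
  na <- length(a); nb <- length(b)
  d_obs <- ecdf_sup_diff(a, b)
  if (na + nb <= 12L) {
    pooled <- c(a, b)
    splits <- utils::combn(na + nb, na)
    d_all <- apply(splits, 2, function(idx) {
      ecdf_sup_diff(pooled[idx], pooled[-idx])
    })
    p <- mean(d_all >= d_obs - 1e-12)
    method <- "exact"
  } else {
    n_eff <- na * nb / (na + nb)
    p <- kolmogorov_sf(sqrt(n_eff) * d_obs)
    method <- "asymptotic"
  }
  structure(
    tibble::tibble(
      statistic = d_obs, p_value = p, n_a = na, n_b = nb, method = method
    ),
    class = c("ks_compare", class(tibble::tibble()))
  )
}
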