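test_that("strength thresholding follows the run-length rule with half-hop bounds", {
  trk <- make_track(c(0.1, 0.5, 0.6, 0.2))
  seg <- segment_by_strength(trk, threshold = 0.4, min_segment = 0)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$start, 0.005)
  expect_equal(seg$end, 0.025)
  expect_equal(seg$first_frame, 2L)
  expect_equal(seg$last_frame, 3L)

  # nothing exceeds the threshold strictly
  seg2 <- segment_by_strength(make_track(rep(0.44, 8)), threshold = 0.45)
  expect_equal(nrow(seg2), 0)
  # equality does not count as exceeding either
  seg2b <- segment_by_strength(make_track(rep(0.45, 8)), threshold = 0.45)
  expect_equal(nrow(seg2b), 0)

  # an interior run of 10 frames spans exactly 10 hops
  seg3 <- segment_by_strength(make_track(c(0.1, rep(0.5, 10), 0.1)), threshold = 0.3)
  expect_equal(nrow(seg3), 1)
  expect_equal(seg3$end - seg3$start, 0.100, tolerance = 1e-9)
  # a run starting at frame 0 is clamped to the recording start
  seg3e <- segment_by_strength(make_track(rep(0.5, 10)), threshold = 0.3)
  expect_equal(seg3e$start, 0)
  expect_equal(seg3e$end - seg3e$start, 0.095, tolerance = 1e-9)
})

test_that("segments shorter than min_segment are discarded, boundaries clamped", {
  trk <- make_track(c(0.9, 0.1, 0.9, 0.9, 0.9, 0.1))
  seg <- segment_by_strength(trk, threshold = 0.5, min_segment = 0.02)
  # the lone first frame (0.01 s) is dropped, the 3-frame run kept
  expect_equal(nrow(seg), 1)
  expect_equal(seg$first_frame, 3L)
  # a leading voiced frame clamps at time 0
  seg_all <- segment_by_strength(trk, threshold = 0.5, min_segment = 0)
  expect_equal(seg_all$start[1], 0)
})

test_that("intensity/ZCR detection finds harmonic stretches, rejects noise and silence", {
  rate <- 16000
  tone <- make_tone(200, dur = 0.5, rate = rate)
  clip <- audio_signal(c(tone$samples, numeric(rate / 2)), rate)
  seg <- segment_by_intensity_zcr(clip)
  expect_gt(nrow(seg), 0)
  voiced_cover <- sum(pmin(seg$end, 0.5) - pmin(seg$start, 0.5))
  silence_cover <- sum(pmax(seg$end, 0.5) - pmax(seg$start, 0.5))
  expect_gte(voiced_cover, 0.9 * 0.5)
  expect_lt(silence_cover, 0.05 * 0.5)

  noise <- audio_signal(withr::with_seed(5, rnorm(rate, 0, 0.3)), rate)
  expect_equal(nrow(segment_by_intensity_zcr(noise)), 0)
  expect_equal(nrow(segment_by_intensity_zcr(audio_signal(numeric(rate), rate))), 0)
})

test_that("threshold sweep hits the trivial extremes and is monotone", {
  strengths <- withr::with_seed(3, runif(200, -0.2, 0.9))
  trk <- make_track(strengths)
  ref <- make_segments(c(0.2, 1.1), c(0.8, 1.6))
  curve <- sweep_threshold(trk, ref, thresholds = c(-1, seq(0, 0.8, by = 0.1), 1))
  expect_equal(curve$sensitivity[curve$threshold == -1], 1)
  expect_equal(curve$specificity[curve$threshold == 1], 1)
  # superlevel sets are nested: sens non-increasing, spec non-decreasing
  expect_true(all(diff(curve$sensitivity) <= 1e-12))
  expect_true(all(diff(curve$specificity) >= -1e-12))
  expect_error(sweep_threshold(trk, ref[0, ], thresholds = 0.3), "reference")
  expect_error(sweep_threshold(trk, ref, thresholds = numeric(0)), "empty")
})

test_that("lowering the threshold never removes a voiced frame", {
  strengths <- withr::with_seed(9, runif(150, -0.5, 1))
  trk <- make_track(strengths)
  thresholds <- sort(runif(10, -0.5, 0.9))
  prev <- NULL
  for (th in rev(thresholds)) {
    seg <- segment_by_strength(trk, threshold = th, min_segment = 0)
    frames <- unlist(purrr::map2(seg$first_frame, seg$last_frame, seq))
    if (!is.null(prev)) expect_true(all(prev %in% frames))
    prev <- frames
  }
})

test_that("choose_threshold applies the specificity/sensitivity criterion", {
  curve <- structure(
    tibble::tibble(
      threshold = c(0.2, 0.3, 0.4),
      specificity = c(0.80, 0.92, 0.97),
      sensitivity = c(0.9, 0.7, 0.5)
    ),
    class = c("threshold_curve", class(tibble::tibble()))
  )
  chosen <- choose_threshold(curve)
  expect_equal(as.numeric(chosen), 0.3)
  expect_equal(attr(chosen, "sensitivity"), 0.7)

  # no admissible point
  low_spec <- dplyr::mutate(curve, specificity = specificity - 0.2)
  expect_error(choose_threshold(low_spec), "no admissible threshold")

  # sensitivity tie resolved towards the smaller threshold
  tie <- dplyr::mutate(curve, specificity = 0.95, sensitivity = c(0.7, 0.7, 0.5))
  expect_equal(as.numeric(choose_threshold(tie)), 0.2)
})

test_that("both detectors return disjoint sorted segments within the recording", {
  res <- synth_render(synth_speech_script(dur = 4, seed = 21), rate = 16000, seed = 21)
  trk <- estimate_pitch(res$audio)
  for (seg in list(
    segment_by_strength(trk, threshold = 0.2),
    segment_by_intensity_zcr(res$audio)
  )) {
    expect_true(all(seg$end > seg$start))
    expect_true(all(seg$start >= 0))
    expect_true(all(seg$end <= duration(res$audio) + 1e-9))
    if (nrow(seg) > 1) expect_true(all(diff(seg$start) > 0))
    if (nrow(seg) > 1) expect_true(all(seg$start[-1] >= seg$end[-nrow(seg)]))
  }
})
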