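test_that("frame confusion counts match hand rasterisation", {
  # 10 cells of 1 s; reference voiced cells {2..5}, test voiced {3..6} (0-based)
  ref <- make_segments(2, 6)
  test <- make_segments(3, 7)
  conf <- frame_confusion(test, ref, duration = 10, grid_step = 1)
  expect_equal(conf$tp, 3)
  expect_equal(conf$fn, 1)
  expect_equal(conf$fp, 1)
  expect_equal(conf$tn, 5)
  expect_equal(conf$sensitivity, 0.75)
  expect_equal(conf$specificity, 5 / 6, tolerance = 1e-4)

  # identity and empty-test degenerate cases
  conf_id <- frame_confusion(ref, ref, duration = 10, grid_step = 0.01)
  expect_equal(conf_id$sensitivity, 1)
  expect_equal(conf_id$specificity, 1)
  conf_none <- frame_confusion(ref[0, ], ref, duration = 10, grid_step = 0.01)
  expect_equal(conf_none$sensitivity, 0)
  expect_equal(conf_none$specificity, 1)
})

test_that("confusion cells are conserved and roles swap symmetrically", {
  ref <- make_segments(c(0.5, 3.0), c(1.5, 4.2))
  test <- make_segments(c(0.8, 2.8), c(1.9, 3.9))
  a <- frame_confusion(test, ref, duration = 5, grid_step = 0.001)
  expect_equal(a$tp + a$fp + a$tn + a$fn, ceiling(5 / 0.001))
  b <- frame_confusion(ref, test, duration = 5, grid_step = 0.001)
  expect_equal(a$tp, b$tp)
  expect_equal(a$tn, b$tn)
  expect_equal(a$fp, b$fn)
  expect_equal(a$fn, b$fp)
})

test_that("segment matching is greedy by overlap and one-to-one", {
  ref <- make_segments(c(0.0, 1.0, 2.0), c(0.5, 1.5, 2.5))
  pairs_id <- match_segments(ref, ref)
  expect_equal(nrow(pairs_id), 3)
  expect_equal(pairs_id$overlap, c(0.5, 0.5, 0.5))

  test <- make_segments(0.05, 0.2)
  p <- match_segments(test, make_segments(0.0, 0.1), min_overlap = 0.02)
  expect_equal(nrow(p), 1)
  expect_equal(p$overlap_start, 0.05)
  expect_equal(p$overlap_end, 0.1)

  expect_equal(nrow(match_segments(
    make_segments(0.2, 0.3), make_segments(0.0, 0.1)
  )), 0)

  # one long test segment overlapping two reference segments is used once
  long_test <- make_segments(0.0, 1.5)
  p2 <- match_segments(long_test, ref)
  expect_equal(nrow(p2), 1)
  expect_true(all(!duplicated(p2$test_id)))
  expect_true(all(!duplicated(p2$ref_id)))
})

test_that("matched-overlap feature correlation reproduces Pearson r and p", {
  # piecewise-constant f0 tracks so overlap mean_f0 equals chosen vectors
  f_ref <- c(100, 150, 210, 320)
  f_test <- c(112, 150, 190, 350)
  f0_ref <- rep(f_ref, each = 10)
  f0_test <- rep(f_test, each = 10)
  trk_ref <- make_track(rep(0.8, 40), f0 = f0_ref)
  trk_test <- make_track(rep(0.8, 40), f0 = f0_test)
  seg <- make_segments((0:3) * 0.1, (0:3) * 0.1 + 0.095)
  pairs <- match_segments(seg, seg)
  rep <- correlate_matched(pairs, trk_test, trk_ref, features = "mean_f0")
  oracle <- cor.test(f_ref, f_test)
  expect_equal(rep$rho, unname(oracle$estimate), tolerance = 1e-12)
  expect_equal(rep$p_value, oracle$p.value, tolerance = 1e-12)
  expect_equal(rep$n, 4)

  # identical tracks: perfect correlation on every feature with variability
  wiggle <- c(0, 2, -1, 3, 1, 0, -2, 1, 2, 0)
  f0_var <- f0_ref + as.vector(outer(wiggle, c(1, 2.5, 0.7, 1.8)))
  trk_same <- make_track(rep(0.8, 40), f0 = f0_var)
  rep_id <- correlate_matched(pairs, trk_same, trk_same)
  expect_true(all(abs(rep_id$rho - 1) < 1e-9))

  expect_error(correlate_matched(pairs[1:2, ], trk_test, trk_ref), "3")
  flat <- make_track(rep(0.8, 40), f0 = rep(200, 40))
  expect_error(
    correlate_matched(pairs, flat, flat, features = "mean_f0"),
    "zero variance"
  )
})

test_that("correlation is invariant to affine rescaling of either track's feature", {
  f_ref <- c(100, 150, 210, 320, 260)
  f0_ref <- rep(f_ref, each = 10)
  trk_ref <- make_track(rep(0.8, 50), f0 = f0_ref)
  trk_aff <- make_track(rep(0.8, 50), f0 = 1.8 * f0_ref + 40)
  seg <- make_segments((0:4) * 0.1, (0:4) * 0.1 + 0.095)
  pairs <- match_segments(seg, seg)
  rep <- correlate_matched(pairs, trk_aff, trk_ref, features = "mean_f0")
  expect_equal(rep$rho, 1, tolerance = 1e-9)
})

test_that("KS statistic and exact/asymptotic p-values behave as specified", {
  k0 <- ks_compare(c(1, 5, 9), c(1, 5, 9))
  expect_equal(k0$statistic, 0)
  expect_equal(k0$p_value, 1)

  k1 <- ks_compare(c(1, 2, 3), c(4, 5, 6))
  expect_equal(k1$statistic, 1)
  expect_equal(k1$p_value, 0.1) # 2 of choose(6,3)=20 assignments reach D=1
  expect_equal(k1$method, "exact")

  expect_error(ks_compare(numeric(0), 1:3), "non-empty")

  # asymptotic branch approaches the reference distribution for larger n
  a <- withr::with_seed(7, rnorm(60))
  b <- withr::with_seed(8, rnorm(80, 0.3))
  mine <- ks_compare(a, b)
  ref <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$method, "asymptotic")
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-6)
})

test_that("exact KS p-values match exhaustive enumeration for all small splits", {
  withr::with_seed(42, {
    for (na in 1:5) {
      for (nb in na:(10 - na)) {
        if (nb < 1) next
        a <- round(rnorm(na), 2)
        b <- round(rnorm(nb, 0.5), 2)
        res <- ks_compare(a, b)
        expect_equal(res$statistic, oracle_ks_d(a, b), tolerance = 1e-12)
        expect_equal(res$p_value, oracle_ks_p(a, b), tolerance = 1e-12)
      }
    }
  })
})
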