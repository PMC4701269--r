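test_that("mood classification applies the QIDS/YMRS cut-offs", {
  expect_equal(as.character(classify_mood(8, 3)), "depressive")
  expect_equal(as.character(classify_mood(7, 5)), "euthymic")
  expect_equal(as.character(classify_mood(9, 6)), "mixed")
  expect_equal(as.character(classify_mood(2, 6)), "hypomanic")
  # the four states partition the score plane
  grid <- expand.grid(qid = 0:15, ymrs = 0:12)
  states <- classify_mood(grid$qid, grid$ymrs)
  expect_true(all(!is.na(states)))
  expect_equal(
    sum(states == "mixed"),
    sum(grid$qid >= 8 & grid$ymrs >= 6)
  )
  expect_error(classify_mood(-1, 3), "non-negative")
})

test_that("ordinal scale runs hypomania < euthymia < depression, mixed excluded", {
  expect_equal(mood_ordinal("hypomanic"), 1L)
  expect_equal(mood_ordinal("euthymic"), 2L)
  expect_equal(mood_ordinal("depressive"), 3L)
  expect_equal(mood_ordinal(c("depressive", "hypomanic")), c(3L, 1L))
  expect_error(mood_ordinal("mixed"), "linear")
  expect_error(mood_ordinal("elated"), "unknown")
})

test_that("spearman rho and exact p match enumeration on frozen cases", {
  expect_equal(spearman_cor(1:4, c(10, 20, 30, 40))$rho, 1)
  expect_equal(spearman_cor(1:3, c(3, 2, 1))$rho, -1)
  res <- spearman_cor(c(1, 2, 3), c(1, 3, 2))
  expect_equal(res$rho, 0.5)
  # enumeration: every permutation of 3 ranks has |rho| >= 0.5
  expect_equal(res$p_value, 1.0)
  expect_equal(res$method, "exact")

  expect_error(spearman_cor(1:2, 2:1), "at least 3")
  expect_error(spearman_cor(c(1, 1, 1), 1:3), "constant")
})

test_that("spearman exact p agrees with full n! enumeration", {
  withr::with_seed(14, {
    for (n in 4:6) {
      for (rep in 1:3) {
        x <- rnorm(n)
        y <- sample(c(rnorm(n - 1), x[1])) # occasional tie structure via rounding
        res <- spearman_cor(x, y)
        expect_equal(res$p_value, oracle_spearman_p(x, y), tolerance = 1e-12)
      }
    }
  })
})

test_that("spearman is invariant under strictly monotone transforms", {
  withr::with_seed(15, {
    x <- rnorm(8)
    y <- rnorm(8)
    base <- spearman_cor(x, y)
    warped <- spearman_cor(exp(2 * x), y^3 + 5 * y)
    expect_equal(warped$rho, base$rho, tolerance = 1e-12)
    expect_equal(warped$p_value, base$p_value, tolerance = 1e-12)
  })
})

test_that("t-approximation branch engages above n = 9", {
  withr::with_seed(16, {
    x <- rnorm(15)
    y <- x + rnorm(15, 0, 2)
    res <- spearman_cor(x, y)
    expect_equal(res$method, "t-approximation")
    ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
    expect_equal(res$rho, unname(ref$estimate), tolerance = 1e-12)
  })
})

test_that("longitudinal report correlates summaries with the mood ordinal", {
  # MAD of mean F0 strictly increasing with the ordinal -> rho 1 on that row
  states <- c("hypomanic", "euthymic", "depressive", "euthymic", "hypomanic")
  ordinal <- c(1, 2, 3, 2, 1)
  assessments <- tibble::tibble(
    session_id = 1:5,
    qid = ifelse(states == "depressive", 9L, 2L),
    ymrs = ifelse(states == "hypomanic", 7L, 1L)
  )
  summaries <- purrr::map_dfr(1:5, function(i) {
    tibble::tibble(
      session_id = i,
      feature = c("mean_f0", "std_f0", "jitter"),
      median = c(190, 8, 0.01) + i * 0.1,
      mad = c(10 + 5 * ordinal[i], 4, 0.004),
      skewness = c(0.2, 0.5, 0.8) + 0.01 * i
    )
  })
  rep <- longitudinal_report(summaries, assessments)
  row <- dplyr::filter(rep, feature == "mean_f0", statistic == "mad")
  expect_equal(row$rho, 1)
  expect_equal(row$n, 5)
  expect_equal(nrow(rep), 9)

  # all euthymic -> constant ordinal -> undefined correlation
  flat <- dplyr::mutate(assessments, qid = 2L, ymrs = 1L)
  expect_error(longitudinal_report(summaries, flat), "constant")

  # mixed sessions are excluded with a warning
  mixed <- assessments
  mixed$qid[2] <- 10L
  mixed$ymrs[2] <- 8L
  expect_warning(rep2 <- longitudinal_report(summaries, mixed), "mixed")
  expect_equal(unique(rep2$n), 4)
})

test_that("synthetic cohorts recover the scripted mood-MAD association", {
  coh <- synth_cohort(seed = 123)
  expect_equal(nrow(coh$assessments), 15)
  states <- classify_mood(coh$assessments$qid, coh$assessments$ymrs)
  expect_equal(sum(states == "depressive"), 2)
  expect_equal(sum(states == "hypomanic"), 4)
  expect_equal(sum(states == "euthymic"), 9)
  rep <- longitudinal_report(coh$summaries, coh$assessments)
  row <- dplyr::filter(rep, feature == "mean_f0", statistic == "mad")
  expect_gt(row$rho, 0)
})
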