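mood_states <- c("hypomanic", "euthymic", "depressive", "mixed")

#' Classify a clinician assessment into a mood state
#'
#' Applies the scale cut-offs: a QIDS (quick depression inventory) score at
#' or above `qid_cut` indicates a depressive state; a YMRS (Young Mania
#' Rating Scale) score at or above `ymrs_cut` indicates a hypomanic state;
#' both at once is a mixed state; neither is euthymia (clinical remission).
#' The four states partition the score plane, so every assessment gets
#' exactly one label.
#'
#' @param qid,ymrs Non-negative integer scores (vectorised).
#' @param qid_cut Depression cut-off (default 8).
#' @param ymrs_cut Hypomania cut-off (default 6).
#' @return A factor with levels `hypomanic`, `euthymic`, `depressive`,
#'   `mixed`.
#' @examples
#' classify_mood(c(8, 7, 9), c(3, 5, 6))
#' @export
classify_mood <- function(qid, ymrs, qid_cut = 8, ymrs_cut = 6) {
  if (any(qid < 0, na.rm = TRUE) || any(ymrs < 0, na.rm = TRUE)) {
    stop("scores must be non-negative", call. = FALSE)
  }
  dep <- qid >= qid_cut
  hyp <- ymrs >= ymrs_cut
  state <- dplyr::case_when(
    dep & hyp ~ "mixed",
    dep ~ "depressive",
    hyp ~ "hypomanic",
    TRUE ~ "euthymic"
  )
  factor(state, levels = mood_states)
}

#' Ordinal rank of a mood state
#'
#' Places states on a single clinical dimension ranked in increasing order
#' from hypomania through euthymia to depression: hypomanic = 1,
#' euthymic = 2, depressive = 3. The mixed state does not fit this linear
#' dimensional model and raises an error; exclude mixed sessions before
#' ranking (as [longitudinal_report()] does).
#'
#' @param state Character vector or factor of mood states.
#' @return Integer ranks.
#' @export
mood_ordinal <- function(state) {
  state <- as.character(state)
  bad <- setdiff(unique(state), mood_states)
  if (length(bad) > 0) {
    stop("unknown mood state: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(state == "mixed")) {
    stop("mixed state is not on the linear hypomania-depression scale",
      call. = FALSE
    )
  }
  unname(c(hypomanic = 1L, euthymic = 2L, depressive = 3L)[state])
}

# all permutations of 1..n as an (n! x n) matrix
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  for (pos in seq_len(n)) {
    block <- (pos - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[block, pos] <- n
    out[block, -pos] <- sub
  }
  out
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Computes rho as the Pearson correlation of mid-ranks (ties receive
#' average ranks). For `n <= 9` the two-sided p-value is exact, obtained by
#' enumerating all `n!` permutations of one rank vector and counting
#' `|rho_perm| >= |rho_obs|`; for larger n it uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` with n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`; neither constant.
#' @return A one-row tibble: `rho`, `p_value`, `n`, `method`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("inputs must not contain NA", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("correlation undefined: constant input", call. = FALSE)
  }
  rho <- stats::cor(rx, ry)
  if (n <= 9L) {
    perms <- all_permutations(n)
    # rho is linear in sum(rx[perm] * ry): permuting ranks preserves moments
    s_all <- drop(matrix(rx[perms], nrow(perms)) %*% ry)
    mu <- n * mean(rx) * mean(ry)
    sc <- (n - 1) * stats::sd(rx) * stats::sd(ry)
    rho_all <- (s_all - mu) / sc
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tt <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tt), df = n - 2)
    }
    method <- "t-approximation"
  }
  tibble::tibble(rho = rho, p_value = p, n = n, method = method)
}

#' Correlate longitudinal feature summaries with mood state
#'
#' Joins per-session feature summaries with clinician assessments, derives
#' each session's mood state and ordinal rank (hypomanic < euthymic <
#' depressive), excludes mixed-state sessions with a warning, and computes
#' the Spearman correlation between every summary statistic
#' (median/MAD/skewness of mean F0, F0 standard deviation and jitter) and
#' the ordinal mood rank.
#'
#' @param summaries Tibble of per-session summaries in long form:
#'   `session_id`, `feature`, `median`, `mad`, `skewness` (stack of
#'   [summarize_features()] outputs with a `session_id` column).
#' @param assessments Tibble with `session_id`, `qid`, `ymrs` (e.g. from
#'   [read_assessments()]).
#' @param qid_cut,ymrs_cut Cut-offs passed to [classify_mood()].
#' @return A tibble with one row per feature x statistic: `feature`,
#'   `statistic`, `rho`, `p_value`, `n`. Statistics that are constant or
#'   undefined across the usable sessions get `NA` rho and p.
#' @export
longitudinal_report <- function(summaries, assessments,
                                qid_cut = 8, ymrs_cut = 6) {
  needed <- c("session_id", "qid", "ymrs")
  if (!all(needed %in% names(assessments))) {
    stop("`assessments` needs columns: ", paste(needed, collapse = ", "),
      call. = FALSE
    )
  }
  assessments <- dplyr::mutate(
    assessments,
    state = classify_mood(.data$qid, .data$ymrs, qid_cut, ymrs_cut)
  )
  n_mixed <- sum(assessments$state == "mixed")
  if (n_mixed > 0) {
    warning(
      n_mixed, " mixed-state session(s) excluded: not on the linear mood scale",
      call. = FALSE
    )
    assessments <- dplyr::filter(assessments, .data$state != "mixed")
  }
  if (nrow(assessments) < 3L) {
    stop("fewer than 3 usable (non-mixed) sessions", call. = FALSE)
  }
  assessments <- dplyr::mutate(assessments, ordinal = mood_ordinal(.data$state))
  if (length(unique(assessments$ordinal)) < 2L) {
    stop("correlation undefined: mood ordinal is constant across sessions",
      call. = FALSE
    )
  }

  long <- summaries |>
    tidyr::pivot_longer(
      cols = c("median", "mad", "skewness"),
      names_to = "statistic", values_to = "value"
    ) |>
    dplyr::inner_join(
      dplyr::select(assessments, "session_id", "ordinal"),
      by = "session_id"
    )
  long |>
    dplyr::group_by(.data$feature, .data$statistic) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::filter(df, !is.na(.data$value))
      res <- tryCatch(
        spearman_cor(df$value, df$ordinal),
        error = function(e) tibble::tibble(
          rho = NA_real_, p_value = NA_real_, n = nrow(df),
          method = NA_character_
        )
      )
      dplyr::select(res, "rho", "p_value", "n")
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(
      match(.data$feature, c("mean_f0", "std_f0", "jitter")),
      match(.data$statistic, c("median", "mad", "skewness"))
    )
}
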