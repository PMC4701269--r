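#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for voicemark result objects
#'
#' `tidy()` returns the per-element view of a result (curve points, per
#' feature correlations); `glance()` returns a one-row summary (the chosen
#' operating point, overall agreement).
#'
#' @param x A `threshold_curve`, `agreement_report`, `frame_confusion` or
#'   `ks_compare` object.
#' @param min_spec,min_sens Criterion passed to [choose_threshold()] by
#'   `glance.threshold_curve()`.
#' @param ... Ignored.
#' @return A tibble.
#' @name voicemark-tidiers
NULL

#' @rdname voicemark-tidiers
#' @method tidy threshold_curve
#' @export
tidy.threshold_curve <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname voicemark-tidiers
#' @method glance threshold_curve
#' @export
glance.threshold_curve <- function(x, min_spec = 0.9, min_sens = 0.6, ...) {
  chosen <- tryCatch(
    choose_threshold(x, min_spec = min_spec, min_sens = min_sens),
    error = function(e) NULL
  )
  if (is.null(chosen)) {
    return(tibble::tibble(
      chosen_threshold = NA_real_, sensitivity = NA_real_,
      specificity = NA_real_, admissible = FALSE
    ))
  }
  tibble::tibble(
    chosen_threshold = as.numeric(chosen),
    sensitivity = attr(chosen, "sensitivity"),
    specificity = attr(chosen, "specificity"),
    admissible = TRUE
  )
}

#' @rdname voicemark-tidiers
#' @method tidy agreement_report
#' @export
tidy.agreement_report <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname voicemark-tidiers
#' @method glance agreement_report
#' @export
glance.agreement_report <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x),
    min_rho = min(x$rho),
    max_p = max(x$p_value)
  )
}

#' @rdname voicemark-tidiers
#' @method tidy frame_confusion
#' @export
tidy.frame_confusion <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname voicemark-tidiers
#' @method tidy ks_compare
#' @export
tidy.ks_compare <- function(x, ...) {
  tibble::as_tibble(x)
}
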