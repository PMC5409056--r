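#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for repamp result objects
#'
#' `tidy()` returns the per-observation rows of a result as a plain
#' tibble; `glance()` returns its one-row (or one-row-per-statistic)
#' experiment-level summary.
#'
#' @param x An `overlap_summary`, `depth_profile` or `dispersion_test`.
#' @param ... Unused.
#' @return A tibble.
#' @name repamp-tidiers
NULL

#' @rdname repamp-tidiers
#' @method tidy overlap_summary
#' @export
tidy.overlap_summary <- function(x, ...) {
  tibble::as_tibble(unclass_result(x))
}

#' @rdname repamp-tidiers
#' @method glance overlap_summary
#' @export
glance.overlap_summary <- function(x, ...) {
  ex <- attr(x, "experiment")
  ex <- ex[ex$reduction == "per_sample_mean", ]
  wide <- tidyr::pivot_wider(ex[, c("statistic", "weighting", "mean", "sd")],
    names_from = c("weighting", "statistic"), values_from = c("mean", "sd"),
    names_glue = "{weighting}_{statistic}_{.value}"
  )
  dplyr::mutate(wide, n_samples = ex$n[1])
}

#' @rdname repamp-tidiers
#' @method tidy depth_profile
#' @export
tidy.depth_profile <- function(x, ...) {
  tibble::as_tibble(unclass_result(x))
}

#' @rdname repamp-tidiers
#' @method glance depth_profile
#' @export
glance.depth_profile <- function(x, ...) {
  sat <- attr(x, "saturation")
  dplyr::mutate(sat,
    n_depths = length(unique(x$depth)),
    n_resamples = attr(x, "n_resamples"),
    saturation_threshold = attr(x, "saturation_threshold"),
    saturation_window = attr(x, "saturation_window")
  )
}

#' @rdname repamp-tidiers
#' @method tidy dispersion_test
#' @export
tidy.dispersion_test <- function(x, ...) {
  tibble::as_tibble(unclass_result(x))
}

#' @rdname repamp-tidiers
#' @param alpha Significance level used to count rejections.
#' @method glance dispersion_test
#' @export
glance.dispersion_test <- function(x, alpha = 0.05, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(unclass_result(x)), .data$metric),
    n_tests = dplyr::n(),
    n_rejected = sum(.data$p <= alpha),
    mean_delta_d_pct = mean(.data$delta_d_pct),
    .groups = "drop"
  )
}

unclass_result <- function(x) {
  attr(x, "experiment") <- NULL
  attr(x, "saturation") <- NULL
  class(x) <- setdiff(class(x), c("overlap_summary", "depth_profile", "dispersion_test"))
  x
}
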