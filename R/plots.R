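#' Plot methods for repamp results
#'
#' `autoplot()` methods return ggplot objects: per-sample overlap values
#' for an [overlap_summary()], overlap-versus-depth curves (with the
#' detected saturation depth marked) for a [depth_profile()], and the
#' relative dispersion excess per sample for a set of dispersion tests.
#'
#' @param object A repamp result object.
#' @param ... Unused.
#' @return A `ggplot`.
#' @name repamp-plots
NULL

#' @rdname repamp-plots
#' @method autoplot overlap_summary
#' @export
autoplot.overlap_summary <- function(object, ...) {
  d <- tidy(object)
  d <- tidyr::pivot_longer(d, c("unweighted", "weighted"),
    names_to = "weighting", values_to = "overlap"
  )
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$statistic, y = .data$overlap,
    colour = .data$weighting
  )) +
    ggplot2::geom_boxplot(outlier.shape = NA, position = ggplot2::position_dodge(0.7)) +
    ggplot2::geom_point(
      position = ggplot2::position_jitterdodge(
        jitter.width = 0.1,
        dodge.width = 0.7
      ),
      alpha = 0.5, size = 1
    ) +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%"), limits = c(0, 1)) +
    ggplot2::labs(
      x = NULL, y = "OTU overlap", colour = NULL,
      title = "OTU overlap between/among technical replicates"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname repamp-plots
#' @method autoplot depth_profile
#' @export
autoplot.depth_profile <- function(object, ...) {
  d <- tidy(object)
  sat <- attr(object, "saturation")
  p <- ggplot2::ggplot(d, ggplot2::aes(
    x = .data$depth, y = .data$mean,
    colour = .data$statistic, linetype = .data$weighting
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1)
  if (any(!is.na(d$sd))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd,
        fill = .data$statistic
      ),
      alpha = 0.15, colour = NA
    )
  }
  if (!is.null(sat) && any(!is.na(sat$saturation_depth))) {
    p <- p + ggplot2::geom_vline(
      data = sat[!is.na(sat$saturation_depth), ],
      ggplot2::aes(xintercept = .data$saturation_depth, colour = .data$statistic),
      linetype = "dotted", alpha = 0.6
    )
  }
  p +
    ggplot2::scale_x_continuous(labels = scales_comma) +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(
      x = "sequencing depth (reads)", y = "mean OTU overlap",
      colour = NULL, linetype = NULL, fill = NULL,
      title = "OTU overlap vs sequencing depth"
    ) +
    ggplot2::theme_minimal()
}

scales_comma <- function(x) format(x, big.mark = ",", scientific = FALSE, trim = TRUE)

#' @rdname repamp-plots
#' @method autoplot dispersion_test
#' @export
autoplot.dispersion_test <- function(object, ...) {
  d <- tidy(object)
  d$significant <- d$p <= 0.05
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$sample, y = .data$delta_d_pct,
    fill = .data$significant
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::facet_wrap(~ .data$metric) +
    ggplot2::labs(
      x = NULL, y = "dispersion excess over null (%)",
      fill = "p <= 0.05",
      title = "Observed vs null-model dispersion of technical replicates"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, hjust = 1))
}

#' Plot level-wise beta diversity
#'
#' Column chart of mean dissimilarity per comparison level (technical,
#' biological, treatment, across-location), per metric.
#'
#' @param levels A tibble from [beta_level_summary()], optionally with a
#'   `metric` column (as produced by [run_analysis()]).
#' @return A `ggplot`.
#' @export
plot_beta_levels <- function(levels) {
  if (!"metric" %in% names(levels)) levels$metric <- "dissimilarity"
  ggplot2::ggplot(levels, ggplot2::aes(
    x = .data$level, y = .data$mean_dissimilarity,
    fill = .data$metric
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = NULL, y = "mean dissimilarity", fill = NULL,
      title = "Beta diversity by comparison level"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
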