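#' Plot a methylation track with optional DMR highlights
#'
#' @param track Methylation tibble `chrom`, `pos`, `methylation` (one or more
#'   chromosomes; facetted).
#' @param dmrs Optional DMR tibble to shade.
#' @param sample_label Legend label for the track.
#' @return A ggplot object.
#' @export
plot_methylation_track <- function(track, dmrs = NULL,
                                   sample_label = "methylation") {
  p <- ggplot2::ggplot(track, ggplot2::aes(x = .data$pos,
                                           y = .data$methylation)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey30") +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = sample_label) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (!is.null(dmrs) && nrow(dmrs) > 0) {
    p <- p + ggplot2::geom_rect(
      data = as_tibble(dmrs),
      ggplot2::aes(xmin = .data$start, xmax = .data$end, ymin = 0, ymax = 1),
      inherit.aes = FALSE, alpha = 0.2, fill = "firebrick"
    )
  }
  p
}

#' Plot per-sample DMR methylation by group
#'
#' Dot plot of DMR-mean methylation per sample, grouped by hominin group —
#' the visual form of the range-exclusion (fixation) filter.
#'
#' @param dmr One row of a filtered `dmr_set` carrying a `sample_means`
#'   list-column (from [variability_filter()]).
#' @return A ggplot object.
#' @export
plot_dmr_sample_means <- function(dmr) {
  mm <- dmr$sample_means[[1]]
  ggplot2::ggplot(mm, ggplot2::aes(x = .data$group, y = .data$mean,
                                   colour = .data$group)) +
    ggplot2::geom_jitter(width = 0.1, height = 0, size = 2) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "DMR mean methylation",
                  title = sprintf("%s:%d-%d (%s)", dmr$chrom, dmr$start,
                                  dmr$end, dmr$lineage %||% "unassigned")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot a threshold calibration summary
#'
#' Bar chart of real versus mean simulated DMR counts at the calibrated
#' thresholds, per scan direction.
#'
#' @param x,object A `dmr_calibration` from [calibrate_thresholds()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_calibration <- function(x) {
  df <- tibble(
    direction = rep(c("hyper", "hypo"), each = 2),
    kind = rep(c("real", "simulated (mean)"), 2),
    count = c(x$real_counts["hyper"], x$mean_simulated_counts["hyper"],
              x$real_counts["hypo"], x$mean_simulated_counts["hypo"])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$direction, y = .data$count,
                                   fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(y = "DMR count at calibrated threshold", x = NULL,
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_calibration
#' @export
autoplot.dmr_calibration <- function(object, ...) plot_calibration(object)

#' Plot the pipeline funnel
#'
#' DMR counts surviving each pipeline step.
#'
#' @param x,object A `dmr_pipeline` result from [run_pipeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_funnel <- function(x) {
  df <- x$funnel |>
    mutate(step = factor(.data$step, levels = rev(.data$step)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$step)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), hjust = -0.2,
                       size = 3) +
    ggplot2::labs(x = "DMRs", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_funnel
#' @export
autoplot.dmr_pipeline <- function(object, ...) plot_funnel(object)
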