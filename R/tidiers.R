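#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a threshold calibration
#'
#' @param x A `dmr_calibration` from [calibrate_thresholds()].
#' @param ... Unused.
#' @return One row per scan direction: `direction`, `q_threshold`,
#'   `real_count`, `mean_simulated_count`, `achieved_fdr`.
#' @export
tidy.dmr_calibration <- function(x, ...) {
  tibble(
    direction = c("hyper", "hypo"),
    q_threshold = c(x$q_threshold_plus, x$q_threshold_minus),
    real_count = unname(x$real_counts[c("hyper", "hypo")]),
    mean_simulated_count = unname(x$mean_simulated_counts[c("hyper", "hypo")]),
    achieved_fdr = unname(x$achieved_fdr[c("hyper", "hypo")])
  )
}

#' @rdname tidy.dmr_calibration
#' @return `glance()`: a one-row summary with the pooled FDR and settings.
#' @export
glance.dmr_calibration <- function(x, ...) {
  tibble(n_sims = x$n_sims, target_fdr = x$target_fdr,
         pooled_fdr = x$pooled_fdr,
         real_total = sum(x$real_counts),
         mean_simulated_total = sum(x$mean_simulated_counts))
}

#' Tidy a pipeline result
#'
#' @param x A `dmr_pipeline` from [run_pipeline()].
#' @param ... Unused.
#' @return `tidy()`: the final DMR tibble (one row per fixed, lineage-labeled
#'   DMR). `glance()`: one row with per-step funnel counts and the mode.
#' @export
tidy.dmr_pipeline <- function(x, ...) {
  as_tibble(x$dmrs) |> select(-dplyr::any_of("sample_means"))
}

#' @rdname tidy.dmr_pipeline
#' @export
glance.dmr_pipeline <- function(x, ...) {
  wide <- stats::setNames(as.list(x$funnel$n), x$funnel$step)
  dplyr::bind_cols(tibble(mode = x$mode), as_tibble(wide))
}
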