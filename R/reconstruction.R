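#' Reconstruction parameters
#'
#' Parameters controlling the conversion of per-CpG deamination counts into a
#' methylation track.
#'
#' @param ct_ratio_cap Sites with raw C→T ratio above this cap are treated as
#'   putative pre-mortem C→T mutations and discarded (default 0.25; raise to
#'   0.5 for low-coverage samples).
#' @param max_coverage Sites covered by more reads than this are discarded as
#'   suspected PCR duplicates (default 100).
#' @param window_cpgs Width (in CpGs) of the sliding smoothing window (default
#'   25; 50 for low-coverage samples).
#' @param mu100 The smoothed C→T ratio corresponding to 100% methylation; if
#'   `NULL` it must be supplied via a reference (bone mode) or computed from
#'   the genome-wide mean (tooth mode).
#' @param tissue_mode `"bone"` (mu100 from a modern reference) or `"tooth"`
#'   (mu100 set to `1/0.75` times the genome-wide mean smoothed ratio, so that
#'   the genome-wide mean maps to 75% methylation).
#' @param smoothing `"pooled"` (window ratio is pooled counts, sum(t)/sum(n))
#'   or `"ratio_mean"` (mean of per-site ratios).
#' @return A list of class `reconstruction_params`.
#' @export
reconstruction_params <- function(ct_ratio_cap = 0.25, max_coverage = 100,
                                  window_cpgs = 25, mu100 = NULL,
                                  tissue_mode = c("bone", "tooth"),
                                  smoothing = c("pooled", "ratio_mean")) {
  tissue_mode <- match.arg(tissue_mode)
  smoothing <- match.arg(smoothing)
  if (!is.null(mu100) && (mu100 <= 0 || mu100 > 1)) {
    abort("mu100 must be in (0, 1]")
  }
  if (window_cpgs < 1) abort("window_cpgs must be >= 1")
  structure(list(ct_ratio_cap = ct_ratio_cap, max_coverage = max_coverage,
                 window_cpgs = window_cpgs, mu100 = mu100,
                 tissue_mode = tissue_mode, smoothing = smoothing),
            class = "reconstruction_params")
}

#' Filter out putative pre-mortem substitutions and artifacts
#'
#' Applies the pre-mortem filters to a deamination count track:
#' (i) sites where A+G reads outnumber C+T reads (putative mutations; needs an
#' `ag_count` column), (ii) for single-stranded libraries, sites whose
#' opposite-strand G→A ratio exceeds one sequencing error per position (needs a
#' `ga_ratio` column), (iii) sites with raw C→T ratio above `ct_ratio_cap`,
#' and (iv) sites covered by more than `max_coverage` reads (suspected PCR
#' duplicates). Filters whose auxiliary columns are absent are skipped with a
#' warning. Per-filter removal tallies are attached as
#' `attr(result, "filter_tally")`.
#'
#' @param track Count track tibble: `chrom`, `pos`, `c_count`, `t_count`,
#'   optionally `ag_count` and `ga_ratio`.
#' @param params A [reconstruction_params()].
#' @param library_type `"double"` or `"single"`; the G→A filter only applies to
#'   single-stranded libraries.
#' @return The track restricted to surviving sites (uncovered sites are also
#'   dropped).
#' @export
apply_premortem_filters <- function(track, params = reconstruction_params(),
                                    library_type = c("double", "single")) {
  library_type <- match.arg(library_type)
  stopifnot_cols(track, c("chrom", "pos", "c_count", "t_count"))
  n <- track$c_count + track$t_count
  keep <- n > 0
  tally <- c(uncovered = sum(!keep))
  if ("ag_count" %in% names(track)) {
    bad <- keep & track$ag_count > n
    tally["ag_mutation"] <- sum(bad)
    keep <- keep & !bad
  } else {
    tally["ag_mutation"] <- NA_integer_
  }
  if (library_type == "single") {
    if ("ga_ratio" %in% names(track)) {
      mean_cov <- mean(n[n > 0])
      bad <- keep & track$ga_ratio > 1 / mean_cov
      tally["ga_single_strand"] <- sum(bad)
      keep <- keep & !bad
    } else {
      warn("single-stranded library but no ga_ratio column; G->A filter skipped")
      tally["ga_single_strand"] <- NA_integer_
    }
  }
  ratio <- ifelse(n > 0, track$t_count / n, NA_real_)
  bad <- keep & ratio > params$ct_ratio_cap
  tally["ct_ratio_cap"] <- sum(bad, na.rm = TRUE)
  keep <- keep & !bad
  bad <- keep & n > params$max_coverage
  tally["max_coverage"] <- sum(bad)
  keep <- keep & !bad
  out <- track[keep, , drop = FALSE]
  attr(out, "filter_tally") <- tally
  out
}

#' Raw per-site C→T ratio
#'
#' The raw deamination signal \eqn{t_i / n_i} with \eqn{n_i = c_i + t_i}.
#' Uncovered sites (\eqn{n_i = 0}) are excluded.
#'
#' @param track Count track tibble.
#' @return The track with added columns `n` and `ct_ratio`, restricted to
#'   covered sites.
#' @export
#' @examples
#' ct_ratio(tibble::tibble(chrom = "chr1", pos = 0, c_count = 9, t_count = 1))
ct_ratio <- function(track) {
  stopifnot_cols(track, c("chrom", "pos", "c_count", "t_count"))
  track |>
    mutate(n = .data$c_count + .data$t_count) |>
    filter(.data$n > 0) |>
    mutate(ct_ratio = .data$t_count / .data$n)
}

#' Smooth the C→T ratio over a sliding CpG window
#'
#' The value at site i is the pooled ratio sum(t)/sum(n) over a window of
#' `window_cpgs` consecutive CpGs centred at i (truncated at chromosome ends;
#' windows never span chromosomes). `"ratio_mean"` mode averages per-site
#' ratios instead.
#'
#' @param track Count track (covered, filtered sites).
#' @param window_cpgs Window width in CpGs; 1 leaves per-site ratios untouched.
#' @param smoothing `"pooled"` or `"ratio_mean"`.
#' @return The track with columns `n`, `ct_ratio`, and `smoothed_ratio`.
#' @export
smooth_ct_ratio <- function(track, window_cpgs = 25,
                            smoothing = c("pooled", "ratio_mean")) {
  smoothing <- match.arg(smoothing)
  r <- ct_ratio(track)
  r <- r |>
    group_by(.data$chrom) |>
    mutate(smoothed_ratio = if (smoothing == "pooled") {
      rolling_sum(.data$t_count, window_cpgs) /
        rolling_sum(.data$n, window_cpgs)
    } else {
      rolling_sum(.data$ct_ratio, window_cpgs) /
        rolling_sum(rep(1, dplyr::n()), window_cpgs)
    }) |>
    ungroup()
  r
}

#' Estimate the deamination rate
#'
#' The deamination rate \eqn{\pi} is the overall C→T ratio (pooled counts)
#' across CpG positions that are fully methylated in a modern reference
#' methylome, after pre-mortem filtering.
#'
#' @param track Filtered count track.
#' @param reference Reference methylation tibble `chrom`, `pos`, `methylation`.
#' @param min_methylation Sites with reference methylation at or above this are
#'   treated as fully methylated (default 1; relax to e.g. 0.95 when the
#'   reference rarely reports exactly 1).
#' @return The estimated rate (a single number in (0, 1)).
#' @export
estimate_pi <- function(track, reference, min_methylation = 1) {
  stopifnot_cols(reference, c("chrom", "pos", "methylation"))
  full <- reference |> filter(.data$methylation >= min_methylation)
  j <- inner_join(ct_ratio(track), full, by = c("chrom", "pos"))
  if (nrow(j) == 0) {
    abort(paste0("no fully methylated reference sites intersect the track; ",
                 "relax min_methylation (e.g. 0.95)"))
  }
  pi_hat <- sum(j$t_count) / sum(j$n)
  if (pi_hat <= 0 || pi_hat >= 1) {
    abort("estimated pi is outside (0, 1); check the inputs")
  }
  pi_hat
}

#' Linearly transform smoothed C→T ratios to methylation
#'
#' Zero ratio maps to 0% methylation and `mu100` (the mean ratio at fully
#' methylated reference positions) maps to 100%; ratios above `mu100` are set
#' to 100%. In tooth mode no modern reference exists, so `mu100` is set to
#' `1/0.75` times the genome-wide mean smoothed ratio, i.e. the genome-wide
#' mean ratio is assumed to represent 75% methylation (the genome-wide mean of
#' a modern bone methylome).
#'
#' @param smoothed Track with a `smoothed_ratio` column (see
#'   [smooth_ct_ratio()]).
#' @param mu100 Ratio corresponding to 100% methylation (bone mode).
#' @param tissue_mode `"bone"` or `"tooth"`.
#' @return A methylation track tibble: `chrom`, `pos`, `methylation`, with
#'   `attr(., "mu100")` recording the transformation constant.
#' @export
to_methylation <- function(smoothed, mu100 = NULL,
                           tissue_mode = c("bone", "tooth")) {
  tissue_mode <- match.arg(tissue_mode)
  stopifnot_cols(smoothed, c("chrom", "pos", "smoothed_ratio"))
  if (tissue_mode == "tooth") {
    mu100 <- mean(smoothed$smoothed_ratio) / 0.75
  }
  if (is.null(mu100)) abort("mu100 must be supplied in bone mode")
  if (mu100 <= 0) abort("mu100 must be > 0")
  out <- tibble(chrom = smoothed$chrom, pos = smoothed$pos,
                methylation = pmin(smoothed$smoothed_ratio / mu100, 1))
  attr(out, "mu100") <- mu100
  out
}

#' Reconstruct a methylation map from a deamination count track
#'
#' Full reconstruction: pre-mortem filtering, sliding-window smoothing of the
#' C→T ratio, and linear transformation to methylation. In bone mode, `mu100`
#' and the deamination rate are estimated from the fully methylated positions
#' of a modern reference map (they coincide: both are the mean C→T ratio at
#' fully methylated sites).
#'
#' @param track Raw count track.
#' @param params A [reconstruction_params()].
#' @param reference Modern reference methylation track (required in bone mode
#'   when `params$mu100` is `NULL`).
#' @param library_type Passed to [apply_premortem_filters()].
#' @param min_methylation Threshold for "fully methylated" reference sites.
#' @return A methylation track with attributes `pi`, `mu100`, and
#'   `filter_tally`.
#' @export
reconstruct_methylome <- function(track, params = reconstruction_params(),
                                  reference = NULL,
                                  library_type = "double",
                                  min_methylation = 0.95) {
  filtered <- apply_premortem_filters(track, params, library_type)
  sm <- smooth_ct_ratio(filtered, params$window_cpgs, params$smoothing)
  mu100 <- params$mu100
  pi_hat <- NA_real_
  if (params$tissue_mode == "bone" && is.null(mu100)) {
    if (is.null(reference)) {
      abort("bone mode needs mu100 or a modern reference map")
    }
    pi_hat <- estimate_pi(filtered, reference, min_methylation)
    mu100 <- pi_hat
  }
  out <- to_methylation(sm, mu100, params$tissue_mode)
  attr(out, "pi") <- pi_hat
  attr(out, "filter_tally") <- attr(filtered, "filter_tally")
  attr(out, "window_cpgs") <- params$window_cpgs
  out
}
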