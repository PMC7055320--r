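#' Reconstruct methylomes for every reconstructed sample of a panel
#'
#' Fills the `methylation` list-column for samples with deamination counts:
#' pre-mortem filtering, smoothing and linear transformation, with the modern
#' reference (for the deamination rate and the 100%-methylation ratio) taken
#' from the highest-coverage modern-human WGBS sample of the panel. Samples
#' whose mean coverage is below `low_coverage_below` get the low-coverage
#' settings (C→T ratio cap 0.5, 50-CpG window). Tooth samples use tooth-mode
#' rescaling. Estimated deamination rates are stored in `panel$pi_hat`.
#'
#' @param panel A `sample_panel` (see [simulate_panel()]).
#' @param params Base [reconstruction_params()].
#' @param min_methylation Reference sites at or above this count as fully
#'   methylated when estimating the deamination rate.
#' @param low_coverage_below Mean-coverage cutoff for low-coverage settings.
#' @return The panel with `methylation` filled for reconstructed samples and
#'   a numeric `pi_hat` column.
#' @export
reconstruct_panel <- function(panel, params = reconstruction_params(),
                              min_methylation = 0.95,
                              low_coverage_below = 10) {
  wgbs_amh <- which(panel$group == "AMH" & panel$technology == "WGBS")
  if (length(wgbs_amh) == 0) abort("panel has no modern-human WGBS reference")
  cov_of <- function(i) {
    cc <- panel$meth_counts[[i]]
    mean(cc$meth_count + cc$unmeth_count)
  }
  ref_idx <- wgbs_amh[which.max(vapply(wgbs_amh, cov_of, numeric(1)))]
  reference <- panel$methylation[[ref_idx]]
  panel$pi_hat <- NA_real_
  for (i in which(panel$technology == "reconstructed")) {
    counts <- panel$counts[[i]]
    mean_cov <- mean(counts$c_count + counts$t_count)
    p <- params
    if (mean_cov < low_coverage_below) {
      p$ct_ratio_cap <- max(p$ct_ratio_cap, 0.5)
      p$window_cpgs <- max(p$window_cpgs, 50)
    }
    tissue <- panel$tissue[i] %||% "femur"
    p$tissue_mode <- if (identical(tissue, "tooth")) "tooth" else "bone"
    rec <- reconstruct_methylome(counts, p, reference = reference,
                                 min_methylation = min_methylation)
    panel$methylation[[i]] <- rec
    panel$pi_hat[i] <- if (p$tissue_mode == "bone") attr(rec, "pi") else
      estimate_pi(apply_premortem_filters(counts, p), reference,
                  min_methylation)
  }
  attr(panel, "reference_id") <- panel$id[ref_idx]
  panel
}

#' Run the full DMR pipeline on a sample panel
#'
#' Executes the five-step comparative analysis: (1) reciprocal two-way DMR
#' detection among the three reconstructed core hominin methylomes, at
#' thresholds calibrated per detection run by simulation-based FDR
#' (step 3 of the conceptual pipeline); (2) three-way intersection yielding
#' hominin-specific DMRs; (4) lineage assignment against the chimpanzee
#' outgroup; (5) within-group variability (fixation) filtering. A per-step
#' funnel of DMR counts is recorded.
#'
#' @param panel A `sample_panel`; reconstructions are computed if absent.
#' @param params A [detector_params()].
#' @param mode `"wgbs"` (only WGBS + reconstructed maps in filtering;
#'   unbiased genomic distribution) or `"strict"` (arrays included in
#'   assignment and filtering).
#' @param n_sims Null simulations per calibration (default 100).
#' @param target_fdr Calibration target (default 0.05).
#' @param seed Master seed for the calibration simulations.
#' @param recon_params [reconstruction_params()] for [reconstruct_panel()].
#' @return A `dmr_pipeline` list: `dmrs` (final labeled `dmr_set`),
#'   `all_candidates` (lineage-annotated pre-filter set), `funnel`
#'   (step-by-step counts), `calibrations`, `thresholds`, `panel`, `params`,
#'   `mode`.
#' @export
run_pipeline <- function(panel, params = detector_params(),
                         mode = c("wgbs", "strict"), n_sims = 100,
                         target_fdr = 0.05, seed = 1,
                         recon_params = reconstruction_params()) {
  mode <- match.arg(mode)
  if (!"pi_hat" %in% names(panel)) {
    panel <- reconstruct_panel(panel, recon_params)
  }
  core <- panel[panel$core, ]
  if (nrow(core) != 3) abort("panel must carry exactly 3 core samples")
  hominins <- core$group
  core_samples <- purrr::map(seq_len(3), function(i) {
    list(id = core$id[i], group = core$group[i],
         counts = apply_premortem_filters(core$counts[[i]], recon_params),
         methylation = core$methylation[[i]],
         pi = core$pi_hat[i])
  })
  names(core_samples) <- hominins
  pairs <- utils::combn(hominins, 2, simplify = FALSE)
  seeds <- derive_seeds(seed, 2 * length(pairs))
  calibrations <- list()
  pair_sets <- list()
  for (pidx in seq_along(pairs)) {
    pr <- pairs[[pidx]]
    s1 <- core_samples[[pr[1]]]
    s2 <- core_samples[[pr[2]]]
    cal1 <- calibrate_thresholds(s1$counts, s2$methylation, params,
                                 pi = s1$pi, n_sims = n_sims,
                                 target_fdr = target_fdr,
                                 seed = seeds[2 * pidx - 1])
    cal2 <- calibrate_thresholds(s2$counts, s1$methylation, params,
                                 pi = s2$pi, n_sims = n_sims,
                                 target_fdr = target_fdr,
                                 seed = seeds[2 * pidx])
    key <- paste(pr, collapse = "_vs_")
    calibrations[[paste0(key, ":", s1$id)]] <- cal1
    calibrations[[paste0(key, ":", s2$id)]] <- cal2
    pair_sets[[key]] <- reciprocal_two_way(
      s1, s2, params,
      thresholds1 = c(hyper = cal1$q_threshold_plus,
                      hypo = cal1$q_threshold_minus),
      thresholds2 = c(hyper = cal2$q_threshold_plus,
                      hypo = cal2$q_threshold_minus)
    )
  }
  positions <- attr(panel, "positions") %||%
    dplyr::distinct(core_samples[[1]]$methylation[, c("chrom", "pos")])
  # orient a pair set relative to hominin h (flip when h is the second member)
  oriented <- function(h, other) {
    key1 <- paste(h, other, sep = "_vs_")
    key2 <- paste(other, h, sep = "_vs_")
    if (!is.null(pair_sets[[key1]])) return(pair_sets[[key1]])
    d <- pair_sets[[key2]]
    if (nrow(d) > 0) {
      d$direction <- ifelse(d$direction == "hyper", "hypo", "hyper")
    }
    d
  }
  specific <- purrr::map_dfr(hominins, function(h) {
    others <- setdiff(hominins, h)
    ix <- three_way_intersect(oriented(h, others[1]), oriented(h, others[2]),
                              positions, params$min_cpgs)
    if (nrow(ix) > 0) ix$specific_to <- h
    ix
  })
  if (nrow(specific) == 0) {
    specific <- tibble(chrom = character(), start = integer(),
                       end = integer(), n_cpgs = integer(),
                       direction = character(), q_max = numeric(),
                       specific_to = character())
  }
  strict <- mode == "strict"
  assigned <- if (nrow(specific) > 0) {
    assign_lineage(specific, panel, strict = strict)
  } else {
    specific |> mutate(lineage = character(0), assign_status = character(0))
  }
  # orient direction relative to the derived lineage: an AMH-specific DMR
  # placed on the archaic ancestor branch means the archaics moved, not AMH
  kept <- assigned |>
    filter(.data$assign_status == "assigned") |>
    mutate(direction = ifelse(.data$lineage == "archaic" &
                                .data$specific_to == "AMH",
                              ifelse(.data$direction == "hyper", "hypo",
                                     "hyper"),
                              .data$direction))
  filtered <- if (nrow(kept) > 0) {
    variability_filter(kept, panel, strict = strict,
                       min_gap = params$min_mean_diff %||% 0)
  } else {
    kept |> mutate(fixed = logical(0), sample_means = list())
  }
  final <- filtered |> filter(.data$fixed)
  funnel <- tibble(
    step = c("two_way", "three_way_specific", "lineage_assigned",
             "variability_fixed"),
    n = c(sum(vapply(pair_sets, nrow, numeric(1))), nrow(specific),
          nrow(kept), nrow(final))
  )
  structure(list(dmrs = final, all_candidates = assigned, funnel = funnel,
                 calibrations = calibrations,
                 thresholds = purrr::map(calibrations, function(cal) {
                   c(hyper = cal$q_threshold_plus,
                     hypo = cal$q_threshold_minus)
                 }),
                 panel = panel, params = params, mode = mode),
            class = "dmr_pipeline")
}

#' @export
print.dmr_pipeline <- function(x, ...) {
  cat("DMR pipeline (", x$mode, " mode)\n", sep = "")
  print(x$funnel)
  if (nrow(x$dmrs) > 0) {
    cat("final DMRs by lineage:\n")
    print(table(x$dmrs$lineage))
  }
  invisible(x)
}

#' Compare pipeline output against planted truth
#'
#' Scores a detected DMR set against the planted intervals of a synthetic
#' panel: a planted DMR is recovered if some reported DMR overlaps it; label
#' accuracy is the fraction of matched reported DMRs whose lineage equals the
#' planted lineage; false positives are reported DMRs overlapping no planted
#' interval.
#'
#' @param dmrs A `dmr_set` (with a `lineage` column for label scoring, and a
#'   `direction` column for direction scoring).
#' @param truth Planted-interval tibble (`attr(panel, "truth")`).
#' @return A list with `sensitivity`, `label_accuracy`,
#'   `direction_accuracy`, `n_false_positive`, and the matched tibble
#'   `matches`.
#' @export
evaluate_recovery <- function(dmrs, truth) {
  if (nrow(truth) == 0) abort("truth has no planted intervals")
  overlap_of <- function(k) {
    hits <- which(dmrs$chrom == truth$chrom[k] &
                    dmrs$start < truth$end[k] & dmrs$end > truth$start[k])
    if (length(hits) == 0) return(NA_integer_)
    if ("lineage" %in% names(dmrs)) {
      good <- hits[!is.na(dmrs$lineage[hits]) &
                     dmrs$lineage[hits] == truth$lineage[k]]
      if (length(good) > 0) return(good[1])
    }
    hits[1]
  }
  match_idx <- vapply(seq_len(nrow(truth)), overlap_of, integer(1))
  recovered <- !is.na(match_idx)
  label_ok <- direction_ok <- rep(NA, nrow(truth))
  if ("lineage" %in% names(dmrs)) {
    label_ok[recovered] <- dmrs$lineage[match_idx[recovered]] ==
      truth$lineage[recovered]
  }
  if ("direction" %in% names(dmrs)) {
    direction_ok[recovered] <- dmrs$direction[match_idx[recovered]] ==
      truth$direction[recovered]
  }
  fp <- vapply(seq_len(nrow(dmrs)), function(j) {
    !any(truth$chrom == dmrs$chrom[j] & truth$start < dmrs$end[j] &
           truth$end > dmrs$start[j])
  }, logical(1))
  list(
    sensitivity = mean(recovered),
    label_accuracy = if (any(recovered) && "lineage" %in% names(dmrs)) {
      mean(label_ok[recovered])
    } else NA_real_,
    direction_accuracy = if (any(recovered) && "direction" %in% names(dmrs)) {
      mean(direction_ok[recovered])
    } else NA_real_,
    n_false_positive = sum(fp),
    matches = tibble(truth_row = seq_len(nrow(truth)), recovered = recovered,
                     dmr_row = match_idx, lineage_ok = label_ok,
                     direction_ok = direction_ok)
  )
}
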