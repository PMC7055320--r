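#' Reciprocal two-way DMR detection between two samples
#'
#' To avoid biases from the reconstruction process, each pair of samples is
#' compared twice: the deamination map of sample 1 against the reconstructed
#' methylome of sample 2, and vice versa. The two runs' DMRs are oriented
#' relative to sample 1 (direction of the second run is flipped) and merged:
#' overlapping same-direction DMRs from the two runs are unioned, and a DMR
#' found by only one run is retained and flagged.
#'
#' @param sample1,sample2 Lists with elements `id`, `counts` (filtered count
#'   track), `methylation` (reconstructed track), and `pi`.
#' @param params A [detector_params()] (thresholds included); per-run
#'   thresholds can be supplied via `thresholds1` / `thresholds2`.
#' @param thresholds1,thresholds2 Optional named vectors
#'   `c(hyper = , hypo = )` overriding the params thresholds for run 1
#'   (sample1 counts vs sample2 reference) and run 2.
#' @return A `dmr_set` tibble with columns `chrom`, `start`, `end`, `n_cpgs`,
#'   `direction` (relative to sample 1), `q_max`, `found_in`
#'   (`"both"`/`"run1"`/`"run2"`).
#' @export
reciprocal_two_way <- function(sample1, sample2, params = detector_params(),
                               thresholds1 = NULL, thresholds2 = NULL) {
  run_with <- function(test_s, ref_s, thr) {
    p <- params
    if (!is.null(thr)) {
      p$q_threshold_plus <- thr[["hyper"]]
      p$q_threshold_minus <- thr[["hypo"]]
    }
    detect_dmrs(test_s$counts, ref_s$methylation, p, pi = test_s$pi)
  }
  d1 <- run_with(sample1, sample2, thresholds1)
  d2 <- run_with(sample2, sample1, thresholds2)
  if (nrow(d2) > 0) {
    d2$direction <- ifelse(d2$direction == "hyper", "hypo", "hyper")
  }
  d1$run <- if (nrow(d1) > 0) "run1" else character(0)
  d2$run <- if (nrow(d2) > 0) "run2" else character(0)
  both <- bind_rows(d1, d2)
  if (nrow(both) == 0) {
    out <- tibble(chrom = character(), start = integer(), end = integer(),
                  n_cpgs = integer(), direction = character(),
                  q_max = numeric(), found_in = character())
    class(out) <- c("dmr_set", class(out))
    return(out)
  }
  out <- both |>
    group_by(.data$chrom, .data$direction) |>
    dplyr::group_modify(function(d, key) merge_genomic_union(d)) |>
    ungroup() |>
    select("chrom", "start", "end", "n_cpgs", "direction", "q_max",
           "found_in") |>
    arrange(.data$chrom, .data$start)
  class(out) <- c("dmr_set", class(out))
  out
}

# union-merge overlapping half-open intervals within one chromosome/direction;
# q_max is the max over merged members, n_cpgs the max (recounted later when
# CpG positions are available)
merge_genomic_union <- function(d) {
  d <- d[order(d$start), , drop = FALSE]
  grp <- cumsum(c(1, as.integer(d$start[-1] >= cummax(d$end)[-nrow(d)])))
  d |>
    mutate(.g = grp) |>
    group_by(.data$.g) |>
    summarise(start = min(.data$start), end = max(.data$end),
              n_cpgs = max(.data$n_cpgs), q_max = max(.data$q_max),
              found_in = if (length(unique(.data$run)) > 1) "both" else
                unique(.data$run),
              .groups = "drop") |>
    select(-".g")
}

#' Intersect two DMR lists to find hominin-specific DMRs
#'
#' A DMR specific to one hominin must be detected both against the second and
#' against the third hominin; only the overlapping portion of the two source
#' DMRs is taken (half-open interval intersection), the direction of the two
#' sources must agree, the portion's CpG count is re-checked against
#' `min_cpgs`, and its score is the minimum of the two source scores.
#'
#' @param dmrs_1v2,dmrs_1v3 `dmr_set` tibbles from two comparisons sharing
#'   hominin 1, both oriented relative to hominin 1.
#' @param cpg_positions Tibble `chrom`, `pos` used to re-count CpGs in the
#'   overlapping portions.
#' @param min_cpgs Minimum CpGs in a surviving portion.
#' @return A `dmr_set` tibble of hominin-1-specific DMRs.
#' @export
three_way_intersect <- function(dmrs_1v2, dmrs_1v3, cpg_positions,
                                min_cpgs = 50) {
  if (nrow(dmrs_1v2) == 0 || nrow(dmrs_1v3) == 0) {
    out <- tibble(chrom = character(), start = integer(), end = integer(),
                  n_cpgs = integer(), direction = character(),
                  q_max = numeric())
    class(out) <- c("dmr_set", class(out))
    return(out)
  }
  j <- inner_join(as_tibble(dmrs_1v2), as_tibble(dmrs_1v3),
                  by = "chrom", suffix = c("_a", "_b"),
                  relationship = "many-to-many") |>
    filter(.data$start_a < .data$end_b, .data$start_b < .data$end_a)
  conflicts <- j |> filter(.data$direction_a != .data$direction_b)
  if (nrow(conflicts) > 0) {
    inform(sprintf("%d overlapping DMR pair(s) dropped for direction conflict",
                   nrow(conflicts)))
  }
  out <- j |>
    filter(.data$direction_a == .data$direction_b) |>
    mutate(start = pmax(.data$start_a, .data$start_b),
           end = pmin(.data$end_a, .data$end_b),
           q_max = pmin(.data$q_max_a, .data$q_max_b),
           direction = .data$direction_a) |>
    select("chrom", "start", "end", "direction", "q_max")
  out$n_cpgs <- count_cpgs_in(out, cpg_positions)
  out <- out |>
    filter(.data$n_cpgs >= min_cpgs) |>
    select("chrom", "start", "end", "n_cpgs", "direction", "q_max") |>
    arrange(.data$chrom, .data$start)
  class(out) <- c("dmr_set", class(out))
  out
}

count_cpgs_in <- function(intervals, cpg_positions) {
  vapply(seq_len(nrow(intervals)), function(k) {
    p <- cpg_positions$pos[cpg_positions$chrom == intervals$chrom[k]]
    sum(p >= intervals$start[k] & p < intervals$end[k])
  }, numeric(1)) |> as.integer()
}

#' Adjust array-measured DMR methylation for probe placement
#'
#' Methylation-array probes cover only part of a DMR's CpGs, so the raw
#' probe mean `m` is corrected by how representative the probed positions are
#' in a full (WGBS) reference map over the same DMR:
#' \deqn{m' = \min(m \cdot \bar\psi_{all} / \bar\psi_{probed},\ 1)}
#' where the ratio compares the reference's mean methylation over all DMR
#' CpGs with its mean over the probed CpGs only. When the probes are
#' representative the ratio is 1 and \eqn{m' = m}.
#'
#' @param m Mean methylation over the probes in the DMR.
#' @param ref_mean_all Reference mean methylation over all DMR CpGs.
#' @param ref_mean_probed Reference mean methylation over the probed CpGs.
#' @return Corrected methylation in \[0, 1\]; falls back to `m` (with a
#'   warning attribute) when `ref_mean_probed` is 0.
#' @export
#' @examples
#' adjust_array_methylation(0.4, ref_mean_all = 0.6, ref_mean_probed = 0.3)
adjust_array_methylation <- function(m, ref_mean_all, ref_mean_probed) {
  ifelse(is.na(ref_mean_probed) | ref_mean_probed <= 0, m,
         pmin(m * ref_mean_all / ref_mean_probed, 1))
}

#' Assign DMRs to the lineage where the methylation change occurred
#'
#' Polarizes hominin-specific DMRs with the chimpanzee outgroup by parsimony.
#' For each DMR, the distance of hominin H to the chimpanzee is the mean
#' absolute per-CpG methylation difference over the sites shared by the two
#' maps. For an AMH-specific DMR: if both archaic hominins are closer to the
#' chimpanzee the DMR arose on the AMH branch; if the AMH is closer than both
#' it arose in the archaic ancestor; otherwise it is discarded as
#' inconclusive. A Neanderthal-(or Denisovan-)specific DMR is assigned to
#' that branch only if both other hominins are closer to the chimpanzee, and
#' discarded otherwise. DMRs with too few chimpanzee-covered CpGs are
#' discarded as `no_outgroup_data`. In strict mode, chimpanzee array samples
#' (probe means corrected via [adjust_array_methylation()]) contribute
#' DMR-level distances averaged with the per-site WGBS distance.
#'
#' @param dmrs A `dmr_set` with a `specific_to` column naming the hominin the
#'   DMR discriminates (`"AMH"`, `"Neanderthal"`, `"Denisovan"`).
#' @param panel A `sample_panel` whose reconstructed core samples carry
#'   `methylation` tracks (see [simulate_panel()] / [run_pipeline()]).
#' @param strict Use chimpanzee array samples in addition to the WGBS map.
#' @param min_shared_cpgs Minimum chimpanzee-covered CpGs per DMR (default
#'   10).
#' @return The input tibble with added columns `lineage`
#'   (`"AMH"`, `"archaic"`, `"Neanderthal"`, `"Denisovan"`, or `NA` for
#'   discarded DMRs) and `assign_status`
#'   (`"assigned"`/`"inconclusive"`/`"no_outgroup_data"`).
#' @export
assign_lineage <- function(dmrs, panel, strict = FALSE,
                           min_shared_cpgs = 10) {
  core <- panel[panel$core, ]
  core_by_group <- stats::setNames(core$methylation, core$group)
  chimp_wgbs <- panel$methylation[panel$group == "chimpanzee" &
                                    panel$technology == "WGBS"][[1]]
  chimp_arrays <- panel[panel$group == "chimpanzee" &
                          panel$technology %in% c("array450K", "array850K"), ]
  hominins <- c("AMH", "Neanderthal", "Denisovan")
  lineage <- character(nrow(dmrs))
  status <- character(nrow(dmrs))
  for (k in seq_len(nrow(dmrs))) {
    iv <- dmrs[k, ]
    chimp_sites <- track_in_interval(chimp_wgbs, iv)
    if (nrow(chimp_sites) < min_shared_cpgs) {
      lineage[k] <- NA_character_
      status[k] <- "no_outgroup_data"
      next
    }
    d <- vapply(hominins, function(h) {
      hs <- track_in_interval(core_by_group[[h]], iv)
      shared <- inner_join(hs, chimp_sites, by = c("chrom", "pos"),
                           suffix = c("_h", "_c"))
      if (nrow(shared) < min_shared_cpgs) return(NA_real_)
      mean(abs(shared$methylation_h - shared$methylation_c))
    }, numeric(1))
    if (strict && nrow(chimp_arrays) > 0) {
      d_arr <- chimp_array_distances(iv, chimp_arrays, panel, core_by_group,
                                     hominins)
      d <- stats::setNames(ifelse(is.na(d_arr), d, (d + d_arr) / 2),
                           hominins)
    }
    if (anyNA(d)) {
      lineage[k] <- NA_character_
      status[k] <- "no_outgroup_data"
      next
    }
    h1 <- iv$specific_to
    others <- setdiff(hominins, h1)
    if (all(d[others] < d[h1])) {
      lineage[k] <- if (h1 == "AMH") "AMH" else h1
      status[k] <- "assigned"
    } else if (h1 == "AMH" && all(d[h1] < d[others])) {
      lineage[k] <- "archaic"
      status[k] <- "assigned"
    } else {
      lineage[k] <- NA_character_
      status[k] <- "inconclusive"
    }
  }
  dmrs$lineage <- lineage
  dmrs$assign_status <- status
  dmrs
}

track_in_interval <- function(track, iv) {
  track |>
    filter(.data$chrom == iv$chrom, .data$pos >= iv$start,
           .data$pos < iv$end)
}

# DMR-level |mean_H - m'| distances from chimpanzee array samples, averaged
# over arrays covering the DMR; NA when no probes fall inside.
chimp_array_distances <- function(iv, chimp_arrays, panel, core_by_group,
                                  hominins) {
  per_array <- purrr::map(seq_len(nrow(chimp_arrays)), function(a) {
    probes <- track_in_interval(chimp_arrays$methylation[[a]], iv)
    if (nrow(probes) == 0) return(NULL)
    ref_id <- chimp_arrays$full_map_ref[a]
    ref <- panel$methylation[panel$id == ref_id][[1]]
    ref_all <- track_in_interval(ref, iv)
    ref_probed <- ref_all[ref_all$pos %in% probes$pos, ]
    m_adj <- adjust_array_methylation(
      mean(probes$methylation),
      ref_mean_all = mean(ref_all$methylation),
      ref_mean_probed = mean(ref_probed$methylation)
    )
    vapply(hominins, function(h) {
      hs <- track_in_interval(core_by_group[[h]], iv)
      if (nrow(hs) == 0) return(NA_real_)
      abs(mean(hs$methylation) - m_adj)
    }, numeric(1))
  })
  per_array <- per_array[!vapply(per_array, is.null, logical(1))]
  if (length(per_array) == 0) {
    return(stats::setNames(rep(NA_real_, length(hominins)), hominins))
  }
  colMeans(do.call(rbind, per_array), na.rm = TRUE)
}

#' Filter out DMRs with high within-group variability
#'
#' A lineage-assigned DMR is kept (deemed fixed) only if every sample of the
#' derived group lies strictly outside the range of DMR-mean methylation of
#' all comparison-group samples, with all derived samples on the same side of
#' that range. Comparison samples are every panel sample outside the derived
#' group (including low-resolution reconstructed samples and, in strict mode,
#' array samples with Eq.-style probe correction); samples with no data over
#' the DMR are excluded with a note. Ties with the comparison range discard
#' the DMR (conservative).
#'
#' @param dmrs A `dmr_set` with a `lineage` column.
#' @param panel A `sample_panel` with per-sample `methylation` tracks (and
#'   probe tracks for array samples).
#' @param strict Include array samples (default `FALSE`: only WGBS and
#'   reconstructed maps, preserving an unbiased genomic distribution).
#' @param min_gap Fixation margin: minimum distance between every derived
#'   sample and the comparison range (default 0, the plain range-exclusion
#'   rule; the pipeline passes the detector's excursion-level consistency
#'   difference so that a fixed DMR must separate the groups by a magnitude
#'   consistent with the DMR definition, not merely by a tie-break).
#' @return The input tibble with added logical column `fixed` and list-column
#'   `sample_means` (per-sample DMR means used for the decision).
#' @export
variability_filter <- function(dmrs, panel, strict = FALSE, min_gap = 0) {
  derived_groups <- list(
    AMH = "AMH", archaic = c("Neanderthal", "Denisovan"),
    Neanderthal = "Neanderthal", Denisovan = "Denisovan"
  )
  use <- panel$technology %in% c("reconstructed", "WGBS") |
    (strict & panel$technology %in% c("array450K", "array850K", "RRBS"))
  sub <- panel[use, ]
  fixed <- logical(nrow(dmrs))
  means_list <- vector("list", nrow(dmrs))
  for (k in seq_len(nrow(dmrs))) {
    iv <- dmrs[k, ]
    mm <- sample_dmr_means(iv, sub, panel)
    means_list[[k]] <- mm
    lin <- iv$lineage
    if (is.na(lin)) {
      fixed[k] <- FALSE
      next
    }
    dg <- derived_groups[[lin]]
    der <- mm$mean[mm$group %in% dg]
    cmp <- mm$mean[!(mm$group %in% dg)]
    if (length(der) == 0 || length(cmp) == 0) {
      fixed[k] <- FALSE
      next
    }
    fixed[k] <- all(der > max(cmp) + min_gap) || all(der < min(cmp) - min_gap)
  }
  dmrs$fixed <- fixed
  dmrs$sample_means <- means_list
  dmrs
}

# Per-sample mean methylation over a DMR. Reconstructed samples use the
# pooled C->T ratio over the interval rescaled by their mu100 (the
# variance-optimal DMR-level estimate, free of smoothing-window edge
# effects); WGBS samples pool read counts; array samples are probe means
# with the representativeness correction against their full-map reference.
sample_dmr_means <- function(iv, sub, panel) {
  mm <- purrr::map_dfr(seq_len(nrow(sub)), function(i) {
    tech <- sub$technology[i]
    if (tech == "reconstructed" && !is.null(sub$counts[[i]]) &&
        !is.null(attr(sub$methylation[[i]], "mu100"))) {
      cc <- track_in_interval(sub$counts[[i]], iv)
      n_tot <- sum(cc$c_count + cc$t_count)
      if (nrow(cc) == 0 || n_tot == 0) return(NULL)
      m <- min(sum(cc$t_count) / n_tot / attr(sub$methylation[[i]], "mu100"),
               1)
      return(tibble(id = sub$id[i], group = sub$group[i], mean = m))
    }
    if (tech == "WGBS" && !is.null(sub$meth_counts[[i]])) {
      cc <- track_in_interval(sub$meth_counts[[i]], iv)
      n_tot <- sum(cc$meth_count + cc$unmeth_count)
      if (nrow(cc) == 0 || n_tot == 0) return(NULL)
      return(tibble(id = sub$id[i], group = sub$group[i],
                    mean = sum(cc$meth_count) / n_tot))
    }
    tr <- sub$methylation[[i]]
    if (is.null(tr)) return(NULL)
    x <- track_in_interval(tr, iv)
    if (nrow(x) == 0) return(NULL)
    m <- mean(x$methylation)
    if (tech %in% c("array450K", "array850K", "RRBS") &&
        !is.na(sub$full_map_ref[i])) {
      ref <- panel$methylation[panel$id == sub$full_map_ref[i]][[1]]
      ref_all <- track_in_interval(ref, iv)
      if (nrow(ref_all) > 0) {
        ref_probed <- ref_all[ref_all$pos %in% x$pos, ]
        m <- adjust_array_methylation(m, mean(ref_all$methylation),
                                      mean(ref_probed$methylation))
      }
    }
    tibble(id = sub$id[i], group = sub$group[i], mean = m)
  })
  mm
}
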