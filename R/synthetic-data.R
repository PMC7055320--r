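#' Simulation configuration for synthetic hominin methylomes
#'
#' Bundles every parameter of the synthetic-data generator: the CpG position
#' model, the baseline (ancestral) methylome, per-sample coverage and
#' deamination rates, the planted lineage-specific differentially methylated
#' regions (DMRs), and within-group variability. The defaults reproduce the
#' study design the detection pipeline assumes: a four-taxon panel
#' (anatomically modern humans, Neanderthal, Denisovan, chimpanzee outgroup)
#' with three high-quality reconstructed "core" methylomes, additional
#' whole-genome bisulfite (WGBS), reconstructed, and methylation-array samples
#' used for filtering, and planted group-specific methylation shifts.
#'
#' @param n_chromosomes Number of chromosomes to simulate.
#' @param cpgs_per_chromosome Number of CpG sites per chromosome.
#' @param spacing Inter-CpG spacing model: a list with `dist` (`"geometric"` or
#'   `"constant"`) and `mean` (nucleotides between consecutive CpGs).
#' @param baseline Baseline methylation model: the genome alternates between
#'   highly methylated background blocks (per-site beta draws centred at
#'   `mean_high`) and unmethylated island blocks (centred at `mean_low`),
#'   with geometric block lengths of means `block_high` and `block_low` CpGs.
#'   The defaults give a bimodal per-site distribution with ~80% of CpGs in
#'   the methylated state and a genome-wide mean of ~0.75 (the typical mean
#'   of a bone WGBS methylome), with the regional (blocky) structure of real
#'   methylomes that makes a smoothed reference map meaningful.
#' @param coverage Read-coverage model: a list with `dist` (`"nbinom"` or
#'   `"constant"`), `mean`, and (for `"nbinom"`) `size` (dispersion).
#' @param pi_default Default per-sample deamination rate for reconstructed
#'   (ancient) samples: the probability that a methylated cytosine is read as
#'   thymine.
#' @param planted_dmrs Tibble describing planted DMRs: columns `lineage`
#'   (`"AMH"`, `"Neanderthal"`, `"Denisovan"`, or `"archaic"`), `span_cpgs`,
#'   `delta` (true methylation shift), `direction` (`"hyper"`/`"hypo"`).
#'   `NULL` plants the default 10 60-CpG shifts of 0.6 per lineage.
#' @param within_group_sd Standard deviation of per-sample offsets on the logit
#'   scale, modelling within-group (inter-individual) variability.
#' @param probe_fraction Fraction of CpGs carried by simulated methylation
#'   arrays.
#' @param samples Sample roster tibble (id, group, tissue, sex, age_class,
#'   technology, pi, core, full_map_ref); `NULL` uses the default panel.
#' @param seed Integer master seed; identical config + seed gives identical
#'   output.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_chromosomes = 1, cpgs_per_chromosome = 500)
#' cfg$planted_dmrs
sim_config <- function(n_chromosomes = 2,
                       cpgs_per_chromosome = 20000,
                       spacing = list(dist = "geometric", mean = 20),
                       baseline = list(mean_low = 0.05, mean_high = 0.92,
                                       block_low = 40, block_high = 160,
                                       concentration = 30),
                       coverage = list(dist = "nbinom", mean = 30, size = 5),
                       pi_default = 0.05,
                       planted_dmrs = NULL,
                       within_group_sd = 0.15,
                       probe_fraction = 0.05,
                       samples = NULL,
                       seed = 1) {
  if (is.null(planted_dmrs)) {
    planted_dmrs <- tidyr::expand_grid(
      lineage = c("AMH", "Neanderthal", "Denisovan", "archaic"),
      idx = seq_len(10)
    ) |>
      mutate(span_cpgs = 60,
             delta = 0.6,
             direction = ifelse(.data$idx %% 2 == 1, "hyper", "hypo")) |>
      select(-"idx")
  }
  planted_dmrs <- as_tibble(planted_dmrs)
  stopifnot_cols(planted_dmrs, c("lineage", "span_cpgs", "delta", "direction"),
                 "planted_dmrs")
  if (any(planted_dmrs$delta <= 0 | planted_dmrs$delta >= 1)) {
    abort("planted delta must be in (0, 1)")
  }
  if (is.null(samples)) samples <- default_sample_roster(pi_default)
  samples <- as_tibble(samples)
  stopifnot_cols(samples, c("id", "group", "technology"), "samples")
  if (!"pi" %in% names(samples)) samples$pi <- pi_default
  if (!"core" %in% names(samples)) {
    samples$core <- samples$technology == "reconstructed"
  }
  if (any(samples$pi <= 0 | samples$pi >= 1)) abort("all pi must be in (0, 1)")
  if (anyDuplicated(samples$id)) abort("sample ids must be unique")
  structure(list(
    n_chromosomes = n_chromosomes,
    cpgs_per_chromosome = cpgs_per_chromosome,
    spacing = spacing,
    baseline = baseline,
    coverage = coverage,
    pi_default = pi_default,
    planted_dmrs = planted_dmrs,
    within_group_sd = within_group_sd,
    probe_fraction = probe_fraction,
    samples = samples,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# The default roster mirrors the study design: three reconstructed core
# methylomes (one per hominin), WGBS + reconstructed + 450K-array modern human
# samples and a low-coverage Neanderthal for variability filtering, and a
# chimpanzee outgroup (WGBS + 850K arrays).
default_sample_roster <- function(pi_default = 0.05) {
  tibble(
    id = c("amh_core", "bone1", "bone2", "amh_skull", "amh_array1",
           "amh_array2", "amh_array3", "nea_core", "nea_lowcov", "den_core",
           "chimp_wgbs", "chimp_array1", "chimp_array2"),
    group = c(rep("AMH", 7), "Neanderthal", "Neanderthal", "Denisovan",
              rep("chimpanzee", 3)),
    tissue = c("femur", "femur", "femur", "skull", "femur", "femur", "femur",
               "phalanx", "femur", "phalanx", "rib", "femur", "femur"),
    sex = c("M", "F", "F", "M", "F", "M", "F", "F", "F", "F", "F", "M", "F"),
    age_class = c("adult", "adult", "adult", "juvenile", "adult", "adult",
                  "adult", "adult", "adult", "juvenile", "adult", "adult",
                  "adult"),
    technology = c("reconstructed", "WGBS", "WGBS", "reconstructed",
                   "array450K", "array450K", "array450K", "reconstructed",
                   "reconstructed", "reconstructed", "WGBS", "array850K",
                   "array850K"),
    pi = pi_default,
    core = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE,
             TRUE, FALSE, FALSE, FALSE),
    full_map_ref = c(NA, NA, NA, NA, "bone2", "bone2", "bone2", NA, NA, NA,
                     NA, "chimp_wgbs", "chimp_wgbs")
  )
}

#' Generate ordered CpG positions
#'
#' Draws inter-CpG spacings from the configured model and accumulates them into
#' strictly increasing 0-based positions per chromosome.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `chrom`, `pos`.
#' @export
#' @examples
#' generate_cpg_positions(sim_config(n_chromosomes = 1,
#'                                   cpgs_per_chromosome = 10))
generate_cpg_positions <- function(config) {
  with_rng(config$seed, {
    purrr::map_dfr(seq_len(config$n_chromosomes), function(ch) {
      n <- config$cpgs_per_chromosome
      inc <- draw_spacings(n - 1, config$spacing)
      tibble(chrom = paste0("chr", ch), pos = cumsum(c(0, inc)))
    })
  })
}

draw_spacings <- function(n, spacing) {
  if (n <= 0) return(integer(0))
  if (spacing$dist == "constant") {
    inc <- rep(as.integer(spacing$mean), n)
  } else if (spacing$dist == "geometric") {
    # 1 + geometric: spacings are always positive
    inc <- 1L + stats::rgeom(n, prob = 1 / spacing$mean)
  } else {
    abort(sprintf("unknown spacing model '%s'", spacing$dist))
  }
  # bounded redraw guard for degenerate user-supplied models
  bad <- which(inc <= 0)
  tries <- 0
  while (length(bad) > 0 && tries < 100) {
    inc[bad] <- 1L + stats::rgeom(length(bad), prob = 1 / spacing$mean)
    bad <- which(inc <= 0)
    tries <- tries + 1
  }
  if (length(bad) > 0) abort("spacing model keeps producing non-positive draws")
  inc
}

#' Generate per-sample true methylomes with planted lineage-specific DMRs
#'
#' Draws a baseline (ancestral) methylome from the bimodal mixture, places the
#' configured non-overlapping DMRs, and applies the planted methylation shift
#' to every sample of the derived lineage (`"archaic"` shifts both Neanderthal
#' and Denisovan). Inside a planted region the pre-shift baseline is reset to
#' 0.2 (hyper) or 0.8 (hypo) so the full shift fits in \[0, 1\]. Within-group
#' variability is modelled as one per-sample offset on the logit scale.
#'
#' @param config A [sim_config()].
#' @param positions CpG positions from [generate_cpg_positions()].
#' @return A list with `true_methylation` (named list of per-sample tibbles
#'   `chrom`, `pos`, `methylation`) and `truth` (tibble of planted intervals:
#'   `chrom`, `start`, `end`, `cpg_start`, `cpg_end`, `n_cpgs`, `lineage`,
#'   `direction`, `delta_true`).
#' @export
generate_lineage_methylomes <- function(config, positions) {
  n_sites <- nrow(positions)
  with_rng(config$seed + 1, {
    base <- draw_baseline(n_sites, config$baseline)
    plan <- place_planted_dmrs(config, positions)
    # Each planted DMR sits inside a homogeneous baseline domain extending
    # `flank` CpGs beyond the shifted span (a DMR lives within a coherent
    # regulatory region, not at a block boundary); the regional pre-shift
    # baseline of 0.2 (hyper) / 0.8 (hypo) also keeps the full shift in [0,1].
    flank <- 30L
    for (k in seq_len(nrow(plan))) {
      idx <- max(plan$row_start[k] - flank, 1):min(plan$row_end[k] + flank,
                                                   n_sites)
      base[idx] <- if (plan$direction[k] == "hyper") 0.2 else 0.8
    }
    lineage_groups <- list(
      AMH = "AMH", Neanderthal = "Neanderthal", Denisovan = "Denisovan",
      archaic = c("Neanderthal", "Denisovan")
    )
    groups <- unique(config$samples$group)
    group_meth <- lapply(groups, function(g) {
      m <- base
      for (k in seq_len(nrow(plan))) {
        if (g %in% lineage_groups[[plan$lineage[k]]]) {
          idx <- plan$row_start[k]:plan$row_end[k]
          shift <- if (plan$direction[k] == "hyper") plan$delta[k] else
            -plan$delta[k]
          m[idx] <- clamp(m[idx] + shift)
        }
      }
      m
    })
    names(group_meth) <- groups
    offsets <- stats::rnorm(nrow(config$samples), 0, config$within_group_sd)
    true_meth <- purrr::map(seq_len(nrow(config$samples)), function(i) {
      g <- config$samples$group[i]
      m <- group_meth[[g]]
      m <- inv_logit(logit(clamp(m, 1e-4, 1 - 1e-4)) + offsets[i])
      tibble(chrom = positions$chrom, pos = positions$pos, methylation = m)
    })
    names(true_meth) <- config$samples$id
    truth <- plan |>
      mutate(start = positions$pos[.data$row_start],
             end = positions$pos[.data$row_end] + 1L,
             n_cpgs = .data$row_end - .data$row_start + 1L) |>
      select("chrom", "start", "end", cpg_start = "row_start",
             cpg_end = "row_end", "n_cpgs", "lineage", "direction",
             delta_true = "delta")
    list(true_methylation = true_meth, truth = truth)
  })
}

draw_baseline <- function(n, b) {
  conc <- b$concentration
  # alternating methylated background / unmethylated island blocks with
  # geometric lengths; per-site beta noise around the block state
  hi_state <- stats::runif(1) < b$block_high / (b$block_high + b$block_low)
  hi <- logical(n)
  i <- 1
  while (i <= n) {
    len <- 1L + stats::rgeom(1, 1 / if (hi_state) b$block_high else b$block_low)
    j <- min(i + len - 1, n)
    hi[i:j] <- hi_state
    hi_state <- !hi_state
    i <- j + 1
  }
  m <- numeric(n)
  if (any(hi)) {
    m[hi] <- stats::rbeta(sum(hi), b$mean_high * conc,
                          (1 - b$mean_high) * conc)
  }
  if (any(!hi)) {
    m[!hi] <- stats::rbeta(sum(!hi), b$mean_low * conc,
                           (1 - b$mean_low) * conc)
  }
  m
}

# Non-overlapping placement of planted DMRs by rejection sampling over CpG
# indices. The guard margin keeps planted regions (and their homogeneous
# flanks) well separated so two neighbouring planted differences cannot fuse
# into a single detected excursion.
place_planted_dmrs <- function(config, positions, margin = 300) {
  plan <- config$planted_dmrs
  if (nrow(plan) == 0) {
    return(tibble(chrom = character(), row_start = integer(),
                  row_end = integer(), lineage = character(),
                  direction = character(), delta = numeric()))
  }
  n_per_chrom <- config$cpgs_per_chromosome
  chroms <- unique(positions$chrom)
  taken <- list()
  out <- vector("list", nrow(plan))
  for (k in seq_len(nrow(plan))) {
    span <- plan$span_cpgs[k]
    ok <- FALSE
    for (try in seq_len(1000)) {
      ch <- sample(chroms, 1)
      lo <- sample.int(n_per_chrom - span - 2 * margin, 1) + margin
      hi <- lo + span - 1
      clash <- any(vapply(taken[[ch]] %||% list(), function(iv) {
        lo <= iv[2] + margin && hi >= iv[1] - margin
      }, logical(1)))
      if (!clash) {
        taken[[ch]] <- c(taken[[ch]], list(c(lo, hi)))
        ok <- TRUE
        break
      }
    }
    if (!ok) abort("could not place planted DMRs without overlap; reduce count or span")
    offset <- (match(ch, chroms) - 1) * n_per_chrom
    out[[k]] <- tibble(chrom = ch, row_start = offset + lo,
                       row_end = offset + hi, lineage = plan$lineage[k],
                       direction = plan$direction[k], delta = plan$delta[k])
  }
  bind_rows(out)
}

#' Simulate a deamination count map from a true methylome
#'
#' Post-mortem deamination converts methylated cytosines to thymines, so at a
#' CpG with true methylation \eqn{\psi_i}, coverage \eqn{n_i}, and deamination
#' rate \eqn{\pi}, the observed thymine count is binomial:
#' \eqn{t_i \sim B(n_i, \pi\psi_i)}.
#'
#' @param true_methylation Tibble `chrom`, `pos`, `methylation`.
#' @param coverage Coverage model list (see [sim_config()]), or a single number
#'   for constant coverage.
#' @param pi Deamination rate in (0, 1).
#' @param seed Optional seed.
#' @return A count track tibble: `chrom`, `pos`, `c_count`, `t_count`. Sites
#'   with zero coverage have both counts zero.
#' @export
#' @examples
#' m <- tibble::tibble(chrom = "chr1", pos = 0:9, methylation = 0.8)
#' simulate_deamination(m, coverage = 30, pi = 0.05, seed = 1)
simulate_deamination <- function(true_methylation, coverage, pi, seed = NULL) {
  if (pi <= 0 || pi >= 1) abort("pi must be in (0, 1)")
  stopifnot_cols(true_methylation, c("chrom", "pos", "methylation"))
  psi <- clamp(true_methylation$methylation)
  n_sites <- length(psi)
  with_rng(seed, {
    n <- draw_coverage(n_sites, coverage)
    t_cnt <- stats::rbinom(n_sites, n, pi * psi)
    tibble(chrom = true_methylation$chrom, pos = true_methylation$pos,
           c_count = n - t_cnt, t_count = t_cnt)
  })
}

draw_coverage <- function(n_sites, coverage) {
  if (is.numeric(coverage) && length(coverage) == 1) {
    return(rep(as.integer(coverage), n_sites))
  }
  if (coverage$dist == "constant") {
    rep(as.integer(coverage$mean), n_sites)
  } else if (coverage$dist == "nbinom") {
    stats::rnbinom(n_sites, mu = coverage$mean, size = coverage$size)
  } else {
    abort(sprintf("unknown coverage model '%s'", coverage$dist))
  }
}

#' Subsample array-style probes from a methylation track
#'
#' Emulates methylation-array coverage: probes are a subset of CpG positions
#' carrying (optionally noisy) beta values. With `bias_unmethylated = TRUE`,
#' probe placement is skewed towards unmethylated sites, reproducing the
#' RRBS-style ascertainment bias.
#'
#' @param track Tibble `chrom`, `pos`, `methylation`.
#' @param probe_fraction Fraction of CpGs to retain, in (0, 1\].
#' @param seed Optional seed.
#' @param noise_sd Gaussian measurement noise added to beta values (clamped to
#'   \[0, 1\]).
#' @param bias_unmethylated Skew sampling towards low-methylation sites.
#' @return A tibble `chrom`, `pos`, `methylation` (probes only).
#' @export
subsample_array_probes <- function(track, probe_fraction, seed = NULL,
                                   noise_sd = 0, bias_unmethylated = FALSE) {
  if (probe_fraction <= 0 || probe_fraction > 1) {
    abort("probe_fraction must be in (0, 1]")
  }
  stopifnot_cols(track, c("chrom", "pos", "methylation"))
  n <- nrow(track)
  k <- max(1L, round(probe_fraction * n))
  with_rng(seed, {
    w <- if (bias_unmethylated) (1 - track$methylation) + 0.05 else rep(1, n)
    idx <- sort(sample.int(n, k, prob = w))
    out <- track[idx, c("chrom", "pos", "methylation")]
    if (noise_sd > 0) {
      out$methylation <- clamp(out$methylation + stats::rnorm(k, 0, noise_sd))
    }
    out
  })
}

#' Simulate a complete sample panel
#'
#' Runs the whole generator: CpG positions, lineage methylomes with planted
#' DMRs, and per-sample data by technology (deamination counts for
#' reconstructed samples, read counts and measured methylation for WGBS,
#' probe subsets for arrays). The planted truth is attached as
#' `attr(panel, "truth")` and CpG positions as `attr(panel, "positions")`.
#'
#' @param config A [sim_config()].
#' @return A `sample_panel` tibble: one row per sample with metadata columns
#'   and list-columns `counts` (reconstructed samples), `meth_counts` (WGBS
#'   read counts: `meth_count`, `unmeth_count`), `methylation` (measured
#'   methylation for WGBS/array samples), and `true_methylation`.
#' @export
#' @examples
#' cfg <- sim_config(n_chromosomes = 1, cpgs_per_chromosome = 2000,
#'                   planted_dmrs = tibble::tibble(lineage = "AMH",
#'                     span_cpgs = 60, delta = 0.6, direction = "hyper"))
#' panel <- simulate_panel(cfg)
#' attr(panel, "truth")
simulate_panel <- function(config) {
  positions <- generate_cpg_positions(config)
  gm <- generate_lineage_methylomes(config, positions)
  samples <- config$samples
  seeds <- derive_seeds(config$seed + 2, nrow(samples))
  counts <- vector("list", nrow(samples))
  meth_counts <- vector("list", nrow(samples))
  meth <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    tm <- gm$true_methylation[[samples$id[i]]]
    tech <- samples$technology[i]
    if (tech == "reconstructed") {
      counts[[i]] <- simulate_deamination(tm, config$coverage, samples$pi[i],
                                          seed = seeds[i])
    } else if (tech %in% c("WGBS", "RRBS")) {
      tr <- if (tech == "RRBS") {
        subsample_array_probes(tm, 0.1, seed = seeds[i] + 1,
                               bias_unmethylated = TRUE)
      } else tm
      cc <- with_rng(seeds[i], {
        n <- draw_coverage(nrow(tr), config$coverage)
        n <- pmax(n, 1L)  # bisulfite maps report only covered sites
        mc <- stats::rbinom(nrow(tr), n, clamp(tr$methylation))
        tibble(chrom = tr$chrom, pos = tr$pos, meth_count = mc,
               unmeth_count = n - mc)
      })
      meth_counts[[i]] <- cc
      meth[[i]] <- tibble(chrom = cc$chrom, pos = cc$pos,
                          methylation = cc$meth_count /
                            (cc$meth_count + cc$unmeth_count))
    } else if (tech %in% c("array450K", "array850K")) {
      meth[[i]] <- subsample_array_probes(tm, config$probe_fraction,
                                          seed = seeds[i], noise_sd = 0.02)
    } else {
      abort(sprintf("unknown technology '%s'", tech))
    }
  }
  panel <- samples |>
    mutate(counts = counts, meth_counts = meth_counts, methylation = meth,
           true_methylation = unname(gm$true_methylation[samples$id]))
  attr(panel, "truth") <- gm$truth
  attr(panel, "positions") <- positions
  attr(panel, "config") <- config
  class(panel) <- c("sample_panel", class(panel))
  panel
}
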