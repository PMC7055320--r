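#' Methylation-array beta value
#'
#' \eqn{\beta} = methylated signal / (methylated + unmethylated signal).
#'
#' @param methylated,unmethylated Non-negative signal intensities (vectors).
#' @return Beta values in \[0, 1\]; `NA` where the total signal is zero (such
#'   sites are dropped downstream).
#' @export
#' @examples
#' beta_value(3, 1)
beta_value <- function(methylated, unmethylated) {
  if (any(methylated < 0 | unmethylated < 0, na.rm = TRUE)) {
    abort("signals must be non-negative")
  }
  total <- methylated + unmethylated
  ifelse(total > 0, methylated / total, NA_real_)
}

#' Density of differentially methylated CpGs along the genome
#'
#' Computes, per window, the fraction of CpGs that fall inside any DMR.
#' `"dmr_centered"` uses one window of `window_size` nucleotides centred on
#' the midpoint of each DMR; `"tiled"` partitions each chromosome into
#' non-overlapping windows starting at position 0.
#'
#' @param dmrs DMR tibble (`chrom`, `start`, `end`).
#' @param cpg_positions Tibble `chrom`, `pos` of all CpGs.
#' @param mode `"dmr_centered"` or `"tiled"`.
#' @param window_size Window width in nucleotides (default 100 kb).
#' @return A tibble `chrom`, `window_start`, `window_end`, `n_cpgs`,
#'   `n_derived`, `fraction` (NA for windows containing no CpGs).
#' @export
derived_cpg_density <- function(dmrs, cpg_positions,
                                mode = c("dmr_centered", "tiled"),
                                window_size = 1e5) {
  mode <- match.arg(mode)
  stopifnot_cols(cpg_positions, c("chrom", "pos"))
  in_dmr <- function(chrom, pos) {
    hit <- rep(FALSE, length(pos))
    d <- dmrs[dmrs$chrom == chrom[1], , drop = FALSE]
    for (k in seq_len(nrow(d))) {
      hit <- hit | (pos >= d$start[k] & pos < d$end[k])
    }
    hit
  }
  windows <- if (mode == "dmr_centered") {
    mid <- (dmrs$start + dmrs$end) %/% 2
    tibble(chrom = dmrs$chrom,
           window_start = pmax(mid - window_size %/% 2, 0),
           window_end = pmax(mid - window_size %/% 2, 0) + window_size)
  } else {
    cpg_positions |>
      group_by(.data$chrom) |>
      summarise(max_pos = max(.data$pos), .groups = "drop") |>
      dplyr::reframe(window_start = seq(0, .data$max_pos, by = window_size),
                     .by = "chrom") |>
      mutate(window_end = .data$window_start + window_size)
  }
  purrr::map_dfr(seq_len(nrow(windows)), function(k) {
    w <- windows[k, ]
    p <- cpg_positions$pos[cpg_positions$chrom == w$chrom &
                             cpg_positions$pos >= w$window_start &
                             cpg_positions$pos < w$window_end]
    n_der <- if (length(p) > 0) sum(in_dmr(rep(w$chrom, length(p)), p)) else 0L
    tibble(chrom = w$chrom, window_start = w$window_start,
           window_end = w$window_end, n_cpgs = length(p),
           n_derived = as.integer(n_der),
           fraction = if (length(p) > 0) n_der / length(p) else NA_real_)
  })
}

#' Scan a DMR for windows where methylation tracks expression
#'
#' Slides overlapping windows of `window` CpGs across a DMR's per-tissue
#' methylation, computes Pearson's correlation between the window-mean
#' methylation and the expression of each candidate gene across tissues,
#' picks the window with the best absolute correlation per gene, and reports
#' its regression p-value. Benjamini-Hochberg adjustment across gene-level
#' best windows is applied by the caller or via `adjust = TRUE` (default)
#' across the genes tested here.
#'
#' @param methylation_by_tissue Tibble: `pos` plus one numeric column per
#'   tissue (per-CpG methylation of the DMR in that tissue).
#' @param expression Tibble: `gene` plus one numeric column per tissue
#'   (matching tissue column names).
#' @param window Window width in CpGs (default 25); DMRs with fewer CpGs use
#'   a single whole-DMR window.
#' @param adjust Apply BH adjustment across the genes tested.
#' @param min_tissues Minimum tissues with data (default 3).
#' @return A tibble `gene`, `window_start_idx`, `r`, `p`, `q` (one row per
#'   gene: its best window); genes with undefined correlation (zero variance)
#'   are skipped.
#' @export
methylation_expression_scan <- function(methylation_by_tissue, expression,
                                        window = 25, adjust = TRUE,
                                        min_tissues = 3) {
  stopifnot_cols(methylation_by_tissue, "pos")
  stopifnot_cols(expression, "gene")
  tissues <- intersect(setdiff(names(methylation_by_tissue), "pos"),
                       setdiff(names(expression), "gene"))
  if (length(tissues) < min_tissues) {
    abort(sprintf("need at least %d shared tissues", min_tissues))
  }
  n_cpg <- nrow(methylation_by_tissue)
  w <- min(window, n_cpg)
  starts <- seq_len(n_cpg - w + 1)
  meth_mat <- as.matrix(methylation_by_tissue[, tissues, drop = FALSE])
  win_means <- vapply(starts, function(s) {
    colMeans(meth_mat[s:(s + w - 1), , drop = FALSE])
  }, numeric(length(tissues)))
  if (is.null(dim(win_means))) win_means <- matrix(win_means, nrow = 1)
  res <- purrr::map_dfr(seq_len(nrow(expression)), function(g) {
    e <- as.numeric(unlist(expression[g, tissues]))
    ok <- is.finite(e)
    if (sum(ok) < min_tissues) return(NULL)
    best <- NULL
    for (s in seq_along(starts)) {
      m <- win_means[, s][ok]
      if (stats::sd(m) == 0 || stats::sd(e[ok]) == 0) next
      r <- stats::cor(m, e[ok])
      if (is.null(best) || abs(r) > abs(best$r)) {
        best <- list(s = starts[s], r = r, m = m)
      }
    }
    if (is.null(best)) return(NULL)
    fit <- suppressWarnings(summary(stats::lm(e[ok] ~ best$m)))
    p <- fit$coefficients[2, 4]
    tibble(gene = expression$gene[g], window_start_idx = best$s, r = best$r,
           p = p)
  })
  if (nrow(res) > 0 && adjust) {
    res$q <- stats::p.adjust(res$p, method = "BH")
  } else if (nrow(res) > 0) {
    res$q <- NA_real_
  }
  res
}

#' Term enrichment by the hypergeometric test
#'
#' For each annotation term, tests whether the query gene set contains more
#' term members than expected from their background frequency: the one-sided
#' upper-tail hypergeometric probability of drawing at least the observed
#' number of term genes in a query-sized sample from the background, with
#' Benjamini-Hochberg adjustment across terms.
#'
#' @param query_genes Character vector (must be a subset of the background).
#' @param background_genes Character vector (the gene universe).
#' @param annotation Tibble `gene`, `term` (one row per membership).
#' @return A tibble `term`, `n_query`, `n_background`, `fold`, `p`, `q`
#'   sorted by p.
#' @export
term_enrichment <- function(query_genes, background_genes, annotation) {
  if (length(query_genes) == 0) abort("query gene set is empty")
  if (!all(query_genes %in% background_genes)) {
    abort("query genes must be a subset of the background")
  }
  stopifnot_cols(annotation, c("gene", "term"))
  ann <- annotation |> filter(.data$gene %in% background_genes)
  n_bg <- length(unique(background_genes))
  n_q <- length(unique(query_genes))
  res <- ann |>
    group_by(.data$term) |>
    summarise(
      n_background = dplyr::n_distinct(.data$gene),
      n_query = dplyr::n_distinct(intersect(.data$gene, query_genes)),
      .groups = "drop"
    ) |>
    filter(.data$n_background > 0) |>
    mutate(
      fold = (.data$n_query / n_q) / (.data$n_background / n_bg),
      p = stats::phyper(.data$n_query - 1, .data$n_background,
                        n_bg - .data$n_background, n_q, lower.tail = FALSE),
      q = stats::p.adjust(.data$p, method = "BH")
    ) |>
    arrange(.data$p)
  res
}

#' Chi-square comparison of two annotation fractions
#'
#' Generic 2x2 (or 2xk) chi-square test of association between group
#' membership and annotation hits, e.g. comparing the fraction of
#' organ-associated genes among one DMR list's genes with that among another
#' list's.
#'
#' @param hits Integer vector of per-group hit counts.
#' @param totals Integer vector of per-group totals.
#' @return A tibble `statistic`, `df`, `p`, plus per-group `fraction`s in
#'   `attr(., "fractions")`.
#' @export
enrichment_chisq <- function(hits, totals) {
  if (length(hits) != length(totals) || length(hits) < 2) {
    abort("hits and totals must be equal-length vectors of at least 2 groups")
  }
  if (any(hits > totals)) abort("hits cannot exceed totals")
  tab <- rbind(hits, totals - hits)
  ct <- stats::chisq.test(tab)
  out <- tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
                p = ct$p.value)
  attr(out, "fractions") <- hits / totals
  out
}

#' Permutation test of DMR overlap with target intervals
#'
#' Tests whether DMRs overlap a set of target intervals (e.g. enhancer
#' regions) more often than expected: each DMR is repeatedly allocated a
#' random position on its own chromosome, keeping its length and matching the
#' original's GC content and CpG density (each discretized into a 10-bin
#' histogram over the observed DMRs); the overlap count of each permuted list
#' forms the null distribution. Placements failing to match both bins after
#' `max_tries` draws fall back to length-and-chromosome matching (flagged).
#'
#' @param dmrs DMR tibble `chrom`, `start`, `end`.
#' @param targets Target interval tibble `chrom`, `start`, `end`.
#' @param genome Genome composition model: tibble `chrom`, `start`, `end`,
#'   `gc`, `cpg_density` of tiling bins from which candidate placements get
#'   their GC/CpG values, plus per-chromosome lengths as `attr(genome,
#'   "chrom_sizes")` (named vector) or derived from bin ends.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional seed.
#' @param n_bins Histogram bins for matching (default 10).
#' @param max_tries Matched-placement retries per DMR (default 1000).
#' @return A list: `observed`, `null_mean`, `null_sd`, `p`
#'   (`(1 + #null >= obs) / (1 + n_perm)`), `fold`, `n_relaxed`, `null`.
#' @export
matched_interval_permutation <- function(dmrs, targets, genome,
                                         n_perm = 10000, seed = NULL,
                                         n_bins = 10, max_tries = 1000) {
  stopifnot_cols(genome, c("chrom", "start", "end", "gc", "cpg_density"))
  chrom_sizes <- attr(genome, "chrom_sizes")
  if (is.null(chrom_sizes)) {
    cs <- genome |>
      group_by(.data$chrom) |>
      summarise(size = max(.data$end), .groups = "drop")
    chrom_sizes <- stats::setNames(cs$size, cs$chrom)
  }
  lookup <- function(chrom, start, end) {
    g <- genome[genome$chrom == chrom, ]
    mid <- (start + end) / 2
    i <- findInterval(mid, g$start)
    i <- clamp(i, 1, nrow(g))
    c(gc = g$gc[i], cpg = g$cpg_density[i])
  }
  obs_comp <- t(vapply(seq_len(nrow(dmrs)), function(k) {
    lookup(dmrs$chrom[k], dmrs$start[k], dmrs$end[k])
  }, numeric(2)))
  gc_breaks <- unique(stats::quantile(obs_comp[, 1],
                                      probs = seq(0, 1, length.out = n_bins + 1)))
  cpg_breaks <- unique(stats::quantile(obs_comp[, 2],
                                       probs = seq(0, 1, length.out = n_bins + 1)))
  bin_of <- function(x, breaks) {
    clamp(findInterval(x, breaks, rightmost.closed = TRUE), 1,
          length(breaks) - 1)
  }
  obs_bins <- cbind(bin_of(obs_comp[, 1], gc_breaks),
                    bin_of(obs_comp[, 2], cpg_breaks))
  overlap_count <- function(d) {
    sum(vapply(seq_len(nrow(d)), function(k) {
      any(targets$chrom == d$chrom[k] & targets$start < d$end[k] &
            targets$end > d$start[k])
    }, logical(1)))
  }
  observed <- overlap_count(dmrs)
  lens <- dmrs$end - dmrs$start
  n_relaxed <- 0L
  with_rng(seed, {
    null <- vapply(seq_len(n_perm), function(p) {
      new_start <- integer(nrow(dmrs))
      for (k in seq_len(nrow(dmrs))) {
        size <- chrom_sizes[[dmrs$chrom[k]]]
        placed <- FALSE
        for (try in seq_len(max_tries)) {
          s <- sample.int(max(size - lens[k], 1), 1) - 1L
          comp <- lookup(dmrs$chrom[k], s, s + lens[k])
          if (bin_of(comp[1], gc_breaks) == obs_bins[k, 1] &&
              bin_of(comp[2], cpg_breaks) == obs_bins[k, 2]) {
            placed <- TRUE
            break
          }
        }
        if (!placed) n_relaxed <<- n_relaxed + 1L
        new_start[k] <- s
      }
      overlap_count(tibble(chrom = dmrs$chrom, start = new_start,
                           end = new_start + lens))
    }, numeric(1))
    list(observed = observed, null_mean = mean(null),
         null_sd = stats::sd(null),
         p = (1 + sum(null >= observed)) / (1 + n_perm),
         fold = observed / max(mean(null), .Machine$double.eps),
         n_relaxed = n_relaxed, null = null)
  })
}

#' Permutation test of DMR distance to point features
#'
#' Compares the observed median distance from DMR midpoints to their nearest
#' point feature (e.g. lineage-specific sequence changes) with the null
#' distribution obtained by re-allocating the features uniformly at random on
#' their own chromosomes.
#'
#' @param dmrs DMR tibble `chrom`, `start`, `end`.
#' @param features Tibble `chrom`, `pos` of point features.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param n_perm Number of permutations.
#' @param seed Optional seed.
#' @return A list: `observed_median`, `null_median_mean`, `fold`
#'   (null / observed: how many times closer than expected), `p`
#'   (`(1 + #null <= obs) / (1 + n_perm)`, one-sided for "closer"), `null`.
#' @export
nearest_feature_distance_test <- function(dmrs, features, chrom_sizes,
                                          n_perm = 10000, seed = NULL) {
  mids <- dmrs |>
    mutate(mid = (.data$start + .data$end) %/% 2) |>
    filter(.data$chrom %in% unique(features$chrom))
  if (nrow(mids) < nrow(dmrs)) {
    inform(sprintf("%d DMR(s) on chromosomes without features excluded",
                   nrow(dmrs) - nrow(mids)))
  }
  med_dist <- function(feat) {
    d <- vapply(seq_len(nrow(mids)), function(k) {
      f <- feat$pos[feat$chrom == mids$chrom[k]]
      min(abs(f - mids$mid[k]))
    }, numeric(1))
    stats::median(d)
  }
  observed <- med_dist(features)
  with_rng(seed, {
    null <- vapply(seq_len(n_perm), function(p) {
      perm <- features |>
        mutate(pos = vapply(.data$chrom, function(ch) {
          sample.int(chrom_sizes[[ch]], 1) - 1
        }, numeric(1)))
      med_dist(perm)
    }, numeric(1))
    list(observed_median = observed, null_median_mean = mean(null),
         fold = mean(null) / max(observed, 1),
         p = (1 + sum(null <= observed)) / (1 + n_perm),
         null = null)
  })
}

#' One-sided binomial test for phenotype direction matches
#'
#' Exact upper-tail binomial probability of observing at least `matches`
#' direction-concordant phenotypes out of `total` under a null match
#' probability `p0` (default a coin flip): used to test whether clinical
#' phenotype directions predicted from gene dosage agree with observed
#' between-group differences more often than chance.
#'
#' @param matches Number of concordant phenotypes.
#' @param total Total phenotypes compared.
#' @param p0 Null concordance probability.
#' @return The exact p-value \eqn{P(X \ge matches)}.
#' @export
#' @examples
#' phenotype_direction_binomial(8, 9)
phenotype_direction_binomial <- function(matches, total, p0 = 0.5) {
  if (total <= 0) abort("total must be positive")
  if (matches < 0 || matches > total) abort("matches must be in [0, total]")
  sum(stats::dbinom(matches:total, total, p0))
}
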