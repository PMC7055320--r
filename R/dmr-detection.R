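#' Detector parameters
#'
#' Parameters of the binomial log-likelihood CUSUM detector of differentially
#' methylated regions (DMRs).
#'
#' @param delta Minimum methylation difference defining a DMR (default 0.5).
#' @param min_cpgs Minimum number of CpGs in a reported DMR (default 50, i.e.
#'   twice the 25-CpG smoothing window).
#' @param gap_nt Maximum inter-CpG gap within a DMR; the cumulative score is
#'   reset to zero across larger gaps (default 1000 nt).
#' @param q_threshold_plus,q_threshold_minus Peak-score thresholds for the
#'   hypermethylation / hypomethylation scans, usually from
#'   [calibrate_thresholds()]; 0 reports all excursions.
#' @param pi Deamination rate of the test sample (required by
#'   [detect_dmrs()] unless supplied there).
#' @param phi_eps Reference methylation is clipped to
#'   `[phi_eps, 1 - phi_eps]` so the per-site statistics stay finite
#'   (default 0.01).
#' @param llr_floor Finite floor applied to `-Inf` per-site statistics.
#' @param min_mean_diff Excursion-level consistency filter: the pooled
#'   methylation estimate of the test sample over a candidate DMR must
#'   differ from the mean reference methylation in the claimed direction by
#'   at least this much. Defaults to `delta / 2`: the per-site likelihood
#'   statistic is the primary enforcement of the full difference `delta`,
#'   and the pooled estimate is biased toward the reference by window edges
#'   and the deamination-rate scale, so the consistency check runs at half
#'   the target difference to reject drift artifacts without re-penalizing
#'   estimator noise.
#' @return A list of class `detector_params`.
#' @export
detector_params <- function(delta = 0.5, min_cpgs = 50, gap_nt = 1000,
                            q_threshold_plus = 0, q_threshold_minus = 0,
                            pi = NULL, phi_eps = 0.01, llr_floor = -1e6,
                            min_mean_diff = delta / 2) {
  if (delta <= 0 || delta >= 1) abort("delta must be in (0, 1)")
  if (min_cpgs < 1) abort("min_cpgs must be >= 1")
  if (gap_nt <= 0) abort("gap_nt must be > 0")
  if (q_threshold_plus < 0 || q_threshold_minus < 0) {
    abort("thresholds must be >= 0")
  }
  structure(list(delta = delta, min_cpgs = min_cpgs, gap_nt = gap_nt,
                 q_threshold_plus = q_threshold_plus,
                 q_threshold_minus = q_threshold_minus, pi = pi,
                 phi_eps = phi_eps, llr_floor = llr_floor,
                 min_mean_diff = min_mean_diff),
            class = "detector_params")
}

#' Per-site log-likelihood-ratio statistics
#'
#' `llr_plus()` tests hypermethylation of the test sample: the log ratio of
#' the binomial likelihoods of the observed thymine count `t` out of `n` reads
#' under success probability \eqn{\pi(\varphi + \Delta)} (alternative) versus
#' \eqn{\pi\varphi} (null), where \eqn{\varphi} is the reference methylation.
#' In closed form,
#' \deqn{\ell^+ = t\left[\ln\left(1 + \frac{\Delta}{\varphi}\right) -
#'   \ln\frac{1-\pi(\varphi+\Delta)}{1-\pi\varphi}\right] +
#'   n \ln\frac{1-\pi(\varphi+\Delta)}{1-\pi\varphi}.}
#' `llr_minus()` is the mirror test for hypomethylation
#' (\eqn{\varphi - \Delta}). Because every rate is scaled by the deamination
#' rate \eqn{\pi}, the alternative success probability
#' \eqn{\pi(\varphi + \Delta)} is a valid binomial rate even where
#' \eqn{\varphi + \Delta > 1}, and evaluating the statistic there yields the
#' negative drift that lets the cumulative score decay across highly
#' methylated stretches (for the hypo test, the alternative level is floored
#' at `alt_floor` so \eqn{\varphi - \Delta \le 0} sites likewise drift
#' negative). `-Inf` values are clamped at `llr_floor`.
#'
#' @param t,n Thymine count and total read count (vectors).
#' @param phi Reference methylation in (0, 1).
#' @param pi Deamination rate in (0, 1).
#' @param delta Methylation difference under the alternative.
#' @param llr_floor Finite floor for `-Inf` values.
#' @param alt_floor Floor for the hypo-test alternative level
#'   \eqn{\varphi - \Delta} (default 0.01).
#' @return Numeric vector of per-site statistics.
#' @export
#' @examples
#' llr_plus(t = 3, n = 10, phi = 0.2, pi = 0.05, delta = 0.5)
llr_plus <- function(t, n, phi, pi, delta, llr_floor = -1e6) {
  if (any(pi * (phi + delta) >= 1, na.rm = TRUE)) {
    abort("pi * (phi + delta) must be < 1")
  }
  lr <- log((1 - pi * (phi + delta)) / (1 - pi * phi))
  out <- t * (log(1 + delta / phi) - lr) + n * lr
  zero_t <- !is.na(t) & t == 0
  out[zero_t] <- (n * lr)[zero_t]  # guard 0 * Inf when phi -> 0
  pmax(out, llr_floor)
}

#' @rdname llr_plus
#' @export
llr_minus <- function(t, n, phi, pi, delta, llr_floor = -1e6,
                      alt_floor = 0.01) {
  alt <- pmax(phi - delta, alt_floor)
  lr <- log((1 - pi * alt) / (1 - pi * phi))
  v <- t * (log(alt / phi) - lr) + n * lr
  zero_t <- !is.na(t) & t == 0
  v[zero_t] <- (n * lr)[zero_t]
  pmax(v, llr_floor)
}

#' Cumulative-sum score vector
#'
#' The CUSUM recursion \eqn{Q_0 = 0,\ Q_i = \max(Q_{i-1} + \ell_i, 0)} over
#' per-site statistics ordered by position. After the recursion, the score is
#' reset to zero at every site whose distance to the previous CpG exceeds
#' `gap_nt`, so no excursion spans a large genomic gap (the following site
#' restarts the scan from zero). `NA` statistics (ineligible sites) contribute
#' zero.
#'
#' @param l Per-site statistics (one chromosome, position order).
#' @param pos Matching CpG positions.
#' @param gap_nt Gap threshold in nucleotides.
#' @return Non-negative numeric vector of the same length.
#' @export
#' @examples
#' cusum(c(1, -2, 3), pos = c(0, 100, 200), gap_nt = 1000)
cusum <- function(l, pos, gap_nt = 1000) {
  stopifnot(length(l) == length(pos))
  l[is.na(l)] <- 0
  gap <- c(FALSE, diff(pos) > gap_nt)
  q <- numeric(length(l))
  # A gap site is zeroed after the recursion step, so its statistic never
  # propagates: each stretch between gap sites is an independent scan, and
  # within a stretch Q_i = S_i - min(0, min_j<=i S_j) with S = cumsum(l).
  for (idx in split(seq_along(l), cumsum(gap))) {
    if (gap[idx[1]]) {
      q[idx[1]] <- 0
      idx <- idx[-1]
    }
    if (length(idx) > 0) {
      s <- cumsum(l[idx])
      q[idx] <- s - pmin(cummin(s), 0)
    }
  }
  q
}

#' Extract candidate DMRs from a CUSUM score vector
#'
#' Finds all maximal intervals `[a, b]` with `Q > 0` inside and `Q = 0` at
#' both flanks, locates the (leftmost) peak `m` of each excursion, and reports
#' the interval `[a, m]` with score `Q_m`. Candidates spanning fewer than
#' `min_cpgs` CpGs or with `Q_m` below `q_threshold` are removed.
#'
#' @param q CUSUM scores for one chromosome.
#' @param pos Matching CpG positions.
#' @param min_cpgs Minimum number of CpGs in `[a, m]`.
#' @param q_threshold Minimum peak score.
#' @return A tibble with `cpg_a`, `cpg_m`, `cpg_b` (indices into `q`),
#'   `start`, `end` (0-based half-open genomic interval of `[a, m]`),
#'   `n_cpgs`, and `q_max`.
#' @export
extract_excursions <- function(q, pos, min_cpgs = 50, q_threshold = 0) {
  pos_q <- q > 0
  if (!any(pos_q)) {
    return(tibble(cpg_a = integer(), cpg_m = integer(), cpg_b = integer(),
                  start = integer(), end = integer(), n_cpgs = integer(),
                  q_max = numeric()))
  }
  r <- rle(pos_q)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  a <- starts[r$values]
  b <- ends[r$values]
  # [a, m] is within [a, b], so short excursions can never pass min_cpgs;
  # dropping them before peak-finding keeps the scan cheap on noise
  long_enough <- b - a + 1 >= min_cpgs
  a <- a[long_enough]
  b <- b[long_enough]
  if (length(a) == 0) {
    return(tibble(cpg_a = integer(), cpg_m = integer(), cpg_b = integer(),
                  start = integer(), end = integer(), n_cpgs = integer(),
                  q_max = numeric()))
  }
  m <- q_max <- numeric(length(a))
  for (k in seq_along(a)) {
    seg <- q[a[k]:b[k]]
    pk <- which.max(seg)  # leftmost peak
    m[k] <- a[k] + pk - 1
    q_max[k] <- seg[pk]
  }
  keep <- (m - a + 1) >= min_cpgs & q_max >= q_threshold
  a <- a[keep]; b <- b[keep]; m <- m[keep]; q_max <- q_max[keep]
  tibble(cpg_a = as.integer(a), cpg_m = as.integer(m), cpg_b = as.integer(b),
         start = pos[a], end = pos[m] + 1L,
         n_cpgs = as.integer(m - a + 1), q_max = q_max)
}

#' Detect DMRs between a deamination map and a reference methylome
#'
#' Runs the hypermethylation and hypomethylation scans independently: per-site
#' statistics [llr_plus()] / [llr_minus()] of the raw (filtered) counts
#' against the reference methylation, the CUSUM recursion with the gap reset,
#' excursion extraction, and the CpG-count and score filters. The reference
#' methylation is clipped to `[phi_eps, 1 - phi_eps]`; sites ineligible for a
#' branch (e.g. `phi + delta > 1` for the hyper test) contribute zero to that
#' branch's scan.
#'
#' @param test Count track of the test sample (already pre-mortem filtered:
#'   `chrom`, `pos`, `c_count`, `t_count`).
#' @param reference Reference methylation track (`chrom`, `pos`,
#'   `methylation`), typically smoothed reconstructed or measured methylation.
#' @param params A [detector_params()]; `params$pi` (or `pi`) must be set.
#' @param pi Deamination rate of the test sample (overrides `params$pi`).
#' @return A `dmr_set` tibble: `chrom`, `start`, `end`, `n_cpgs`, `direction`
#'   (`"hyper"` = test above reference), `q_max`, ordered by chromosome and
#'   start.
#' @export
detect_dmrs <- function(test, reference, params = detector_params(),
                        pi = NULL) {
  pi <- pi %||% params$pi
  if (is.null(pi)) abort("the deamination rate pi must be supplied")
  stopifnot_cols(test, c("chrom", "pos", "c_count", "t_count"))
  stopifnot_cols(reference, c("chrom", "pos", "methylation"))
  sites <- inner_join(ct_ratio(test),
                      reference[, c("chrom", "pos", "methylation")],
                      by = c("chrom", "pos"))
  if (nrow(sites) == 0) abort("test and reference share no CpG sites")
  sites <- sites |> arrange(.data$chrom, .data$pos)
  phi <- clamp(sites$methylation, params$phi_eps, 1 - params$phi_eps)
  detect_core(sites$chrom, sites$pos, sites$t_count, sites$n, phi, params, pi)
}

# Both statistics are linear in the thymine count: l = t * A + n * B with
# site-fixed coefficients, so repeated scans over the same sites (the
# calibration loop) can precompute A and n * B once.
llr_coeffs <- function(n, phi_clipped, pi, delta, alt_floor = 0.01) {
  lr_p <- log((1 - pi * (phi_clipped + delta)) / (1 - pi * phi_clipped))
  alt <- pmax(phi_clipped - delta, alt_floor)
  lr_m <- log((1 - pi * alt) / (1 - pi * phi_clipped))
  list(a_plus = log(1 + delta / phi_clipped) - lr_p, nb_plus = n * lr_p,
       a_minus = log(alt / phi_clipped) - lr_m, nb_minus = n * lr_m)
}

# Fast detector core on pre-joined, position-sorted site vectors; shared by
# detect_dmrs() and the calibration loop so real and simulated comparisons
# run through identical code. Candidate excursions must also satisfy the
# DMR definition itself: the pooled methylation estimate of the test sample
# over [a, m] (pooled C->T rate divided by pi, capped at 1) must differ from
# the mean reference methylation by at least `min_mean_diff`.
detect_core <- function(chrom, pos, t, n, phi_clipped, params, pi,
                        coeffs = NULL, chunks = NULL) {
  if (is.null(coeffs)) {
    coeffs <- llr_coeffs(n, phi_clipped, pi, params$delta)
  }
  lp <- pmax(t * coeffs$a_plus + coeffs$nb_plus, params$llr_floor)
  lm <- pmax(t * coeffs$a_minus + coeffs$nb_minus, params$llr_floor)
  if (is.null(chunks)) {
    chunks <- split(seq_along(pos), factor(chrom, levels = unique(chrom)))
  }
  ct <- cumsum(t)
  cn <- cumsum(n)
  cphi <- cumsum(phi_clipped)
  scan_one <- function(l, thr, dir) {
    res <- purrr::map(names(chunks), function(ch) {
      idx <- chunks[[ch]]
      q <- cusum(l[idx], pos[idx], params$gap_nt)
      ex <- extract_excursions(q, pos[idx], params$min_cpgs, thr)
      if (nrow(ex) == 0) return(ex)
      a <- idx[ex$cpg_a]
      m <- idx[ex$cpg_m]
      psi_hat <- pmin((ct[m] - ct[a] + t[a]) /
                        pmax(cn[m] - cn[a] + n[a], 1) / pi, 1)
      phi_bar <- (cphi[m] - cphi[a] + phi_clipped[a]) / (m - a + 1)
      mmd <- params$min_mean_diff %||% (params$delta / 2)
      diff_ok <- if (dir == "hyper") psi_hat - phi_bar >= mmd else
        phi_bar - psi_hat >= mmd
      ex <- ex[diff_ok, , drop = FALSE]
      if (nrow(ex) > 0) ex$chrom <- ch
      ex
    })
    out <- bind_rows(res)
    if (nrow(out) > 0) out$direction <- dir
    out
  }
  out <- bind_rows(
    scan_one(lp, params$q_threshold_plus, "hyper"),
    scan_one(lm, params$q_threshold_minus, "hypo")
  )
  if (nrow(out) == 0) {
    out <- tibble(chrom = character(), start = integer(), end = integer(),
                  n_cpgs = integer(), direction = character(),
                  q_max = numeric())
  } else {
    out <- out |>
      select("chrom", "start", "end", "n_cpgs", "direction", "q_max") |>
      arrange(.data$chrom, .data$start)
  }
  class(out) <- c("dmr_set", class(out))
  out
}

#' Fisher-window DMRs between two bisulfite methylomes
#'
#' Detector for comparisons of two full (WGBS-style) methylomes carrying
#' methylated/unmethylated read counts per CpG: a sliding window of
#' `window` CpGs advances one CpG at a time; in each window the pooled read
#' counts of the two samples form a 2x2 table tested with Fisher's exact
#' test; windows with Benjamini-Hochberg FDR above `fdr` or an absolute
#' pooled methylation difference below `delta` are discarded, and surviving
#' overlapping windows are merged into maximal intervals.
#'
#' @param sample_a,sample_b Tibbles `chrom`, `pos`, `meth_count`,
#'   `unmeth_count`.
#' @param window Window width in CpGs (default 25).
#' @param delta Minimum pooled methylation difference (default 0.5).
#' @param fdr BH-adjusted significance threshold (default 0.05).
#' @return A `dmr_set` tibble: `chrom`, `start`, `end`, `n_cpgs`, `direction`
#'   (`"hyper"` = sample_a above sample_b), `q_max` (minimum window q-value,
#'   as -log10).
#' @export
fisher_window_dmrs <- function(sample_a, sample_b, window = 25, delta = 0.5,
                               fdr = 0.05) {
  for (s in list(sample_a, sample_b)) {
    stopifnot_cols(s, c("chrom", "pos", "meth_count", "unmeth_count"))
  }
  sites <- inner_join(sample_a, sample_b, by = c("chrom", "pos"),
                      suffix = c("_a", "_b")) |>
    arrange(.data$chrom, .data$pos)
  if (nrow(sites) == 0) abort("samples share no CpG sites")
  win <- sites |>
    group_by(.data$chrom) |>
    mutate(
      ma = rolling_sum(.data$meth_count_a, window),
      ua = rolling_sum(.data$unmeth_count_a, window),
      mb = rolling_sum(.data$meth_count_b, window),
      ub = rolling_sum(.data$unmeth_count_b, window)
    ) |>
    ungroup()
  tot_a <- win$ma + win$ua
  tot_b <- win$mb + win$ub
  ok <- tot_a > 0 & tot_b > 0
  win <- win[ok, , drop = FALSE]
  p <- vapply(seq_len(nrow(win)), function(i) {
    stats::fisher.test(matrix(c(win$ma[i], win$ua[i], win$mb[i], win$ub[i]),
                              nrow = 2))$p.value
  }, numeric(1))
  diff_ab <- win$ma / (win$ma + win$ua) - win$mb / (win$mb + win$ub)
  q <- stats::p.adjust(p, method = "BH")
  keep <- q <= fdr & abs(diff_ab) >= delta
  if (!any(keep)) {
    out <- tibble(chrom = character(), start = integer(), end = integer(),
                  n_cpgs = integer(), direction = character(),
                  q_max = numeric())
    class(out) <- c("dmr_set", class(out))
    return(out)
  }
  # each surviving window covers `window` CpGs centred on its site; merge
  # overlapping windows per chromosome and direction
  half <- window %/% 2
  chrom_range <- tibble(chrom = win$chrom, row = seq_len(nrow(win))) |>
    group_by(.data$chrom) |>
    summarise(first_row = min(.data$row), last_row = max(.data$row))
  kept <- win[keep, c("chrom", "pos")] |>
    mutate(q = q[keep], dir = ifelse(diff_ab[keep] > 0, "hyper", "hypo"),
           center_idx = which(keep))
  merged <- kept |>
    group_by(.data$chrom, .data$dir) |>
    dplyr::group_modify(function(d, key) {
      cr <- chrom_range[chrom_range$chrom == key$chrom, ]
      idx <- sort(d$center_idx)
      lo <- pmax(idx - half, cr$first_row)
      hi <- pmin(idx + half, cr$last_row)
      merge_index_intervals(lo, hi) |>
        mutate(q_min = vapply(seq_len(dplyr::n()), function(k) {
          min(d$q[idx >= .data$lo[k] & idx <= .data$hi[k]])
        }, numeric(1)))
    }) |>
    ungroup()
  out <- merged |>
    mutate(start = win$pos[.data$lo], end = win$pos[.data$hi] + 1L,
           n_cpgs = .data$hi - .data$lo + 1L,
           q_max = -log10(pmax(.data$q_min, 1e-300))) |>
    select("chrom", "start", "end", "n_cpgs", direction = "dir", "q_max") |>
    arrange(.data$chrom, .data$start)
  class(out) <- c("dmr_set", class(out))
  out
}

# merge overlapping/adjacent [lo, hi] index intervals (inclusive, sorted by lo)
merge_index_intervals <- function(lo, hi) {
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  out_lo <- lo[1]; out_hi <- hi[1]
  res_lo <- c(); res_hi <- c()
  for (k in seq_along(lo)[-1]) {
    if (lo[k] <= out_hi + 1) {
      out_hi <- max(out_hi, hi[k])
    } else {
      res_lo <- c(res_lo, out_lo); res_hi <- c(res_hi, out_hi)
      out_lo <- lo[k]; out_hi <- hi[k]
    }
  }
  tibble(lo = c(res_lo, out_lo), hi = c(res_hi, out_hi))
}
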