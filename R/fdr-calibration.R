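#' Simulate a null deamination map from a reference methylome
#'
#' Treats the reference methylation as the truth and redraws thymine counts
#' binomially, \eqn{t_i \sim B(n_i, \pi\psi_i)}, with the coverage \eqn{n_i}
#' taken from a template count track (the real sample). Any DMR detected
#' between the resulting map and the reference reflects pure sampling noise
#' plus the smoothing and filtering pipeline, which is the basis for the
#' empirical false discovery rate.
#'
#' @param reference Methylation track `chrom`, `pos`, `methylation`.
#' @param coverage_template Count track supplying per-site coverage.
#' @param pi Deamination rate.
#' @param seed Optional seed.
#' @return A count track tibble over the sites shared by reference and
#'   template.
#' @export
simulate_null_map <- function(reference, coverage_template, pi, seed = NULL) {
  stopifnot_cols(reference, c("chrom", "pos", "methylation"))
  stopifnot_cols(coverage_template, c("chrom", "pos", "c_count", "t_count"))
  j <- inner_join(reference,
                  coverage_template[, c("chrom", "pos", "c_count", "t_count")],
                  by = c("chrom", "pos"))
  n <- j$c_count + j$t_count
  with_rng(seed, {
    t_cnt <- stats::rbinom(nrow(j), n, pi * clamp(j$methylation))
    tibble(chrom = j$chrom, pos = j$pos, c_count = n - t_cnt, t_count = t_cnt)
  })
}

#' Calibrate detector thresholds by simulation-based FDR
#'
#' Chooses the peak-score thresholds \eqn{Q_T^+} and \eqn{Q_T^-} so that the
#' mean number of DMRs detected in simulated null deamination maps is below
#' `target_fdr` times the number of real DMRs at the same threshold. The
#' search grid is the sorted multiset of observed excursion peak scores in the
#' real comparison (the empirical FDR is a step function of the threshold on
#' this grid); thresholds are calibrated separately per direction. If no
#' threshold attains the target, the threshold is `+Inf` (no DMR passes) with
#' a warning.
#'
#' @param test Count track of the real test sample.
#' @param reference Reference methylation track the real comparison runs
#'   against.
#' @param params A [detector_params()] configured as for the real comparison.
#' @param pi Deamination rate of the test sample.
#' @param n_sims Number of simulated null maps (default 100).
#' @param target_fdr Target ratio of mean simulated to real DMR counts
#'   (default 0.05).
#' @param seed Master seed; per-simulation seeds are derived from it.
#' @return A `dmr_calibration` object: a list with `q_threshold_plus`,
#'   `q_threshold_minus`, `real_counts`, `mean_simulated_counts`,
#'   `achieved_fdr` (all per direction), `n_sims`, `target_fdr`, `seed`.
#' @export
calibrate_thresholds <- function(test, reference, params = detector_params(),
                                 pi = NULL, n_sims = 100, target_fdr = 0.05,
                                 seed = 1) {
  pi <- pi %||% params$pi
  if (is.null(pi)) abort("the deamination rate pi must be supplied")
  open_params <- params
  open_params$q_threshold_plus <- 0
  open_params$q_threshold_minus <- 0
  real <- detect_dmrs(test, reference, open_params, pi = pi)
  # pre-join the shared sites once; each null simulation only redraws t
  sites <- inner_join(ct_ratio(test),
                      reference[, c("chrom", "pos", "methylation")],
                      by = c("chrom", "pos")) |>
    arrange(.data$chrom, .data$pos)
  psi <- clamp(sites$methylation)
  phi_clipped <- clamp(sites$methylation, params$phi_eps, 1 - params$phi_eps)
  coeffs <- llr_coeffs(sites$n, phi_clipped, pi, params$delta)
  chunks <- split(seq_along(sites$pos),
                  factor(sites$chrom, levels = unique(sites$chrom)))
  mu <- pi * psi
  seeds <- derive_seeds(seed, n_sims)
  sim_peaks <- purrr::map(seq_len(n_sims), function(s) {
    t_null <- with_rng(seeds[s], stats::rbinom(nrow(sites), sites$n, mu))
    detect_core(sites$chrom, sites$pos, t_null, sites$n, phi_clipped,
                open_params, pi, coeffs = coeffs, chunks = chunks)
  })
  calibrate_direction <- function(dir) {
    real_q <- sort(real$q_max[real$direction == dir])
    sim_q <- purrr::map(sim_peaks, function(d) d$q_max[d$direction == dir])
    if (length(real_q) == 0) {
      return(list(threshold = Inf, real_count = 0, sim_mean = 0, fdr = NA_real_))
    }
    for (thr in real_q) {
      real_count <- sum(real_q >= thr)
      sim_mean <- mean(vapply(sim_q, function(qv) sum(qv >= thr), numeric(1)))
      if (sim_mean / real_count < target_fdr) {
        return(list(threshold = thr, real_count = real_count,
                    sim_mean = sim_mean, fdr = sim_mean / real_count))
      }
    }
    warn(sprintf("no %s threshold attains the FDR target; using +Inf", dir))
    list(threshold = Inf, real_count = 0, sim_mean = 0, fdr = NA_real_)
  }
  plus <- calibrate_direction("hyper")
  minus <- calibrate_direction("hypo")
  structure(list(
    q_threshold_plus = plus$threshold,
    q_threshold_minus = minus$threshold,
    real_counts = c(hyper = plus$real_count, hypo = minus$real_count),
    mean_simulated_counts = c(hyper = plus$sim_mean, hypo = minus$sim_mean),
    achieved_fdr = c(hyper = plus$fdr, hypo = minus$fdr),
    pooled_fdr = {
      rc <- plus$real_count + minus$real_count
      if (rc > 0) (plus$sim_mean + minus$sim_mean) / rc else NA_real_
    },
    n_sims = n_sims, target_fdr = target_fdr, seed = seed
  ), class = "dmr_calibration")
}

#' @export
print.dmr_calibration <- function(x, ...) {
  cat("DMR threshold calibration (", x$n_sims, " null simulations)\n", sep = "")
  cat(sprintf("  Q_T+ = %.3f  (real %d, sim mean %.2f, FDR %.4f)\n",
              x$q_threshold_plus, x$real_counts["hyper"],
              x$mean_simulated_counts["hyper"], x$achieved_fdr["hyper"]))
  cat(sprintf("  Q_T- = %.3f  (real %d, sim mean %.2f, FDR %.4f)\n",
              x$q_threshold_minus, x$real_counts["hypo"],
              x$mean_simulated_counts["hypo"], x$achieved_fdr["hypo"]))
  invisible(x)
}

#' Self-comparison noise check
#'
#' Compares a deamination map against the methylome reconstructed from that
#' same map. Any DMR found reflects detector noise only; a sound pipeline
#' reports a negligible count relative to a genuine between-sample comparison
#' (in practice well under 1%).
#'
#' @param counts Count track of the sample.
#' @param reconstruction Methylation track reconstructed from `counts` (e.g.
#'   via [reconstruct_methylome()]).
#' @param params A [detector_params()] with calibrated thresholds.
#' @param pi Deamination rate of the sample.
#' @return Integer DMR count, with the full `dmr_set` as
#'   `attr(., "dmrs")`.
#' @export
self_comparison_check <- function(counts, reconstruction,
                                  params = detector_params(), pi = NULL) {
  dmrs <- detect_dmrs(counts, reconstruction, params, pi = pi)
  out <- nrow(dmrs)
  attr(out, "dmrs") <- dmrs
  out
}
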