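#' Run configuration
#'
#' A run configuration bundles every tunable of a full pipeline run —
#' simulation (or input paths), reconstruction, detection, calibration — plus
#' the master seed, so a run can be re-executed reproducibly from its saved
#' config. `default_run_config()` carries the standard defaults (methylation
#' difference 0.5, 25-CpG smoothing window, 1000-nt gap, 50-CpG minimum, 100
#' calibration simulations, FDR target 0.05). `read_run_config()` loads a
#' YAML or JSON file and validates it field by field, reporting the path of
#' each invalid field.
#'
#' @param overrides Named list of fields to override, nested as in the
#'   default config.
#' @return A list of class `run_config`.
#' @export
#' @examples
#' cfg <- default_run_config(list(detector = list(delta = 0.4)))
#' cfg$detector$delta
default_run_config <- function(overrides = NULL) {
  cfg <- list(
    seed = 1,
    mode = "wgbs",
    simulation = list(n_chromosomes = 2, cpgs_per_chromosome = 20000,
                      coverage_mean = 30, pi = 0.05, within_group_sd = 0.15,
                      probe_fraction = 0.05, dmrs_per_lineage = 10,
                      dmr_span_cpgs = 60, dmr_delta = 0.6),
    reconstruction = list(ct_ratio_cap = 0.25, max_coverage = 100,
                          window_cpgs = 25, smoothing = "pooled"),
    detector = list(delta = 0.5, min_cpgs = 50, gap_nt = 1000,
                    phi_eps = 0.01),
    calibration = list(n_sims = 100, target_fdr = 0.05),
    output_dir = "."
  )
  if (!is.null(overrides)) cfg <- modify_nested(cfg, overrides)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

modify_nested <- function(base, overrides) {
  for (nm in names(overrides)) {
    if (is.list(overrides[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_nested(base[[nm]], overrides[[nm]])
    } else {
      base[[nm]] <- overrides[[nm]]
    }
  }
  base
}

#' @rdname default_run_config
#' @param path Path to a YAML (or JSON) run-config file; missing fields take
#'   the defaults.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  default_run_config(raw)
}

#' @rdname default_run_config
#' @param config A config list to validate.
#' @export
validate_run_config <- function(config) {
  checks <- list(
    "detector.delta" = function(c) {
      d <- c$detector$delta
      is.numeric(d) && d > 0 && d < 1
    },
    "detector.min_cpgs" = function(c) c$detector$min_cpgs >= 1,
    "detector.gap_nt" = function(c) c$detector$gap_nt > 0,
    "reconstruction.window_cpgs" = function(c)
      c$reconstruction$window_cpgs >= 1,
    "reconstruction.ct_ratio_cap" = function(c) {
      v <- c$reconstruction$ct_ratio_cap
      v > 0 && v <= 1
    },
    "calibration.n_sims" = function(c) c$calibration$n_sims >= 1,
    "calibration.target_fdr" = function(c) {
      v <- c$calibration$target_fdr
      v > 0 && v < 1
    },
    "simulation.pi" = function(c) {
      v <- c$simulation$pi
      v > 0 && v < 1
    },
    "seed" = function(c) is.numeric(c$seed) && c$seed == round(c$seed)
  )
  bad <- names(checks)[!vapply(checks, function(f) isTRUE(f(config)),
                               logical(1))]
  if (length(bad) > 0) {
    abort(sprintf("invalid run config field(s): %s",
                  paste(bad, collapse = ", ")))
  }
  invisible(config)
}

#' @rdname default_run_config
#' @param config A validated `run_config`.
#' @export
#' @details `run_from_config()` executes the full synthetic run the config
#'   describes — panel simulation, reconstruction, detection with calibrated
#'   thresholds, lineage assignment and filtering — and returns the
#'   `dmr_pipeline` result.
run_from_config <- function(config) {
  validate_run_config(config)
  sim <- config$simulation
  planted <- tidyr::expand_grid(
    lineage = c("AMH", "Neanderthal", "Denisovan", "archaic"),
    idx = seq_len(sim$dmrs_per_lineage)
  ) |>
    mutate(span_cpgs = sim$dmr_span_cpgs, delta = sim$dmr_delta,
           direction = ifelse(.data$idx %% 2 == 1, "hyper", "hypo")) |>
    select(-"idx")
  cfg <- sim_config(
    n_chromosomes = sim$n_chromosomes,
    cpgs_per_chromosome = sim$cpgs_per_chromosome,
    coverage = list(dist = "nbinom", mean = sim$coverage_mean, size = 5),
    pi_default = sim$pi,
    planted_dmrs = planted,
    within_group_sd = sim$within_group_sd,
    probe_fraction = sim$probe_fraction,
    seed = config$seed
  )
  panel <- simulate_panel(cfg)
  rp <- reconstruction_params(
    ct_ratio_cap = config$reconstruction$ct_ratio_cap,
    max_coverage = config$reconstruction$max_coverage,
    window_cpgs = config$reconstruction$window_cpgs,
    smoothing = config$reconstruction$smoothing
  )
  dp <- detector_params(
    delta = config$detector$delta, min_cpgs = config$detector$min_cpgs,
    gap_nt = config$detector$gap_nt, phi_eps = config$detector$phi_eps
  )
  run_pipeline(panel, dp, mode = config$mode,
               n_sims = config$calibration$n_sims,
               target_fdr = config$calibration$target_fdr,
               seed = config$seed + 1000, recon_params = rp)
}
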