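test_that("per-site statistics equal binomial pmf log-ratios exactly", {
  set.seed(42)
  n_draw <- 10000
  n <- sample(1:100, n_draw, replace = TRUE)
  t <- rbinom(n_draw, n, runif(n_draw, 0, 0.2))
  pi <- runif(n_draw, 0.01, 0.2)
  delta <- runif(n_draw, 0.1, 0.9)
  phi <- runif(n_draw, 0.01, 0.99)

  got_p <- llr_plus(t, n, phi, pi, delta)
  exp_p <- dbinom(t, n, pi * (phi + delta), log = TRUE) -
    dbinom(t, n, pi * phi, log = TRUE)
  expect_lt(max(abs(got_p - exp_p)), 1e-12)

  elig <- which(phi - delta >= 0.01)
  got_m <- llr_minus(t[elig], n[elig], phi[elig], pi[elig], delta[elig])
  exp_m <- dbinom(t[elig], n[elig], pi[elig] * (phi[elig] - delta[elig]),
                  log = TRUE) -
    dbinom(t[elig], n[elig], pi[elig] * phi[elig], log = TRUE)
  expect_lt(max(abs(got_m - exp_m)), 1e-12)
})

test_that("degenerate statistic cases behave as the model dictates", {
  # identical hypotheses as delta -> 0
  expect_equal(llr_plus(5, 20, 0.3, 0.05, 1e-12), 0, tolerance = 1e-9)
  expect_equal(llr_minus(5, 20, 0.3, 0.05, 1e-12), 0, tolerance = 1e-9)
  # no thymine evidence favours the null for the hyper test
  expect_lt(llr_plus(0, 30, 0.2, 0.05, 0.5), 0)
  # abundant thymines contradict hypomethylation
  expect_lt(llr_minus(20, 20, 0.8, 0.05, 0.5), -10)
  # below the alternative floor the statistic is finite and clamped
  expect_true(is.finite(llr_minus(3, 10, 0.4, 0.05, 0.5)))
})

test_that("the CUSUM recursion matches a naive implementation", {
  expect_equal(cusum(c(1, -2, 3), c(0, 100, 200), 1000), c(1, 0, 3))
  expect_equal(cusum(c(-1, -5, -0.1), c(0, 1, 2), 1000), c(0, 0, 0))

  set.seed(7)
  l <- rnorm(10000, -0.1, 1)
  pos <- cumsum(1 + rgeom(10000, 1 / 20))
  pos[5000:5002] <- pos[5000:5002] + 5000  # force gap resets
  expect_equal(cusum(l, pos, 1000), naive_cusum(l, pos, 1000))

  # NA statistics contribute zero
  expect_equal(cusum(c(1, NA, 2), c(0, 1, 2), 1000), c(1, 1, 3))
})

test_that("excursion extraction matches a brute-force scan", {
  expect_equal(nrow(extract_excursions(rep(0, 50), 1:50, min_cpgs = 1)), 0)

  # single excursion with its peak at the last positive site: [a, m] = [a, b]
  q <- c(0, 1, 2, 3, 0)
  ex <- extract_excursions(q, c(10, 20, 30, 40, 50), min_cpgs = 1)
  expect_equal(ex$cpg_a, 2)
  expect_equal(ex$cpg_m, 4)
  expect_equal(ex$q_max, 3)
  expect_equal(ex$start, 20)
  expect_equal(ex$end, 41)

  set.seed(21)
  for (rep in 1:5) {
    l <- rnorm(10000, -0.05, 1)
    pos <- cumsum(rep(10, 10000))
    q <- cusum(l, pos, 1e9)
    got <- extract_excursions(q, pos, min_cpgs = 5)
    oracle <- naive_excursions(q)
    oracle <- oracle[oracle$m - oracle$a + 1 >= 5, ]
    expect_equal(got$cpg_a, oracle$a)
    expect_equal(got$cpg_m, oracle$m)
    expect_equal(got$q_max, oracle$q_max)
  }
})

test_that("detector finds planted shifts and nothing in self-comparisons", {
  cfg <- sim_config(n_chromosomes = 1, cpgs_per_chromosome = 4000,
                    within_group_sd = 0, seed = 31,
                    planted_dmrs = tibble::tibble(
                      lineage = c("AMH", "AMH"), span_cpgs = 60, delta = 0.6,
                      direction = c("hyper", "hypo")))
  pos <- generate_cpg_positions(cfg)
  gm <- generate_lineage_methylomes(cfg, pos)
  truth <- gm$truth
  amh <- gm$true_methylation[["amh_core"]]
  nea <- gm$true_methylation[["nea_core"]]
  cnt <- simulate_deamination(amh, coverage = 30, pi = 0.05, seed = 32)
  dmrs <- detect_dmrs(cnt, nea, detector_params(q_threshold_plus = 10,
                                                q_threshold_minus = 10),
                      pi = 0.05)
  for (k in seq_len(nrow(truth))) {
    hit <- dmrs[dmrs$start < truth$end[k] & dmrs$end > truth$start[k], ]
    expect_equal(nrow(hit), 1)
    expect_equal(hit$direction, truth$direction[k])
  }
  expect_equal(nrow(dmrs), nrow(truth))

  # counts simulated from the reference itself carry no signal
  cnt_null <- simulate_deamination(nea, coverage = 30, pi = 0.05, seed = 33)
  self_dmrs <- detect_dmrs(cnt_null, nea,
                           detector_params(q_threshold_plus = 10,
                                           q_threshold_minus = 10), pi = 0.05)
  expect_equal(nrow(self_dmrs), 0)
})

test_that("short planted shifts below min_cpgs are not reported", {
  cfg <- sim_config(n_chromosomes = 1, cpgs_per_chromosome = 3000,
                    within_group_sd = 0, seed = 41,
                    planted_dmrs = tibble::tibble(lineage = "AMH",
                                                  span_cpgs = 20, delta = 0.6,
                                                  direction = "hyper"))
  pos <- generate_cpg_positions(cfg)
  gm <- generate_lineage_methylomes(cfg, pos)
  cnt <- simulate_deamination(gm$true_methylation[["amh_core"]],
                              coverage = 30, pi = 0.05, seed = 42)
  dmrs <- detect_dmrs(cnt, gm$true_methylation[["nea_core"]],
                      detector_params(), pi = 0.05)
  truth <- gm$truth
  hit <- dmrs[dmrs$start < truth$end[1] & dmrs$end > truth$start[1], ]
  expect_equal(nrow(hit), 0)
})

test_that("raising score thresholds or min_cpgs never increases DMR counts", {
  panel <- small_panel(seed = 51, cpgs = 4000)
  panel <- reconstruct_panel(panel)
  core <- panel[panel$core, ]
  cnt <- apply_premortem_filters(core$counts[[1]])
  ref <- core$methylation[[2]]
  by_thr <- vapply(c(0, 5, 15, 40), function(thr) {
    nrow(detect_dmrs(cnt, ref,
                     detector_params(q_threshold_plus = thr,
                                     q_threshold_minus = thr),
                     pi = core$pi_hat[1]))
  }, numeric(1))
  expect_true(all(diff(by_thr) <= 0))
  by_cpgs <- vapply(c(30, 50, 80), function(mc) {
    nrow(detect_dmrs(cnt, ref, detector_params(min_cpgs = mc),
                     pi = core$pi_hat[1]))
  }, numeric(1))
  expect_true(all(diff(by_cpgs) <= 0))
})

test_that("no reported DMR spans a gap larger than delta_nt", {
  panel <- small_panel(seed = 61, cpgs = 4000)
  panel <- reconstruct_panel(panel)
  core <- panel[panel$core, ]
  cnt <- apply_premortem_filters(core$counts[[1]])
  dmrs <- detect_dmrs(cnt, core$methylation[[2]], detector_params(),
                      pi = core$pi_hat[1])
  pos_by_chrom <- split(cnt$pos, cnt$chrom)
  for (k in seq_len(nrow(dmrs))) {
    p <- pos_by_chrom[[dmrs$chrom[k]]]
    inside <- p[p >= dmrs$start[k] & p < dmrs$end[k]]
    expect_true(all(diff(inside) <= 1000))
  }
})

test_that("Fisher-window DMRs match a brute-force enumeration on a toy pair", {
  n <- 200
  pos <- seq(0, by = 10, length.out = n)
  block <- 86:115  # one 30-CpG contrast block
  meth_a <- ifelse(seq_len(n) %in% block, 48, 5)
  unmeth_a <- ifelse(seq_len(n) %in% block, 2, 45)
  a <- tibble::tibble(chrom = "chr1", pos = pos, meth_count = meth_a,
                      unmeth_count = unmeth_a)
  b <- tibble::tibble(chrom = "chr1", pos = pos, meth_count = 5,
                      unmeth_count = 45)
  got <- fisher_window_dmrs(a, b, window = 25, delta = 0.5, fdr = 0.05)

  # oracle: same definition, written independently
  half <- 12
  wins <- lapply(seq_len(n), function(i) {
    idx <- max(1, i - half):min(n, i + half)
    c(ma = sum(a$meth_count[idx]), ua = sum(a$unmeth_count[idx]),
      mb = sum(b$meth_count[idx]), ub = sum(b$unmeth_count[idx]))
  })
  p <- vapply(wins, function(w) {
    fisher.test(matrix(w, nrow = 2))$p.value
  }, numeric(1))
  q <- p.adjust(p, "BH")
  d <- vapply(wins, function(w) {
    w["ma"] / (w["ma"] + w["ua"]) - w["mb"] / (w["mb"] + w["ub"])
  }, numeric(1))
  keep <- which(q <= 0.05 & abs(d) >= 0.5)
  lo <- pmax(keep - half, 1)
  hi <- pmin(keep + half, n)
  merged_lo <- min(lo)
  merged_hi <- max(hi)   # the toy has one contiguous surviving run
  expect_equal(nrow(got), 1)
  expect_equal(got$start, pos[merged_lo])
  expect_equal(got$end, pos[merged_hi] + 1)
  expect_equal(got$direction, "hyper")

  # identical samples yield nothing
  expect_equal(nrow(fisher_window_dmrs(a, a)), 0)

  # a maximal-contrast window survives both filters
  big <- tibble::tibble(chrom = "chr1", pos = pos, meth_count = 50,
                        unmeth_count = 0)
  small <- tibble::tibble(chrom = "chr1", pos = pos, meth_count = 0,
                          unmeth_count = 50)
  expect_gt(nrow(fisher_window_dmrs(big, small)), 0)
})
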