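make_sample <- function(panel, idx) {
  list(id = panel$id[idx], counts = apply_premortem_filters(panel$counts[[idx]]),
       methylation = panel$methylation[[idx]], pi = panel$pi_hat[idx])
}

test_that("reciprocal comparison unions the two runs' DMRs", {
  panel <- reconstruct_panel(small_panel(seed = 111, cpgs = 4000))
  core <- panel[panel$core, ]
  s1 <- make_sample(core, 1)
  s2 <- make_sample(core, 2)
  params <- detector_params(q_threshold_plus = 10, q_threshold_minus = 10)
  both <- reciprocal_two_way(s1, s2, params)
  # union equals the brute-force union of the two independent runs
  d1 <- detect_dmrs(s1$counts, s2$methylation, params, pi = s1$pi)
  d2 <- detect_dmrs(s2$counts, s1$methylation, params, pi = s2$pi)
  d2$direction <- ifelse(d2$direction == "hyper", "hypo", "hyper")
  for (k in seq_len(nrow(d1))) {
    expect_true(any(both$chrom == d1$chrom[k] & both$start <= d1$start[k] &
                      both$end >= d1$end[k] &
                      both$direction == d1$direction[k]))
  }
  for (k in seq_len(nrow(d2))) {
    expect_true(any(both$chrom == d2$chrom[k] & both$start <= d2$start[k] &
                      both$end >= d2$end[k] &
                      both$direction == d2$direction[k]))
  }
  # every union DMR is backed by at least one run
  expect_true(all(both$found_in %in% c("both", "run1", "run2")))

  # identical samples: nothing
  none <- reciprocal_two_way(s1, s1, params)
  expect_equal(nrow(none), 0)
})

test_that("three-way intersection is exact half-open interval algebra", {
  cpgs <- tibble::tibble(chrom = "chr1", pos = seq(0, 400, 2))
  d12 <- tibble::tibble(chrom = "chr1", start = 100, end = 200,
                        n_cpgs = 50, direction = "hyper", q_max = 20)
  d13 <- tibble::tibble(chrom = "chr1", start = 150, end = 300,
                        n_cpgs = 75, direction = "hyper", q_max = 12)
  ix <- three_way_intersect(d12, d13, cpgs, min_cpgs = 10)
  expect_equal(ix$start, 150)
  expect_equal(ix$end, 200)
  expect_equal(ix$q_max, 12)
  expect_equal(ix$n_cpgs, 25)

  disjoint <- three_way_intersect(
    d12, dplyr::mutate(d13, start = 250, end = 350), cpgs, min_cpgs = 1)
  expect_equal(nrow(disjoint), 0)

  conflicting <- dplyr::mutate(d13, direction = "hypo")
  expect_message(
    none <- three_way_intersect(d12, conflicting, cpgs, min_cpgs = 1),
    "direction conflict"
  )
  expect_equal(nrow(none), 0)
})

test_that("randomized intersections match a per-base brute-force oracle", {
  set.seed(33)
  cpgs <- tibble::tibble(chrom = "chr1", pos = seq(0, 9999, 5))
  rand_set <- function(n) {
    start <- sort(sample.int(9000, n))
    tibble::tibble(chrom = "chr1", start = start,
                   end = start + sample(200:800, n),
                   n_cpgs = 10, direction = "hyper", q_max = runif(n, 5, 50))
  }
  for (rep in 1:5) {
    a <- rand_set(6)
    b <- rand_set(6)
    got <- three_way_intersect(a, b, cpgs, min_cpgs = 1)
    # per-base oracle over a 10 kb toy
    bases <- 0:9999
    in_a <- rep(FALSE, 10000)
    in_b <- rep(FALSE, 10000)
    for (k in seq_len(nrow(a))) {
      in_a[bases >= a$start[k] & bases < a$end[k]] <- TRUE
    }
    for (k in seq_len(nrow(b))) {
      in_b[bases >= b$start[k] & bases < b$end[k]] <- TRUE
    }
    covered <- sort(unique(unlist(purrr::map(seq_len(nrow(got)), function(k) {
      seq(got$start[k], got$end[k] - 1)
    }))))
    expect_equal(as.integer(covered %||% integer(0)),
                 as.integer(bases[in_a & in_b]))
  }
})

test_that("array methylation adjustment follows the representativeness ratio", {
  expect_equal(adjust_array_methylation(0.4, 0.5, 0.5), 0.4)   # identity
  expect_equal(adjust_array_methylation(0.9, 0.9, 0.6), 1)     # capped
  expect_equal(adjust_array_methylation(0.4, 0.6, 0.3), 0.8)
  expect_equal(adjust_array_methylation(0.4, 0.6, 0), 0.4)     # fallback
})

test_that("lineage assignment applies the parsimony rules", {
  build_panel <- function(amh, nea, den, chimp) {
    pos <- seq(0, 990, 10)
    tr <- function(m) tibble::tibble(chrom = "chr1", pos = pos,
                                     methylation = m)
    tibble::tibble(
      id = c("amh", "nea", "den", "chimp"),
      group = c("AMH", "Neanderthal", "Denisovan", "chimpanzee"),
      technology = c("reconstructed", "reconstructed", "reconstructed",
                     "WGBS"),
      core = c(TRUE, TRUE, TRUE, FALSE),
      full_map_ref = NA_character_,
      methylation = list(tr(amh), tr(nea), tr(den), tr(chimp))
    )
  }
  dmr <- tibble::tibble(chrom = "chr1", start = 0, end = 1000,
                        n_cpgs = 100, direction = "hyper", q_max = 30,
                        specific_to = "AMH")

  # textbook parsimony: archaics cluster with the outgroup -> AMH branch
  p <- build_panel(0.9, 0.2, 0.2, 0.2)
  expect_equal(assign_lineage(dmr, p)$lineage, "AMH")

  # AMH clusters with the outgroup -> archaic ancestor branch
  p2 <- build_panel(0.2, 0.9, 0.9, 0.2)
  out2 <- assign_lineage(dmr, p2)
  expect_equal(out2$lineage, "archaic")

  # Neanderthal-specific: both others must be closer to the chimpanzee
  dmr_nea <- dplyr::mutate(dmr, specific_to = "Neanderthal")
  p3 <- build_panel(0.2, 0.9, 0.2, 0.2)
  expect_equal(assign_lineage(dmr_nea, p3)$lineage, "Neanderthal")

  # mosaic pattern is inconclusive and discarded
  p4 <- build_panel(0.9, 0.2, 0.9, 0.5)
  out4 <- assign_lineage(dmr, p4)
  expect_true(is.na(out4$lineage))
  expect_equal(out4$assign_status, "inconclusive")

  # no outgroup data over the DMR
  p5 <- build_panel(0.9, 0.2, 0.2, 0.2)
  p5$methylation[[4]] <- dplyr::filter(p5$methylation[[4]], pos >= 5000)
  out5 <- assign_lineage(dmr, p5)
  expect_equal(out5$assign_status, "no_outgroup_data")
})

test_that("the range-exclusion filter keeps only fixed DMRs", {
  pos <- seq(0, 990, 10)
  tr <- function(m) tibble::tibble(chrom = "chr1", pos = pos, methylation = m)
  panel <- tibble::tibble(
    id = c("a1", "a2", "a3", "n1", "d1", "c1"),
    group = c("AMH", "AMH", "AMH", "Neanderthal", "Denisovan", "chimpanzee"),
    technology = "WGBS",
    core = FALSE,
    full_map_ref = NA_character_,
    methylation = list(tr(0.85), tr(0.8), tr(0.9), tr(0.2), tr(0.3), tr(0.25)),
    counts = vector("list", 6),
    meth_counts = vector("list", 6)
  )
  dmr <- tibble::tibble(chrom = "chr1", start = 0, end = 1000, n_cpgs = 100,
                        direction = "hyper", q_max = 30, lineage = "AMH")
  expect_true(variability_filter(dmr, panel)$fixed)

  # one AMH sample inside the archaic range breaks fixation
  panel2 <- panel
  panel2$methylation[[2]] <- tr(0.26)
  expect_false(variability_filter(dmr, panel2)$fixed)

  # the fixation margin discards marginal separations
  panel3 <- panel
  panel3$methylation[[2]] <- tr(0.4)
  expect_true(variability_filter(dmr, panel3)$fixed)
  expect_false(variability_filter(dmr, panel3, min_gap = 0.25)$fixed)
})

test_that("range-filter decisions match a brute-force min/max oracle", {
  set.seed(55)
  pos <- seq(0, 990, 10)
  tr <- function(m) tibble::tibble(chrom = "chr1", pos = pos, methylation = m)
  for (rep in 1:20) {
    groups <- c("AMH", "AMH", "AMH", "Neanderthal", "Neanderthal",
                "Denisovan", "chimpanzee")
    vals <- runif(7)
    panel <- tibble::tibble(
      id = paste0("s", 1:7), group = groups, technology = "WGBS",
      core = FALSE, full_map_ref = NA_character_,
      methylation = purrr::map(vals, tr),
      counts = vector("list", 7), meth_counts = vector("list", 7)
    )
    dmr <- tibble::tibble(chrom = "chr1", start = 0, end = 1000,
                          n_cpgs = 100, direction = "hyper", q_max = 10,
                          lineage = "AMH")
    got <- variability_filter(dmr, panel)$fixed
    der <- vals[groups == "AMH"]
    cmp <- vals[groups != "AMH"]
    want <- all(der > max(cmp)) || all(der < min(cmp))
    expect_equal(got, want)
  }
})
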