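test_that("beta values are methylated over total signal", {
  expect_equal(beta_value(3, 1), 0.75)
  expect_equal(beta_value(5, 0), 1)
  expect_equal(beta_value(2, 2), 0.5)
  expect_true(is.na(beta_value(0, 0)))
  expect_error(beta_value(-1, 2), "non-negative")
})

test_that("hypergeometric enrichment matches exact tail enumeration", {
  # exact tail sum oracle on the skeleton/voice-sized instance:
  # query 100, 31 hits; background 1789 with 254 term members
  exact_tail <- function(k, K, n, N) {
    sum(vapply(k:min(K, n), function(x) {
      choose(K, x) * choose(N - K, n - x) / choose(N, n)
    }, numeric(1)))
  }
  bg <- paste0("g", 1:1789)
  term_genes <- bg[1:254]
  query <- c(bg[1:31], bg[255:323])  # 31 hits among 100 query genes
  ann <- tibble::tibble(gene = term_genes, term = "voice")
  res <- term_enrichment(query, bg, ann)
  expect_equal(res$n_query, 31)
  expect_equal(res$p, exact_tail(31, 254, 100, 1789), tolerance = 1e-12)
  expect_equal(res$fold, (31 / 100) / (254 / 1789))

  # a query drawn uniformly has fold around 1
  set.seed(8)
  folds <- replicate(200, {
    q <- sample(bg, 100)
    term_enrichment(q, bg, ann)$fold
  })
  expect_lt(abs(mean(folds) - 1), 0.05)

  expect_error(term_enrichment(character(0), bg, ann), "empty")
  expect_error(term_enrichment("not_in_bg", bg, ann), "subset")
})

test_that("BH-adjusted q values are monotone in p rank", {
  bg <- paste0("g", 1:500)
  ann <- tibble::tibble(
    gene = c(bg[1:50], bg[51:250], bg[251:400]),
    term = c(rep("a", 50), rep("b", 200), rep("c", 150))
  )
  res <- term_enrichment(bg[1:60], bg, ann)
  expect_true(all(diff(res$q[order(res$p)]) >= -1e-12))
})

test_that("the 2xk chi-square comparison uses the shared contingency logic", {
  out <- enrichment_chisq(c(31, 40), c(100, 300))
  oracle <- chisq.test(rbind(c(31, 40), c(69, 260)))
  expect_equal(out$statistic, unname(oracle$statistic))
  expect_equal(out$p, oracle$p.value)
  expect_error(enrichment_chisq(c(5), c(10)), "at least 2")
  expect_error(enrichment_chisq(c(11, 1), c(10, 10)), "exceed")
})

test_that("exact binomial phenotype-direction tails", {
  expect_equal(phenotype_direction_binomial(9, 9), 2^-9)
  # brute-force tail for 26 of 31
  oracle <- sum(choose(31, 26:31)) / 2^31
  expect_equal(phenotype_direction_binomial(26, 31), oracle,
               tolerance = 1e-12)
  expect_gt(phenotype_direction_binomial(5, 10), 0.5)
  expect_error(phenotype_direction_binomial(3, 0), "total")
  # agreement with the exact reference implementation
  expect_equal(phenotype_direction_binomial(18, 22),
               binom.test(18, 22, alternative = "greater")$p.value,
               tolerance = 1e-12)
})

test_that("derived-CpG density counts per-window DMR membership", {
  cpgs <- tibble::tibble(chrom = "chr1", pos = seq(0, 99999, 100))
  dmrs <- tibble::tibble(chrom = "chr1", start = 20000, end = 30000)

  tiled <- derived_cpg_density(dmrs, cpgs, mode = "tiled",
                               window_size = 10000)
  # per-CpG membership oracle
  oracle <- vapply(tiled$window_start, function(ws) {
    p <- cpgs$pos[cpgs$pos >= ws & cpgs$pos < ws + 10000]
    mean(p >= 20000 & p < 30000)
  }, numeric(1))
  expect_equal(tiled$fraction, oracle)

  centered <- derived_cpg_density(dmrs, cpgs, mode = "dmr_centered",
                                  window_size = 10000)
  expect_equal(centered$fraction, 1)  # window fully inside the DMR

  none <- derived_cpg_density(dmrs[0, ], cpgs, mode = "tiled",
                              window_size = 10000)
  expect_true(all(none$fraction == 0))
})

test_that("methylation-expression scan finds the best-correlated window", {
  tissues <- paste0("t", 1:21)
  set.seed(10)
  expr_vals <- runif(21, 1, 10)

  # perfectly linear: expression = 5 - 2 * methylation
  meth <- tibble::tibble(pos = seq_len(30))
  for (ti in seq_along(tissues)) {
    meth[[tissues[ti]]] <- rep((5 - expr_vals[ti]) / 2, 30)
  }
  expr <- tibble::tibble(gene = "G1")
  for (ti in seq_along(tissues)) expr[[tissues[ti]]] <- expr_vals[ti]
  res <- methylation_expression_scan(meth, expr, window = 25)
  expect_equal(res$r, -1, tolerance = 1e-9)
  expect_lt(res$p, 1e-12)

  # zero-variance methylation is skipped
  meth0 <- meth
  for (ti in tissues) meth0[[ti]] <- 0.5
  expect_equal(nrow(methylation_expression_scan(meth0, expr, window = 25)), 0)

  # a planted high-correlation sub-window is located
  n_cpg <- 40
  meth2 <- tibble::tibble(pos = seq_len(n_cpg))
  base_sig <- scale(expr_vals)[, 1]
  for (ti in seq_along(tissues)) {
    col <- rnorm(n_cpg, 0.5, 0.05)
    col[9:33] <- 0.5 + 0.2 * base_sig[ti] + rnorm(25, 0, 0.03)
    meth2[[tissues[ti]]] <- pmin(pmax(col, 0), 1)
  }
  res2 <- methylation_expression_scan(meth2, expr, window = 25)
  expect_gt(abs(res2$r), 0.85)
})

test_that("matched placement permutation behaves analytically", {
  set.seed(12)
  # uniform-composition genome of 1 Mb in 10 kb bins
  genome <- tibble::tibble(chrom = "chr1",
                           start = seq(0, 990000, 10000),
                           end = seq(10000, 1000000, 10000),
                           gc = 0.5, cpg_density = 0.02)
  dmrs <- tibble::tibble(chrom = "chr1",
                         start = seq(100000, 900000, 100000),
                         end = seq(100000, 900000, 100000) + 1000)
  # targets tile 10% of the genome
  targets <- tibble::tibble(chrom = "chr1",
                            start = seq(0, 900000, 100000),
                            end = seq(0, 900000, 100000) + 10000)
  res <- matched_interval_permutation(dmrs, targets, genome, n_perm = 200,
                                      seed = 5)
  # unmatched composition: null overlap ~ 10% of 9 DMRs
  expect_lt(abs(res$null_mean - 0.1 * nrow(dmrs)), 0.5)
  expect_equal(length(res$null), 200)
  expect_gte(res$p, 1 / 201)

  res2 <- matched_interval_permutation(dmrs, targets, genome, n_perm = 50,
                                       seed = 9)
  res3 <- matched_interval_permutation(dmrs, targets, genome, n_perm = 50,
                                       seed = 9)
  expect_identical(res2$null, res3$null)

  # degenerate whole-genome target: observed = all DMRs, and the null is
  # saturated too, so the permutation p cannot show enrichment
  whole <- tibble::tibble(chrom = "chr1", start = 0, end = 1e6)
  res4 <- matched_interval_permutation(dmrs, whole, genome, n_perm = 50,
                                       seed = 2)
  expect_equal(res4$observed, nrow(dmrs))
  expect_equal(res4$null_mean, nrow(dmrs))
  expect_equal(res4$p, 1)
})

test_that("nearest-feature distances and their permutation null", {
  dmrs <- tibble::tibble(chrom = "chr1",
                         start = c(1000, 50000), end = c(2000, 51000))
  feats <- tibble::tibble(chrom = "chr1", pos = c(1500, 50500))
  sizes <- c(chr1 = 100000)
  res <- nearest_feature_distance_test(dmrs, feats, sizes, n_perm = 100,
                                       seed = 3)
  expect_equal(res$observed_median, 0)
  expect_equal(res$p, 1 / 101)

  one <- nearest_feature_distance_test(
    tibble::tibble(chrom = "chr1", start = 100, end = 300),
    tibble::tibble(chrom = "chr1", pos = 5000), sizes, n_perm = 10, seed = 4)
  expect_equal(one$observed_median, 4800)  # |midpoint 200 - 5000|
})
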