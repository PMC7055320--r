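# Small shared fixtures, built in code at test time.

# A compact synthetic panel: one chromosome, a few thousand CpGs, one planted
# DMR per lineage (both directions covered across lineages).
small_config <- function(seed = 7, cpgs = 6000,
                         lineages = c("AMH", "Neanderthal", "Denisovan",
                                      "archaic")) {
  directions <- rep(c("hyper", "hypo"), length.out = length(lineages))
  sim_config(
    n_chromosomes = 1, cpgs_per_chromosome = cpgs,
    planted_dmrs = tibble::tibble(
      lineage = lineages, span_cpgs = 60, delta = 0.6,
      direction = directions
    ),
    seed = seed
  )
}

# fixtures below ~4000 CpGs cannot hold four well-separated planted DMRs;
# plant a single one there
small_panel <- function(seed = 7, cpgs = 6000,
                        lineages = if (cpgs >= 4000) {
                          c("AMH", "Neanderthal", "Denisovan", "archaic")
                        } else "AMH") {
  simulate_panel(small_config(seed = seed, cpgs = cpgs, lineages = lineages))
}

# a flat methylation track (single chromosome, unit spacing scaled by `by`)
flat_track <- function(n, methylation = 0.8, by = 20L, chrom = "chr1") {
  tibble::tibble(chrom = chrom, pos = seq(0L, by = by, length.out = n),
                 methylation = methylation)
}

# independent naive CUSUM recursion used as an oracle against cusum()
naive_cusum <- function(l, pos, gap_nt) {
  l[is.na(l)] <- 0
  q <- numeric(length(l))
  prev <- 0
  gap <- c(FALSE, diff(pos) > gap_nt)
  for (i in seq_along(l)) {
    q[i] <- max(prev + l[i], 0)
    if (gap[i]) q[i] <- 0
    prev <- q[i]
  }
  q
}

# brute-force excursion scan: every maximal zero-delimited positive interval,
# peak = leftmost maximum
naive_excursions <- function(q) {
  out <- list()
  i <- 1
  n <- length(q)
  while (i <= n) {
    if (q[i] > 0) {
      j <- i
      while (j < n && q[j + 1] > 0) j <- j + 1
      seg <- q[i:j]
      m <- i + which.max(seg) - 1
      out[[length(out) + 1]] <- c(a = i, b = j, m = m, q_max = max(seg))
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (length(out) == 0) {
    return(data.frame(a = integer(), b = integer(), m = integer(),
                      q_max = numeric()))
  }
  as.data.frame(do.call(rbind, out))
}
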