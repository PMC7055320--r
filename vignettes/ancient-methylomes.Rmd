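---
title: "Reconstructing and comparing ancient DNA methylomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing and comparing ancient DNA methylomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleomethyl)
library(dplyr)
```

## The measurement model

In ancient DNA, methylated cytosines deaminate post-mortem into thymines,
while unmethylated cytosines (after the standard uracil-excision library
treatment) do not leave a C→T signal. At CpG site $i$ with true methylation
$\psi_i \in [0,1]$, read coverage $n_i$, and a genome-wide deamination rate
$\pi$, the observed thymine count is binomial:

$$t_i \sim B(n_i,\ \pi\,\psi_i).$$

The raw per-site signal is the C→T ratio $t_i/n_i$, which estimates
$\pi\psi_i$. Because $\pi$ is small (a few percent), single sites are almost
uninformative and everything downstream rests on aggregation across
neighbouring CpGs.

## Reconstruction

`reconstruct_methylome()` converts a count track to a methylation track in
three steps.

1. **Pre-mortem filtering** (`apply_premortem_filters()`): sites that look
   like germline C→T substitutions rather than post-mortem damage are
   removed — sites where A+G reads outnumber C+T reads, sites with C→T ratio
   above 0.25 (0.5 for low-coverage samples), sites whose opposite-strand
   G→A ratio exceeds one sequencing error per position (single-stranded
   libraries only), and sites covered by more than 100 reads (suspected PCR
   duplicates).
2. **Smoothing** (`smooth_ct_ratio()`): a sliding window of 25 CpGs
   (50 for low-coverage samples), centred and truncated at chromosome ends.
   The window value is the *pooled* ratio $\sum t / \sum n$. Pooling weights
   sites by coverage and is the maximum-likelihood estimate of a shared
   binomial rate, which is why we prefer it over averaging per-site ratios;
   a `ratio_mean` mode exists for sensitivity analyses.
3. **Linear rescaling** (`to_methylation()`): zero ratio maps to 0%
   methylation and $\mu_{100}$ — the mean ratio at positions that are fully
   methylated in a modern bone reference — maps to 100%; larger ratios are
   capped at 100%. For tooth samples no matched modern reference exists, so
   $\mu_{100}$ is set to $1/0.75$ times the genome-wide mean ratio, i.e. the
   genome-wide mean is assumed to sit at 75% methylation, the genome-wide
   mean of a modern bone methylome. We use the exact $1/0.75$ rather than
   the rounded $1.33$.

The deamination rate $\pi$ is estimated by `estimate_pi()` as the pooled
C→T ratio over fully methylated reference positions. With a measured (WGBS)
reference, "fully methylated" is relaxed to $\ge 0.95$ because finite-
coverage bisulfite values rarely equal exactly 1; this biases $\hat\pi$
down by a few percent of its value, which cancels in reconstruction (the
same quantity serves as $\mu_{100}$) and is immaterial for detection.

## DMR detection

`detect_dmrs()` compares a (filtered, unsmoothed) count track against a
reference methylation track $\varphi_i$ — the smoothed reconstruction or a
measured methylome of another sample. For a minimum difference of interest
$\Delta$ (default 0.5), the per-site log-likelihood-ratio statistics are

$$\ell_i^{+} = \ln\frac{\Pr(t_i \mid n_i, \pi(\varphi_i + \Delta))}
{\Pr(t_i \mid n_i, \pi \varphi_i)},\qquad
\ell_i^{-} = \ln\frac{\Pr(t_i \mid n_i, \pi(\varphi_i - \Delta))}
{\Pr(t_i \mid n_i, \pi \varphi_i)},$$

testing hyper- and hypomethylation of the test sample. The statistics feed a
cumulative-sum scan, $Q_0 = 0$, $Q_i = \max(Q_{i-1} + \ell_i, 0)$, with the
score reset to zero wherever consecutive CpGs are more than $\delta = 1000$
nt apart. Each maximal excursion of $Q$ above zero, truncated at its
(leftmost) peak $m$, is a candidate DMR $[a, m]$ with score $Q_m$;
candidates with fewer than 50 CpGs (twice the smoothing window) are
discarded.

Three numerical choices matter here:

* **Reference clipping.** $\varphi$ is clipped to $[0.01, 0.99]$ so
  $\ln(1+\Delta/\varphi)$ and the hypo branch stay finite and no single
  site dominates an excursion.
* **Genome-wide evaluation.** Because every rate is scaled by $\pi$, the
  alternative success probability $\pi(\varphi+\Delta)$ is a valid binomial
  rate even where $\varphi + \Delta > 1$, and evaluating $\ell^{+}$ there
  yields the negative drift that lets $Q$ decay across the (majority)
  highly methylated genome. Treating such sites as zero-contribution
  instead leaves $Q$ flat over long stretches, so isolated artifacts chain
  into spurious excursions; we therefore evaluate the statistics at every
  site, flooring the hypo alternative level at $\varphi - \Delta \ge 0.01$
  (values of $-\infty$ are clamped at $-10^6$).
* **Excursion-level consistency.** A candidate must also look like a DMR in
  effect size: the pooled methylation estimate of the test sample over
  $[a,m]$ (pooled C→T rate divided by $\pi$, capped at 1) must differ from
  the mean reference methylation in the claimed direction by at least
  $\Delta/2$. The per-site likelihoods are the primary enforcement of the
  full $\Delta$; the pooled estimate is biased toward the reference by
  window edges and by the $\mu_{100}$ scale, so the consistency check runs
  at half the target difference — enough to reject long weak-drift
  artifacts (which sit one order of magnitude below $\Delta$) without
  re-penalizing estimator noise on genuine DMRs.

For comparisons of two full bisulfite methylomes, `fisher_window_dmrs()`
implements the windowed alternative: 25-CpG windows stepping one CpG,
Fisher's exact test on pooled read counts, Benjamini–Hochberg control at
0.05, a pooled methylation difference of at least 0.5, and merging of
surviving overlapping windows.

## Threshold calibration by simulated noise

Reconstruction noise (deamination stochasticity, the sliding window, uneven
coverage) can push $Q$ over any fixed threshold. `calibrate_thresholds()`
estimates this directly: treating the reference map as truth, it redraws
$t_i \sim B(n_i, \pi \psi_i)$ with the real sample's coverage, runs the
identical detector, and repeats this 100 times. The score thresholds
$Q_T^{+}$ and $Q_T^{-}$ are then the smallest observed peak scores for
which the mean number of simulated DMRs is below 5% of the number of real
DMRs at the same threshold. The search grid is the sorted multiset of real
peak scores — the empirical FDR is a step function of the threshold on that
grid, so nothing finer is needed. Thresholds are calibrated per direction;
a pooled summary is also reported. If no threshold meets the target the
threshold is $+\infty$ and nothing is reported, which is the safe failure
mode. `self_comparison_check()` provides the companion sanity check: a
deamination map compared against its own reconstruction should yield a
negligible DMR count (about two orders of magnitude below a genuine
between-sample comparison).

## The comparative pipeline

`run_pipeline()` executes the five-step design on a `sample_panel`:

1. **Reciprocal two-way detection** among the three high-quality
   reconstructed "core" methylomes (one per hominin), each pair compared in
   both orientations (counts of one sample against the reconstruction of
   the other, and vice versa) at the calibrated thresholds. The two runs'
   DMRs are union-merged; a region found by only one orientation is kept
   but flagged, since reciprocity guards against reconstruction bias rather
   than noise, and the real stringency comes next.
2. **Three-way intersection** (`three_way_intersect()`): a DMR specific to
   one hominin must appear against both other hominins with agreeing
   direction; only the overlapping portion is kept, re-checked against the
   50-CpG minimum, with the smaller of the two scores.
3. **FDR control** is the calibration above, applied at detection time.
4. **Lineage assignment** (`assign_lineage()`): with the chimpanzee as
   outgroup, the distance of hominin $H$ to the chimpanzee over a DMR is
   the mean absolute per-CpG methylation difference across sites shared by
   the two maps (at least 10 shared CpGs, else the DMR is set aside as
   lacking outgroup data). An AMH-specific DMR is placed on the AMH branch
   if both archaic hominins are closer to the chimpanzee, on the archaic
   ancestor branch if the AMH is closer than both, and discarded otherwise;
   Neanderthal- and Denisovan-specific DMRs require both other hominins to
   be closer to the chimpanzee. In strict mode, chimpanzee array samples
   contribute DMR-level distances after the probe-representativeness
   correction below.
5. **Fixation filtering** (`variability_filter()`): a DMR is kept only if
   every sample of the derived group lies strictly outside the range of
   DMR-mean methylation across all comparison samples, on a consistent
   side. Low-resolution samples participate as comparison members. The
   pipeline additionally requires the separation to be at least the
   detector's consistency difference ($\Delta/2$), so that fixation is
   claimed on a magnitude commensurate with the DMR definition rather than
   on a tie-break; the exported function defaults to the plain
   range-exclusion rule.

DMR-level methylation per sample is computed with the estimator suited to
each technology: reconstructed samples use the pooled C→T rate over the
interval divided by $\mu_{100}$ (variance-optimal and free of smoothing
edge effects), WGBS samples pool read counts, and array samples take the
probe mean corrected for probe placement:
$m' = \min(m \cdot \bar\psi_{\text{all}}/\bar\psi_{\text{probed}},\ 1)$,
where the ratio compares the full reference map's mean over all DMR CpGs
with its mean over the probed CpGs. The printed form of this correction
divides sums over sets of different sizes; we use means, which reduce to
the same ratio up to the factor $I/J$ and make $m' = m$ exact when probes
are representative.

Two filtering modes are provided. `"wgbs"` uses only reconstructed and
WGBS maps, preserving an unbiased genomic distribution of DMRs; `"strict"`
adds array samples (with the correction above) for more power at the cost
of probe-placement bias. Strict mode can only remove DMRs relative to WGBS
mode.

## The synthetic panel

`simulate_panel()` generates everything the pipeline consumes, so every
stage is testable without external data. The generator emulates:

* **A blocky baseline methylome**: alternating highly methylated background
  (beta-distributed around 0.92, geometric block length with mean 160
  CpGs) and unmethylated islands (around 0.05, mean 40 CpGs), giving the
  bimodal per-site distribution and ~0.75 genome-wide mean typical of bone
  WGBS, and — critically — the regional structure that makes a smoothed
  reference meaningful.
* **Planted lineage-specific DMRs**: non-overlapping spans (default ten
  60-CpG shifts of 0.6 per lineage, both directions) assigned to the AMH,
  Neanderthal, Denisovan, or archaic-ancestor branch. Inside a planted
  region the pre-shift baseline is set to 0.2 (hyper) or 0.8 (hypo) so the
  full shift fits in $[0,1]$, and the homogeneous domain extends 30 CpGs
  beyond the shifted span: a DMR sits inside a coherent regulatory region,
  not astride a methylation block boundary. Planted regions are separated
  by at least 300 CpGs so two planted differences cannot fuse into one
  excursion.
* **Within-group variability** as one per-sample offset on the logit scale
  (sd 0.15 by default). No published estimate of between-individual bone
  methylome dispersion at this resolution exists, so the default is a
  free parameter chosen to be visible to the range filter without
  swamping the planted contrast.
* **Technology mix**: per-sample binomial deamination counts for
  reconstructed samples (negative-binomial coverage, mean 30, dispersion 5,
  occasionally exceeding the 100-read cap so the duplicate filter is
  exercised), read-count WGBS maps, array probe subsets (5% of CpGs, small
  measurement noise), and an RRBS mode whose probe placement is biased
  toward unmethylated sites.

What the generator does **not** emulate: sequence context, mapping and
bisulfite-conversion artifacts, correlated (regional) within-individual
variability, tissue- or age-specific programs, and real probe ascertainment.
Passing tests therefore demonstrate the statistical machinery under the
stated model, not robustness to every artifact of real ancient data.

## Problem sizes and runtime

The test and acceptance workloads run on panels of 2 chromosomes ×
20,000 CpGs (40,000 sites, 13 samples) with 100 calibration simulations
per detection run — large enough that planted 60-CpG DMRs are comfortably
above the 50-CpG minimum and that calibration grids are well populated,
small enough that a full pipeline run takes well under a minute on one
core. The parameter-recovery experiment repeats the full pipeline over 20
seeded replicates.

## Known limitations

* With a single Denisovan (and effectively single Neanderthal) sample, a
  sample-specific deviation is not distinguishable from a group difference;
  the fixation margin suppresses most such events but the residual rate is
  bounded below by the 5% FDR target of the calibration itself.
* The detector's power is asymmetric: hypermethylation of the test sample
  adds thymines (strong evidence), hypomethylation removes them (weaker),
  so hypo DMRs calibrate to lower thresholds and recover slightly less
  reliably.
* Reported intervals $[a, m]$ inherit the excursion's noise ramp on the
  left and truncate at the peak; boundaries are approximate at the scale
  of the smoothing window.
* The lineage rules are parsimony on three taxa plus an outgroup; gene
  flow, incomplete lineage sorting, and convergent changes are outside the
  model.
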