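# netchange

Single-subject detection of longitudinal changes in a resting-state
functional brain network.

## The problem

Group-level connectomics averages away the individual. When the question is
whether *this* patient's brain network reorganized between a baseline and a
post-treatment scan — with no control group and n = 1 — standard
paired statistics do not apply. `netchange` implements a subject-level
nonparametric approach: the spread of a network metric **across the
subject's own brain regions at baseline** serves as the reference
distribution against which each region's pre/post change is judged.

## The method

From two scans of denoised, ROI-averaged time series (time × ROI):

1. **Network construction.** The ROI–ROI Pearson correlation matrix of each
   scan is binarized at |r| > 0.5 (strict; sign discarded). The analytic
   significance of the cutoff is the one-sided Student-t tail
   t = r·sqrt((N−2)/(1−r²)) with N−2 degrees of freedom — for r = 0.5 and
   N = 273 volumes, p = 5.64e-19.
2. **Nodal graph metrics.** For every ROI i: degree D, clustering
   coefficient CC, betweenness centrality BC (normalized by (R−1)(R−2)/2),
   nodal global efficiency GE(i) = mean_{j≠i} 1/d_ij, local efficiency LE
   (efficiency of the neighbor-induced subgraph), and average path length
   APL over reachable peers.
3. **Kernel-resampling null.** Per metric, a Gaussian kernel density
   (Silverman bandwidth) is fitted to the baseline values across ROIs; the
   null distribution of chance differences is built by drawing two samples
   from it and differencing, m = 100,000 times. Each ROI's observed
   (post − baseline) difference gets the two-sided empirical p-value
   p = #(|null| ≥ |observed|)/m, and Benjamini–Hochberg FDR at q < 0.1 is
   applied across the ROIs of each metric.
4. **Deviation screen.** Within each scan, each metric is z-scored across
   ROIs (population SD). ROIs with |z| > 2 in either scan are flagged and
   their trajectory classified as *normalized* (moved ≥ 0.5 SD toward the
   mean), *diverged* (≥ 0.5 SD away), or *stable*.

A block-covariance AR(1) simulator generates paired synthetic scans with
plantable connectivity changes (detach / attach / reassign an ROI), so the
whole pipeline is testable with known ground truth.

## Worked example

```r
library(netchange)

spec <- make_block_covariance(R = 132, n_blocks = 6,
                              rho_in = 0.55, rho_out = 0.1)
pair <- simulate_scan_pair(spec,
  planted = list(list(target_rois = 1, mode = "detach", delta = 0.55)),
  T_baseline = 273, T_post = 273, seeds = c(11, 12))

fit <- netchange(pair$baseline, pair$post, n_null_draws = 10000, seed = 7)
print(fit)
```

```
Single-subject connectome change analysis
  ROIs: 132  edges (baseline/post): 1190 / 1106 
  threshold |r| > 0.5  (analytic p: 5.64e-19 baseline, 5.64e-19 post)
  significant ROI x metric rows at q < 0.1 : 16 
```

The detached region (ROI_0001) is recovered with large significant drops —
its nodal efficiency falls from 0.156 to 0 (q = 0.013), clustering from
0.89 to 0 (q = 0.0026), local efficiency from 0.95 to 0 (q = 0.0026) — and
the deviation screen shows it at |z| = 9.2, far beyond the 2-SD flag line.
`summary(fit)` lists every significant row; `plot(fit, metric = "GE")`
draws the per-ROI stem plots with ±1/2/3 SD reference lines.

File-based use: `run_change_analysis("baseline.tsv", "post.tsv", "out/")`
writes correlation matrices, adjacencies, metric tables, the test-result
table, the deviation report and a reproducibility config echo; a thin CLI
wrapper lives at `inst/scripts/netchange-cli.R` (subcommands `analyze`,
`simulate`).

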