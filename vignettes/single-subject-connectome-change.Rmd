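---
title: "Detecting single-subject connectome change: model, assumptions, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting single-subject connectome change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netchange)
```

## The inference problem

With one subject and two scans there is no sampling distribution in the
usual sense: no replicate subjects, no replicate scans. The approach
implemented here substitutes *space for replication*: the values of a
network metric across the subject's own 132 brain regions at baseline are
treated as draws from that subject's metric distribution, and the question
"how big a pre/post change could arise by chance?" is answered by
resampling from a smooth estimate of that cross-regional distribution.
This is a pragmatic, exploratory device, not a randomization test with
exact guarantees — the calibration study below quantifies exactly how far
from exact it is.

## Pipeline and parameters

**Network construction.** Each scan's ROI-averaged time series (T × R)
yields a Pearson correlation matrix; edges are the pairs with |r| > τ,
strict inequality, default τ = 0.5 (dimensionless). Sign is recorded but
not used by the metrics. The analytic significance of τ is the one-sided
upper tail of t = r√((N−2)/(1−r²)) on N−2 df; at τ = 0.5, N = 273 this is
5.64e-19. A two-sided option exists (`sided = "two"`) and gives twice that
value; the one-sided tail is the default because it is what the printed
per-scan p-values of the motivating use case correspond to. Constant ROI
columns are an error, not silently r = 0: a fabricated zero would delete
edges invisibly.

**Nodal metrics.** Six per-ROI metrics on the binary undirected graph:
degree D (integer, 0..R−1); clustering coefficient CC ∈ [0,1] (0 when
D ≤ 1); betweenness centrality BC with all-shortest-paths counting,
normalized by (R−1)(R−2)/2 so values are comparable across graph sizes (an
unnormalized option is kept); nodal global efficiency GE(i) = mean of
1/d_ij over j ≠ i with 1/∞ = 0; local efficiency LE(i), the same average
computed inside the subgraph induced by i's neighbors with i removed
(Latora–Marchiori convention), 0 when D ≤ 1; and average path length
APL(i), the mean hop count to *reachable* peers, flagged undefined for
isolated nodes and excluded from downstream testing for that metric.
Distances, betweenness and local clustering are computed via igraph; the
efficiency and path-length conventions for disconnected graphs are this
package's, stated above, and every metric is verified against independent
brute-force oracles (Floyd–Warshall distances; the σ_sv·σ_vt path-counting
identity for betweenness) in the test suite.

**Kernel-resampling null.** Per metric: a Gaussian kernel density is
fitted to the baseline values across ROIs — bandwidth h = σ̂·(4/(3n))^(1/5)
(the normal-reference Silverman rule, ≈ 1.06·σ̂·n^(−1/5)), overridable —
and m = 100,000 differences of two independent KDE draws form the null.
Fitting to the *baseline only* is load-bearing: the null's variance comes
from the cross-ROI spread before treatment. The empirical p-value is
two-sided, p = #(|null| ≥ |observed|)/m, because the null is symmetric by
construction and both increases and decreases are of interest. A raw count
of zero is floored at 1/m and flagged (BH needs p > 0; the data only say
p < 1/m). One shared null per metric is drawn — statistically identical to
per-ROI nulls since the fitted density is the same — with a
`fresh_null_per_roi` option for fidelity checks. BH FDR runs within each
metric's family of R ROIs at q < 0.1 (a pooled 6R-family mode exists).
Metrics whose baseline values are constant across ROIs are skipped with a
message: a null model needs spread to exist.

**Deviation screen.** Descriptive, separate from the inference: within
each scan, metrics are z-scored across ROIs using the population SD
(divide by n — the descriptive choice; sample SD available). ROIs beyond
|z| = 2 in either scan are flagged; the pre→post trajectory is
*normalized* if |z| shrank by at least 0.5 SD, *diverged* if it grew by at
least 0.5, else *stable*. The 0.5 margin formalizes what would otherwise
be a visual judgement on stem plots; it is configurable, and the stem
plots (`plot(fit, type = "stem")`) carry the ±1/2/3 SD reference lines for
eyeballing.

## The synthetic-data generator

`make_block_covariance()` builds an R-ROI correlation structure of
`n_blocks` equal blocks: ρ_in within, ρ_out between, positive definiteness
checked by factorization. `simulate_scan()` draws zero-mean multivariate
Gaussian series with optional AR(1) temporal smoothing
(x_t = a·x_{t−1} + √(1−a²)·e_t, stationary start), which preserves the
cross-ROI covariance exactly while shrinking the effective number of
independent volumes, as real fMRI autocorrelation does.
`apply_planted_change()` plants ground truth: *detach* (sever an ROI from
its block), *attach*, or *reassign*.

What it emulates: second-order correlation structure at realistic scale
(132 ROIs, 273 volumes), block organization into functional communities,
per-scan effective-N differences (T may differ between scans), temporal
autocorrelation. What it does not: hemodynamics, physiological noise,
motion, non-Gaussianity, spatially varying SNR. Passing tests therefore
demonstrate the statistical machinery under a faithful second-moment
model, not robustness to fMRI artifacts — those are assumed handled by
upstream denoising, which this package deliberately does not reimplement.

**Generator geometry.** The default spec is 6 blocks of 22 at ρ_in = 0.65,
ρ_out = 0.1. A caution discovered while validating: at T = 273 this
default is *deterministic* under the 0.5 cutoff — every within-block
sample correlation sits > 4 sampling-SDs above the threshold and every
between-block one far below, so the network is always six complete
components, every metric is constant across ROIs, and the kernel null is
undefined (no spread to fit). The simulation studies therefore use
ρ_in = 0.55, which places the population correlation about one
sampling-SD above the cutoff (per-pair edge probability ≈ 0.87): networks
remain dense within blocks and empty between them, but edges are
stochastic and the metrics spread — the regime in which a cross-ROI null
is meaningful. This value was fixed once, on that feasibility argument,
before any calibration was run.

## Simulation studies and what they show

Problem sizes were chosen to run in minutes on one CPU: 200 null pairs and
50 planted-effect repetitions at R = 132, T = 273, with m = 10,000 null
draws (the m = 100,000 default changes nothing but the p-value floor).

**Calibration (null pairs).** With no planted change, each ROI's pre/post
difference is a draw of two iid values of its own metric, and because ROIs
are exchangeable under the block design, the cross-ROI baseline KDE
approximates that marginal. p-values should then be roughly uniform. They
are for the continuously-spread metrics (KS distance from uniform ≈ 0.05
for CC and LE at 200 pairs) and the FDR discovery fraction is well
controlled (≈ 0.03 against the 0.1 level). They are *not* uniform for
degree, nodal efficiency and APL (KS ≈ 0.19) — and the failure is exactly
an atom: ~19% of ROI differences are identically zero (a node in a
saturated block has the same degree, efficiency and path length in both
scans), and a zero difference scores p = 1 against a continuous null. BC
(KS ≈ 0.13) suffers instead from Gaussian-smoothing a zero-inflated,
right-skewed distribution. Both are intrinsic to applying a continuous
kernel null to discrete or degenerate nodal metrics; the effect is
conservative (p pushed toward 1), never anti-conservative, which is the
safe direction for a discovery procedure.

**Power (planted detachment).** Severing one ROI's within-block
correlation entirely (δ = ρ_in) is detected by nodal efficiency in ≈ 96–98%
of repetitions and flagged by the deviation screen (|z| > 2) in 100%,
with ~3% false-positive rows among untouched ROIs. Degree detects in only
≈ 50–70%: the degree null inherits the wide cross-ROI degree spread
(block-mates share sampling noise), so even a complete detachment moves
degree by only ~3 null-SDs, which does not reliably clear the BH hurdle
across 132 ROIs. The degree test is thus conservative by construction —
consistent with degree rarely reaching significance in practice — and
efficiency-type metrics are the sensitive ones under this null.

## Numerical and degenerate-input choices

- Correlation matrices are symmetrized ((C + Cᵀ)/2) and the diagonal set
  to exactly 1 before thresholding; |r| = τ exactly yields no edge.
- p-values of |r| ≥ 1 are an error (the limit is 0; callers must decide).
- Kernel fits require ≥ 8 finite, non-constant values; below that a null
  would be noise pretending to be a distribution.
- Empirical p-values are floored at 1/m with a flag; q-values inherit the
  floor.
- Undefined APL entries (isolated nodes) are excluded per-metric, never
  imputed; the exclusion is reported.
- All randomness flows through explicit integer seeds; a run's config echo
  (JSON) is sufficient to reproduce its outputs byte-for-byte.

## Limitations

Two scans only; no imaging preprocessing (the input must already be
denoised ROI series); binary undirected networks at a single absolute
threshold (no weighted, Fisher-z or density-based variants); the
resampling null is exploratory rather than exact, with the calibration
caveats quantified above; and anatomical layout for network figures is out
of scope (plots use index order).
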