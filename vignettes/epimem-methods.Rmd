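---
title: "Models and methods behind epimem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind epimem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`epimem` re-creates, as a tested pipeline, the computational analysis used to
characterise the enhancer landscape of innate memory (T~IM~) CD8
single-positive thymocytes relative to naive cells and to conventional
antigen-driven memory (T~M~) cells. This vignette explains the models, the
tunable parameters, the synthetic-data generator, and the numerical choices,
in enough detail that a reader can judge what a passing test suite does and
does not demonstrate.

## Peak-atlas interval algebra

All coordinates enter and leave the package as BED (0-based, half-open);
internally everything is a `GRanges`. Two regions are combined only if they
overlap by **at least 1 bp**: book-ended regions (gap 0) are never merged,
which differs from the default of several common merge tools. An *atlas* is
the non-overlapping merge of all peak sets across samples, each atlas region
carrying one logical membership flag per source (again by >= 1 bp overlap).
Strand is carried through I/O but ignored by merging and overlap — peak
calls are unstranded; only the TSS table is stranded.

Point-to-interval distances are measured from the last included base: the
region `chr1:[100,200)` is 51 bp from position 250. Ties between equidistant
points resolve toward the smaller coordinate, for determinism.

## Promoter and enhancer annotation

Two promoter conventions coexist deliberately, selected by pipeline stage:

* **Histone-mark analyses** use a strand-aware window from −5 kb to +2 kb
  around each TSS. Promoters are H3K4me3⁺ merged regions overlapping (>=
  1 bp) any such window; enhancers are H3K4me1⁺ regions at least 2 kb (the
  `enhancer_exclusion`) from every TSS, measured edge-to-TSS, that do not
  overlap any promoter.
* **Accessibility analyses** use the simpler strand-independent ±2 kb
  window: a peak overlapping it is promoter-class, otherwise
  enhancer-class.

"Located between −5 and +2 kb" is read as *overlap* with the window rather
than full containment — the permissive, conventional reading. When an
activity (H3K27ac) region overlaps both a promoter and an enhancer, promoter
precedence applies; regions on chromosomes missing from the TSS table are
enhancer-eligible with a logged warning. These rules make the annotation a
strict partition, which the tests verify (promoter and enhancer sets share
zero bases on every simulated landscape).

## Differential chromatin activity

Replicate counts are pooled (summed) per condition — matching a design where
immunoprecipitations are pooled before sequencing — and both pooled columns
are scaled to the **lowest total library size**, `round(k * Nmin / N)` with
half-away-from-zero rounding. Each region then receives:

* `log2FC = log2((n_a + 1) / (n_b + 1))` — pseudocount 1 keeps (0, 0) at 0;
* a two-sided exact Poisson p-value with equal-split null
  `lambda = (n_a + n_b) / 2`:
  `p = min(1, 2 * min(Pr[X <= min], Pr[X >= max]))`;
* optionally the **library-proportion filter**, expressed as its statistical
  content: conditional on `k_a + k_b`, the raw count `k_a` is
  `Binomial(k_a + k_b, N_a / (N_a + N_b))` under the null, tested exactly and
  two-sided;
* Benjamini–Hochberg q-values (`stats::p.adjust`), with calls requiring
  `q < fdr_alpha` (default 0.05; an 0.001 variant exists for the transgenic
  accessibility comparison) and `|log2FC| > lfc_threshold` (default 0 for
  chromatin, 1 for expression tables).

**Calibration caveat.** The equal-split Poisson test estimates its null rate
from the same two counts it tests. Since `max − lambda = |n_a − n_b| / 2`
while `sd(n_a − n_b) = sqrt(2 lambda)`, rejecting at p < 0.05 requires an
observed difference of about 2.8 standard deviations, so the realised null
rejection rate is ≈ 0.005–0.006 at every depth — markedly conservative
relative to the nominal level (the conditional binomial, by contrast, sits
near 0.045). The practical consequences, which the test suite measures
rather than hides: false-discovery proportions are essentially zero,
sensitivity is high for |log2FC| = 2 at typical depths (≥ 0.93 in the
default simulation), but moderate effects (|log2FC| ≈ 1.5 at mean count
≈ 50, single libraries) are under-called, and downstream cluster
compositions drift accordingly. Deeper libraries or replicate pooling
restore power; the test's exactness and symmetry are unconditional.

## Cross-dataset concordance clustering

Two conventional-memory datasets (an LCMV infection model and a Listeria
infection model) are reduced to one consensus status per enhancer: `up` or
`down` if **at least one** dataset is significant in that direction and the
other is not significantly opposed, else `none` (a strict both-significant
variant is available). Crossing the consensus T~M~ status with the T~IM~
status yields six clusters — gains specific to conventional memory (C1),
shared gains (C2), innate-memory-specific gains (C3), and the mirrored
losses (C4–C6). Contradictory sign pairs are dropped to `none` with a
warning rather than force-assigned; the concordance heatmap has no such
category. Composition percentages are reported per side and sum to 100.

The heatmap fold-change variant takes the **median** of library-normalized
replicate counts per condition before the log-ratio, making single outlier
replicates inert. Cluster-associated genes (nearest TSS by center distance,
ties to the smaller gene id) are compared between the two memory comparisons
with a two-sided Wilcoxon signed-rank test: zeros dropped, exact null by
convolution over the observed (possibly midranked) ranks up to n = 25 —
which stays exact under ties, unlike the classical tabulation — and a
normal approximation with continuity and tie correction beyond.

## Co-binding and motif positional density

Co-binding is plain region-overlap arithmetic: the fraction of EOMES-bound
regions carrying RUNX3 peaks in naive and/or memory cells, and the fraction
already RUNX3-bound in the naive state (the pioneer-factor signature).
Motif positions use a minimal PWM scanner: probabilities get a
pseudo-probability (default 0.01) before a log2-odds transform against a
uniform background; every offset on both strands is scored; `N` contributes
0 bits; ties resolve to the smallest offset with + strand preferred. One
best hit per region is kept — matching a one-site-per-region density — with
no score threshold by default (a threshold is exposed as an option), and
hit *centers* are histogrammed relative to the region center (default
window ±250 bp, bin width 10 bp; the bin width of the original density
display is not documented anywhere we could find, so it is configurable).

## Regulatory-potential target inference

Each gene accumulates contributions from binding-region centers within
100 kb of its TSS, `S = Σ exp(−(0.5 + 4Δ))` with `Δ = |center − TSS| /
100 kb` — a TSS-centered peak contributes `e^−0.5`, a window-edge peak
`e^−4.5`. Score distributions of up- and down-regulated genes (default
grouping: q < 0.05 and |log2FC| > 1) are compared against static genes with
a two-sample KS test (asymptotic Kolmogorov p at effective
`n = n_x n_y / (n_x + n_y)`; exact small-sample p available via
`stats::ks.test`). Because the external package's internal target cutoff is
undocumented, predicted targets use an explicit rule: differentially
expressed genes whose score exceeds a quantile (default 0.5) of the static
score distribution.

## Single-cell correlation

Kendall's tau-b (tie-corrected — digitized fluorescence always carries
ties) measures the association between paired markers per genotype. Two
independent correlations are compared by Fisher z: `atanh(tau)` with
Fieller's variance `0.437 / (n − 4)`, the standard choice for the Fisher
transform of tau (the Pearson-style `1 / (n − 3)` is available for
sensitivity analysis), and a two-sided normal reference. Intensities are
used raw by default with an arcsinh option, since the original transform is
unstated. The loess trend is `stats::loess` with degree 1 and exact
(`surface = "direct"`) evaluation, i.e. local linear regression with
tricube weights, verified in the tests against a per-point weighted
least-squares oracle.

## The synthetic-data generator

Every stage is exercised on data with a machine-readable planted truth.
The generator emulates:

* TSS positions uniform per chromosome with 20 kb minimum spacing, strands
  Bernoulli(0.5);
* H3K4me3 peaks (0.8–1.5 kb) placed inside promoter windows; H3K4me1 peaks
  (0.6–1.2 kb) at least 8 kb from every TSS, mutually separated by >= 2 kb
  — margins chosen so that ±50 bp per-sample boundary jitter can never blur
  a planted class across the 2 kb annotation boundary, which is why exact
  annotation recovery is an achievable (and demanded) target;
* H3K27ac overlaid on 95% of loci; differential enhancers split
  55/34/11 (gains) and 57/36/7 (losses) across the six concordance
  clusters by exact largest-remainder counts, with defaults of 200 regions
  per side;
* Poisson counts at rate `(N_s / N_min) · mu · 2^(beta · memory)`, `mu`
  log-uniform on [20, 500], `beta = ±2` in 10% of regions; a gamma-Poisson
  switch (`overdispersion`) probes robustness to the Poisson assumption;
* EOMES peaks in the shared and innate-memory-specific gain clusters
  (C2/C3) plus a 5% background; RUNX3 co-placed 20–60 bp away for 65% of
  EOMES regions, of which the naive-state subset covers 43% — the
  pre-binding fraction the co-binding stage must recover;
* motif-bearing sequences (background GC 0.42) with the consensus embedded
  at Normal(center, 20 bp) offsets, reverse-complemented half the time;
* expression tables whose differential effects are Normal(±2, 0.5)
  *truncated beyond the |log2FC| = 1 calling threshold* — without
  truncation ~2.3% of draws would fall inside the threshold and planted
  groups would not be exactly recoverable, which is the property the
  generator exists to guarantee;
* bivariate cell intensities from a Gaussian copula with
  `rho = sin(pi tau / 2)` (exact for the bivariate normal) and lognormal
  marginals.

Synthetic motifs are high-information consensus matrices built in code (a
T-box-like `CAGGTGTGAA` and a Runt-like `TGTGGTTT`); no database matrices
are shipped, and the JASPAR-format file under `inst/extdata/` is labelled
synthetic. What the generator does **not** emulate: read-level noise,
GC/mappability bias, overlapping regulatory elements, copy-number effects,
fragment-length structure, or correlated replicates. Passing tests
demonstrate the pipeline's algebra and statistics on data that obey its
model assumptions; they do not certify performance on real sequencing data.

## Determinism and numerical choices

All generation is a pure function of the configuration and its seed; stage
generators derive fixed child seeds and restore the caller's RNG state.
Running the pipeline twice with one seed reproduces every data file byte
for byte; the run manifest is the single exception because it records
per-stage wall time alongside each output's md5 checksum. Normalized counts
round half away from zero (symmetric); p-values are capped into (0, 1];
(0, 0) count pairs give p = 1 by convention; BH is the standard step-up.
Default problem sizes — roughly a tenfold reduction of the motivating
study's region counts (981 promoters, 2010 enhancers, ~2 800 activity
regions), 5 000-region differential simulations, 2 000–5 000 cells — were
chosen so the whole suite runs in well under a minute while keeping
binomial sampling error comfortably inside every stated tolerance; a
`paper_scale` preset reproduces the original magnitudes (9 814 promoters,
20 103 enhancers) for realism runs.

## Known limitations

* The equal-split Poisson test is conservative (see above); it is the
  faithful re-expression of the motivating analysis, not the test we would
  recommend de novo — the conditional binomial is better calibrated.
* Dispersion beyond Poisson is generated but not modelled; there is no
  negative-binomial fitting, TMM, or quantile normalization by design.
* The consensus rule across the two conventional-memory datasets and the
  target-selection cutoff are under-determined by the source material; both
  are exposed as explicit, documented options rather than silent guesses.
* Motif scanning is deliberately minimal (best hit per region); it is not a
  motif-enrichment framework.
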