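# epimem

Innate memory CD8⁺ T cells (T_IM) arise in the thymus under cytokine
signals, without ever meeting their antigen, yet acquire much of the
phenotype of true antigen-experienced memory cells. How much of the
*enhancer* landscape of conventional memory they actually acquire — and
what the transcription factors EOMES and RUNX3 do to chromatin to get them
there — is a question answered by comparing ChIP-seq/ATAC-seq peak
landscapes across naive, innate-memory and conventional-memory cells.

`epimem` implements that comparison as a reusable, fully tested R pipeline
for epigenomics analysts:

* **Peak-atlas interval algebra** — merging with ≥ 1 bp overlap semantics
  (book-ended regions stay separate), atlases with per-sample membership
  flags, Venn counts, overlap fractions, BED I/O (built on
  GenomicRanges).
* **Promoter/enhancer annotation** — promoters are H3K4me3⁺ regions in the
  strand-aware window TSS − 5 kb … TSS + 2 kb; enhancers are H3K4me1⁺
  regions ≥ 2 kb from every TSS with no promoter overlap; accessibility
  peaks use a ± 2 kb TSS rule.
* **Differential chromatin activity** — pooled counts normalized to the
  lowest total library size N_min (counts k ↦ round(k·N_min/N)), exact
  two-sided Poisson test with equal-split null λ = (n_a + n_b)/2,
  log₂ fold-change with pseudocount 1, an exact conditional-binomial
  "proportion of library" filter, and Benjamini–Hochberg FDR.
* **Memory-concordance clustering** — consensus differential status across
  two conventional-memory datasets, six-way clustering against the
  innate-memory calls (C1–C3 gains, C4–C6 losses), composition
  percentages, median-of-replicates fold-changes, Wilcoxon signed-rank
  expression shifts (exact to n = 25, valid under ties).
* **TF co-binding and motifs** — EOMES×RUNX3 overlap fractions including
  naive-state pre-binding, and a minimal log-odds PWM scanner for best-hit
  positional density around region centers.
* **Target inference** — BETA-style regulatory potential
  S = Σ exp(−(0.5 + 4Δ)), Δ = |peak center − TSS|/100 kb, with
  Kolmogorov–Smirnov activating/repressive calls against static genes.
* **Single-cell correlation** — Kendall τ_b with Fisher-z comparison of two
  independent correlations (Fieller variance 0.437/(n − 4)) and loess
  trends.
* **A synthetic-data generator** with a planted ground truth (region
  classes, differential labels, cluster composition, co-binding fractions,
  motif offsets, target taus) so every stage is scored end to end without
  any external download.

## Worked example

The `analysis/` directory holds numbered drivers that run the whole study
on synthetic data (`Rscript analysis/01_simulate.R`, then `02`…`06`), each
reporting what it found and writing its tables under `results/analysis/`.
Output from a run with the default seed:

```
simulated 1000 genes, 2991 regulatory loci (981 promoters / 2010 enhancers),
  186 EOMES peaks, 500 sequences, 4000 cells -> results/analysis
defined 981 promoters and 2010 enhancers; H3K27ac atlas has 2839 regions
  (enhancer=1913, promoter=926)
lcmv    : 335/1913 regions called differential; sensitivity 0.920, FDP 0.000
listeria: 344/1913 regions called differential; sensitivity 0.945, FDP 0.000
tim     : 167/1913 regions called differential; sensitivity 0.949, FDP 0.000
cluster composition (called):
  more_active C1  110 regions  55.0%
  more_active C2   68 regions  34.0%
  more_active C3   22 regions  11.0%
  less_active C4  119 regions  60.7%
  less_active C5   63 regions  32.1%
  less_active C6   14 regions   7.1%
of 186 EOMES peaks, 69.4% carry RUNX3 in naive and/or memory cells;
  50.0% were already RUNX3-bound in naive cells
KS vs static genes: up D=0.855 p=7.25e-57, down D=0.855 p=7.25e-57;
  200 predicted direct targets
group control : n = 2000 cells, Kendall tau-b = 0.468
group mutant  : n = 2000 cells, Kendall tau-b = 0.189
Fisher-z comparison of the two correlations: z = 15.08, p = 2.1e-51
```

Reading it: annotation recovered every planted promoter and enhancer; the
differential stage found ≥ 92% of planted effects with essentially no
false discoveries; the called gain-side cluster composition reproduced the
planted 55/34/11 split exactly (the loss side drifted a few points — the
conservative Poisson test misses some down-calls; see the methods
vignette); EOMES peaks sat overwhelmingly in the shared and
innate-memory-specific gain clusters; and the two cell groups' rank
correlations (targets 0.5 and 0.2) differed with overwhelming evidence.

The same machinery is available programmatically:

```r
library(epimem)
res <- run_pipeline("out", seed = 1)   # all stages, manifest, stable files
res$concordance$composition
```

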