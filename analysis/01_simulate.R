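#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study (genome annotation, peak landscape,
# count matrices, motif sequences, expression tables, single-cell
# intensities) and write every input the later stages consume.

suppressMessages(library(epimem))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
out <- "results/analysis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = seed)
study <- simulate_study(cfg)

tsv <- function(df, name) {
  write.table(df, file.path(out, name), sep = "\t", quote = FALSE,
              row.names = FALSE)
}

tsv(study$annotation$tss, "tss.tsv")
pk <- study$landscape$peaks
for (mark in c("h3k4me3", "h3k4me1", "h3k27ac")) {
  for (cond in names(pk[[mark]])) {
    write_bed(pk[[mark]][[cond]], file.path(out, paste0(mark, "_", cond, ".bed")))
  }
}
write_bed(pk$eomes_tim, file.path(out, "eomes_tim.bed"))
write_bed(pk$runx3_naive, file.path(out, "runx3_naive.bed"))
write_bed(pk$runx3_tim, file.path(out, "runx3_tim.bed"))
tsv(study$landscape$truth, "truth_loci.tsv")

for (cmp in names(study$count_sets)) {
  cm <- study$count_sets[[cmp]]$counts
  tsv(data.frame(region_id = cm$region_ids, cm$counts,
                 check.names = FALSE),
      paste0("counts_", cmp, ".tsv"))
  tsv(data.frame(sample_id = cm$sample_ids, condition = cm$condition,
                 library_size = cm$library_sizes),
      paste0("samples_", cmp, ".tsv"))
}

Biostrings::writeXStringSet(
  Biostrings::DNAStringSet(study$sequences$sequences),
  file.path(out, "sequences.fa"))
tsv(study$sequences$truth, "truth_sequences.tsv")
tsv(study$expression$expression, "expression.tsv")
tsv(study$expression$truth, "truth_genes.tsv")
tsv(study$cells$cells, "cells.tsv")
tsv(study$cells$truth, "truth_cells.tsv")

message("simulated ", nrow(study$annotation$tss), " genes, ",
        nrow(study$landscape$truth), " regulatory loci (",
        sum(study$landscape$truth$reg_class == "promoter"), " promoters / ",
        sum(study$landscape$truth$reg_class == "enhancer"), " enhancers), ",
        length(pk$eomes_tim), " EOMES peaks, ",
        length(study$sequences$sequences), " sequences, ",
        nrow(study$cells$cells), " cells -> ", out)
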