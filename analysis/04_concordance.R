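#!/usr/bin/env Rscript
# Stage 4: cross-dataset enhancer concordance -- consensus conventional-
# memory status, six-way clustering against the innate-memory calls,
# composition percentages, transcription-factor overlap per cluster, and
# the expression shift of cluster-associated genes.

suppressMessages(library(epimem))
out <- "results/analysis"
truth <- read.table(file.path(out, "truth_loci.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
tss <- read_tss(file.path(out, "tss.tsv"))
diff <- lapply(c("lcmv", "listeria", "tim"), function(cmp) {
  read.table(file.path(out, paste0("diff_", cmp, ".tsv")), header = TRUE,
             sep = "\t", stringsAsFactors = FALSE)
})
names(diff) <- c("lcmv", "listeria", "tim")

ids <- diff$lcmv$region_id
align <- function(df) df[match(ids, df$region_id), ]
li <- align(diff$listeria); ti <- align(diff$tim)

tm <- consensus_tm_status(diff$lcmv$log2fc, diff$lcmv$q, li$log2fc, li$q)
tim <- ifelse(ti$q < 0.05, ifelse(ti$log2fc > 0, "up", "down"), "none")
labels <- suppressWarnings(assign_cluster(tm, tim))
comp <- composition(labels)
write.table(data.frame(locus_id = ids, tm = tm, tim = tim,
                       cluster = labels),
            file.path(out, "clusters.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(comp, file.path(out, "cluster_composition.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("cluster composition (called):")
for (i in seq_len(nrow(comp))) {
  message(sprintf("  %s %-12s %4d regions  %5.1f%%", comp$side[i],
                  comp$cluster[i], comp$count[i], comp$percent[i]))
}

# TF overlap per gained cluster
tr <- truth[match(ids, truth$locus_id), ]
loci_gr <- GenomicRanges::GRanges(tr$chrom,
                                  IRanges::IRanges(tr$start + 1, tr$end))
cl_regions <- Filter(function(g) length(g) > 0,
                     sapply(c("C1", "C2", "C3"),
                            function(cl) loci_gr[labels == cl]))
tf_ov <- cluster_tf_overlap(cl_regions,
                            list(EOMES = read_bed(file.path(out, "eomes_tim.bed")),
                                 RUNX3 = read_bed(file.path(out, "runx3_tim.bed"))))
write.table(tf_ov, file.path(out, "cluster_tf_overlap.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("TF overlap by cluster (%):")
for (i in seq_len(nrow(tf_ov))) {
  message(sprintf("  %s x %s: %.1f", tf_ov$cluster[i], tf_ov$factor[i],
                  tf_ov$percent[i]))
}

# expression shift of cluster-associated genes (nearest TSS association)
expr <- read.table(file.path(out, "expression.tsv"), header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE)
tm_lfc <- with(expr[expr$comparison == "tm", ], setNames(log2fc, gene_id))
tim_lfc <- with(expr[expr$comparison == "tim", ], setNames(log2fc, gene_id))
ng <- nearest_gene(loci_gr, tss)
sets <- split(ng$nearest_gene, labels)
sets <- sets[intersect(c("C1", "C2", "C3", "C4", "C5", "C6"), names(sets))]
sets <- Filter(function(g) length(unique(g)) >= 5, lapply(sets, unique))
if (length(sets) > 0) {
  shift <- cluster_expression_shift(tm_lfc, tim_lfc, sets)
  write.table(shift, file.path(out, "cluster_expression_shift.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message("expression shift (conventional vs innate memory) per cluster:")
  for (i in seq_len(nrow(shift))) {
    message(sprintf("  %s: n=%d, W=%.0f, p=%.3g", shift$cluster[i],
                    shift$n[i], shift$W[i], shift$p[i]))
  }
}
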