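#!/usr/bin/env Rscript
# Stage 2: merge the histone-mark peak sets, define promoters (-5/+2 kb,
# H3K4me3) and enhancers (>= 2 kb from any TSS, H3K4me1, promoter-free),
# build the H3K27ac activity atlas and classify its regions.

suppressMessages(library(epimem))
out <- "results/analysis"
tss <- read_tss(file.path(out, "tss.tsv"))

k4me3 <- merge_intervals(c(read_bed(file.path(out, "h3k4me3_naive.bed")),
                           read_bed(file.path(out, "h3k4me3_tim.bed"))))
k4me1 <- merge_intervals(c(read_bed(file.path(out, "h3k4me1_naive.bed")),
                           read_bed(file.path(out, "h3k4me1_tim.bed"))))
promoters <- define_promoters(k4me3, tss)
enhancers <- define_enhancers(k4me1, tss, promoters)

atlas <- build_atlas(list(naive = read_bed(file.path(out, "h3k27ac_naive.bed")),
                          tim = read_bed(file.path(out, "h3k27ac_tim.bed"))))
classified <- classify_activity_atlas(atlas, promoters, enhancers)
vn <- venn_counts(atlas, "naive", "tim")

write_bed(promoters, file.path(out, "promoters.bed"))
write_bed(enhancers, file.path(out, "enhancers.bed"))
write.table(data.frame(region_id = classified$region_id,
                       reg_class = classified$reg_class),
            file.path(out, "h3k27ac_classes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cls <- table(classified$reg_class)
message("defined ", length(promoters), " promoters and ", length(enhancers),
        " enhancers; H3K27ac atlas has ", length(atlas), " regions (",
        paste(names(cls), cls, sep = "=", collapse = ", "),
        "); condition venn only-naive/shared/only-tim = ",
        paste(vn, collapse = "/"))
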