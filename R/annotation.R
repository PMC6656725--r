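#' Promoter/enhancer annotation from histone-mark geometry
#'
#' Two promoter conventions coexist in the pipeline and are both supported:
#' the strand-aware -5 kb/+2 kb window around the TSS used for histone-mark
#' analyses, and the strand-independent +/-2 kb window used for chromatin
#' accessibility peaks. Constants live in [annotation_config()].
#'
#' @name region-annotation
NULL

#' Annotation configuration
#'
#' @param promoter_upstream Upstream extent of the strand-aware promoter
#'   window (bp, default 5000).
#' @param promoter_downstream Downstream extent (bp, default 2000).
#' @param enhancer_exclusion Minimum distance of an enhancer from any TSS
#'   (bp, default 2000).
#' @param atac_window Half-width of the strand-independent promoter window
#'   used for accessibility peaks (bp, default 2000).
#' @return A list of class `annotation_config`.
#' @export
annotation_config <- function(promoter_upstream = 5000L,
                              promoter_downstream = 2000L,
                              enhancer_exclusion = 2000L,
                              atac_window = 2000L) {
  stopifnot(promoter_upstream > 0, promoter_downstream > 0,
            enhancer_exclusion > 0, atac_window > 0)
  structure(list(promoter_upstream = as.integer(promoter_upstream),
                 promoter_downstream = as.integer(promoter_downstream),
                 enhancer_exclusion = as.integer(enhancer_exclusion),
                 atac_window = as.integer(atac_window)),
            class = "annotation_config")
}

#' Read a TSS table
#'
#' TSV with header columns `gene_id`, `chrom`, `position` (0-based TSS
#' coordinate) and `strand` (`+`/`-`).
#'
#' @param path Path to the TSV file.
#' @return `data.frame` with those columns, validated.
#' @export
read_tss <- function(path) {
  tss <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  validate_tss(tss)
}

validate_tss <- function(tss) {
  needed <- c("gene_id", "chrom", "position", "strand")
  if (!all(needed %in% names(tss))) {
    stop("TSS table must have columns: ", paste(needed, collapse = ", "))
  }
  if (anyDuplicated(tss$gene_id)) stop("TSS table has duplicated gene_id")
  if (any(tss$position < 0)) stop("TSS positions must be >= 0")
  if (!all(tss$strand %in% c("+", "-"))) {
    stop("TSS strand must be '+' or '-'")
  }
  tss
}

#' Strand-aware promoter windows around TSSs
#'
#' For a + strand gene the window is `[position - upstream, position +
#' downstream)` in 0-based coordinates; for a - strand gene the window is
#' mirrored. Windows are clipped at the chromosome start and NOT merged: one
#' window per TSS.
#'
#' @param tss TSS table (see [read_tss()]).
#' @param cfg An [annotation_config()].
#' @return `GRanges` with one window per TSS, metadata column `gene_id`.
#' @export
promoter_windows <- function(tss, cfg = annotation_config()) {
  tss <- validate_tss(tss)
  up <- cfg$promoter_upstream
  down <- cfg$promoter_downstream
  plus <- tss$strand == "+"
  start0 <- ifelse(plus, tss$position - up, tss$position - down)
  end0 <- ifelse(plus, tss$position + down, tss$position + up)
  start0 <- pmax(start0, 0)
  GenomicRanges::GRanges(
    seqnames = tss$chrom,
    ranges = IRanges::IRanges(start = start0 + 1, end = end0),
    strand = tss$strand,
    gene_id = tss$gene_id
  )
}

#' Define promoter regions from H3K4me3 peaks
#'
#' Promoters are H3K4me3-positive regions located between -5 and +2 kb of a
#' TSS, read as >= 1 bp overlap of the merged H3K4me3 region with any
#' strand-aware promoter window.
#'
#' @param h3k4me3 Merged `GRanges` of H3K4me3 regions.
#' @param tss TSS table.
#' @param cfg An [annotation_config()].
#' @return Subset of `h3k4me3` classified as promoters.
#' @export
define_promoters <- function(h3k4me3, tss, cfg = annotation_config()) {
  win <- promoter_windows(tss, cfg)
  h3k4me3[overlaps_any(h3k4me3, win)]
}

#' Define enhancer regions from H3K4me1 peaks
#'
#' Enhancers are H3K4me1-positive regions at least `enhancer_exclusion` bp
#' from every TSS (closest region edge to nearest TSS) that do not overlap
#' any H3K4me3-defined promoter. Regions on chromosomes absent from the TSS
#' table are enhancer-eligible (distance is infinite); a warning notes how
#' many.
#'
#' @param h3k4me1 Merged `GRanges` of H3K4me1 regions.
#' @param tss TSS table.
#' @param promoters `GRanges` from [define_promoters()].
#' @param cfg An [annotation_config()].
#' @return Subset of `h3k4me1` classified as enhancers.
#' @export
define_enhancers <- function(h3k4me1, tss, promoters,
                             cfg = annotation_config()) {
  tss <- validate_tss(tss)
  d <- distance_to_nearest_point(h3k4me1, tss)
  off_chrom <- is.infinite(d)
  if (any(off_chrom)) {
    warning(sum(off_chrom), " region(s) lie on chromosomes absent from the ",
            "TSS table; treated as far from any TSS")
  }
  far <- d >= cfg$enhancer_exclusion
  clean <- !overlaps_any(h3k4me1, promoters)
  h3k4me1[far & clean]
}

#' Classify activity-mark regions against promoter/enhancer atlases
#'
#' Each H3K27ac region is labeled `promoter` if it overlaps a promoter by
#' >= 1 bp (promoter precedence when both classes overlap), else `enhancer`
#' if it overlaps an enhancer, else `unclassified`.
#'
#' @param regions `GRanges` of activity regions (e.g. an H3K27ac atlas).
#' @param promoters,enhancers Class atlases from [define_promoters()] /
#'   [define_enhancers()].
#' @return The input `GRanges` with a `reg_class` metadata column.
#' @export
classify_activity_atlas <- function(regions, promoters, enhancers) {
  in_prom <- overlaps_any(regions, promoters)
  in_enh <- overlaps_any(regions, enhancers)
  regions$reg_class <- ifelse(in_prom, "promoter",
                              ifelse(in_enh, "enhancer", "unclassified"))
  regions
}

#' Classify accessibility peaks as promoter- or enhancer-located
#'
#' Accessibility peaks use the simpler strand-independent rule: a peak is
#' promoter-class if it overlaps `[position - atac_window, position +
#' atac_window)` for any TSS, else enhancer-class.
#'
#' @param peaks `GRanges` of ATAC peaks.
#' @param tss TSS table.
#' @param cfg An [annotation_config()].
#' @return The input `GRanges` with a `reg_class` metadata column
#'   (`promoter`/`enhancer`).
#' @export
classify_atac_peaks <- function(peaks, tss, cfg = annotation_config()) {
  tss <- validate_tss(tss)
  w <- cfg$atac_window
  start0 <- pmax(tss$position - w, 0)
  win <- GenomicRanges::GRanges(
    seqnames = tss$chrom,
    ranges = IRanges::IRanges(start = start0 + 1, end = tss$position + w)
  )
  in_prom <- overlaps_any(peaks, win)
  peaks$reg_class <- ifelse(in_prom, "promoter", "enhancer")
  peaks
}

#' Genomic distribution of binding sites
#'
#' Assigns each peak one category with the precedence promoter > 5'UTR >
#' exon > intron > distal intergenic, and reports the percentage breakdown.
#' The gene model is a table of labeled feature intervals (`feature` in
#' `{5utr, exon, intron}`, `chrom`, `start`, `end`, 0-based half-open);
#' promoter windows come from the TSS table and the strand-aware window.
#'
#' @param peaks `GRanges` of binding sites.
#' @param gene_model `data.frame` with columns `feature`, `chrom`, `start`,
#'   `end`.
#' @param tss TSS table used for the promoter category.
#' @param cfg An [annotation_config()].
#' @return `data.frame` with columns `category`, `count`, `percent`
#'   (percentages sum to 100).
#' @export
genomic_distribution <- function(peaks, gene_model, tss,
                                 cfg = annotation_config()) {
  stopifnot(all(c("feature", "chrom", "start", "end") %in% names(gene_model)))
  feat_gr <- function(fname) {
    gm <- gene_model[gene_model$feature == fname, , drop = FALSE]
    if (nrow(gm) == 0L) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(gm$chrom,
                           IRanges::IRanges(gm$start + 1, gm$end))
  }
  prom <- promoter_windows(tss, cfg)
  cats <- c("promoter", "5utr", "exon", "intron", "distal_intergenic")
  hit <- cbind(
    promoter = overlaps_any(peaks, prom),
    `5utr` = overlaps_any(peaks, feat_gr("5utr")),
    exon = overlaps_any(peaks, feat_gr("exon")),
    intron = overlaps_any(peaks, feat_gr("intron"))
  )
  assigned <- apply(hit, 1L, function(h) {
    i <- which(h)
    if (length(i) == 0L) "distal_intergenic" else colnames(hit)[min(i)]
  })
  counts <- vapply(cats, function(cc) sum(assigned == cc), integer(1))
  data.frame(category = cats,
             count = as.integer(counts),
             percent = 100 * counts / length(peaks),
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Nearest gene and signed distance for each region
#'
#' Associates every region with its closest TSS (by center-to-TSS
#' distance). The signed distance is negative when the region lies upstream
#' of the TSS in the gene's orientation. Ties go to the smaller gene id.
#'
#' @param gr `GRanges` of regions.
#' @param tss TSS table.
#' @return `data.frame` with columns `nearest_gene` and `signed_distance`
#'   (`NA` for regions on chromosomes without a TSS).
#' @export
nearest_gene <- function(gr, tss) {
  tss <- validate_tss(tss)
  centers <- (GenomicRanges::start(gr) - 1 + GenomicRanges::end(gr)) / 2
  chroms <- as.character(GenomicRanges::seqnames(gr))
  # order candidate TSSs so that ties resolve to the smaller gene id
  tss <- tss[order(tss$gene_id), ]
  by_chr <- split(tss, tss$chrom)
  out <- data.frame(nearest_gene = rep(NA_character_, length(gr)),
                    signed_distance = rep(NA_real_, length(gr)),
                    stringsAsFactors = FALSE)
  for (i in seq_along(gr)) {
    cand <- by_chr[[chroms[i]]]
    if (is.null(cand)) next
    d <- centers[i] - (cand$position + 1)  # + strand: negative = upstream
    j <- which.min(abs(d))
    signed <- if (cand$strand[j] == "+") d[j] else -d[j]
    out$nearest_gene[i] <- cand$gene_id[j]
    out$signed_distance[i] <- signed
  }
  out
}
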