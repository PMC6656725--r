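#' Interval algebra for peak atlases
#'
#' All peak arithmetic in the pipeline runs on [GenomicRanges::GRanges]
#' objects with the "at least 1 bp" overlap convention: two regions belong
#' together only if they genuinely share a base, so book-ended regions
#' (gap 0) are never merged. This differs from the default of several merge
#' tools, which fuse adjacent intervals.
#'
#' @name interval-algebra
NULL

# findOverlaps warns when query and subject share no seqlevels; for peak
# arithmetic a disjoint chromosome set simply means "no overlap"
overlaps_any <- function(query, subject, minoverlap = 1L) {
  suppressWarnings(IRanges::overlapsAny(query, subject,
                                        minoverlap = minoverlap,
                                        ignore.strand = TRUE))
}

count_overlaps <- function(query, subject, minoverlap = 1L) {
  suppressWarnings(GenomicRanges::countOverlaps(query, subject,
                                                minoverlap = minoverlap,
                                                ignore.strand = TRUE))
}

sort_intervals <- function(gr) {
  o <- order(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr), GenomicRanges::end(gr))
  gr[o]
}

#' Merge intervals that overlap by at least `min_overlap` bp
#'
#' Computes the transitive closure of the "overlaps by >= min_overlap bp"
#' relation and replaces each equivalence class by its spanning interval.
#' With the default `min_overlap = 1` this is a plain merge of genuinely
#' overlapping regions; book-ended intervals stay separate. Strand, name and
#' score are dropped (a merged region has no single parent).
#'
#' @param gr A `GRanges`.
#' @param min_overlap Minimum shared bases for two intervals to merge (>= 1).
#' @return A sorted, non-overlapping `GRanges`.
#' @export
merge_intervals <- function(gr, min_overlap = 1L) {
  stopifnot(min_overlap >= 1L)
  if (length(gr) == 0L) return(GenomicRanges::GRanges())
  gr <- GenomicRanges::granges(gr)
  GenomicRanges::strand(gr) <- "*"
  if (min_overlap == 1L) {
    # reduce() with min.gapwidth = 0 merges overlapping but not adjacent runs
    out <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
    return(sort_intervals(out))
  }
  # general case: union-find over pairwise hits with the required overlap
  hits <- GenomicRanges::findOverlaps(gr, gr, minoverlap = min_overlap,
                                      ignore.strand = TRUE)
  parent <- seq_along(gr)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  for (k in seq_along(qh)) {
    a <- find(qh[k]); b <- find(sh[k])
    if (a != b) parent[b] <- a
  }
  comp <- vapply(seq_along(gr), find, integer(1))
  spans <- lapply(split(seq_along(gr), comp), function(ix) {
    GenomicRanges::GRanges(
      GenomicRanges::seqnames(gr)[ix[1]],
      IRanges::IRanges(min(GenomicRanges::start(gr)[ix]),
                       max(GenomicRanges::end(gr)[ix])))
  })
  sort_intervals(do.call(c, unname(spans)))
}

#' Build a peak atlas with per-source membership flags
#'
#' Pools all peak sets, merges them with 1 bp overlap semantics into
#' non-overlapping atlas regions, and flags for each region which source
#' contributed at least one overlapping (>= 1 bp) peak.
#'
#' @param sets Named list of `GRanges`, one per sample/mark. Names must be
#'   unique and non-empty.
#' @param min_overlap Overlap threshold used for both merging and membership.
#' @return A `GRanges` whose metadata columns are one logical membership flag
#'   per source label, plus a `region_id` column.
#' @export
build_atlas <- function(sets, min_overlap = 1L) {
  if (length(sets) < 1L) stop("build_atlas() needs at least one input set")
  labels <- names(sets)
  if (is.null(labels) || any(!nzchar(labels))) {
    stop("all input sets must be named")
  }
  if (anyDuplicated(labels)) {
    stop("duplicate source labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  # sources may cover disjoint chromosome sets; the combination is still valid
  pooled <- suppressWarnings(
    do.call(c, lapply(unname(sets), GenomicRanges::granges)))
  GenomicRanges::strand(pooled) <- "*"
  atlas <- merge_intervals(pooled, min_overlap = min_overlap)
  mem <- lapply(sets, function(s) {
    overlaps_any(atlas, s, minoverlap = min_overlap)
  })
  mcols <- S4Vectors::DataFrame(mem, check.names = FALSE)
  names(mcols) <- labels
  S4Vectors::mcols(atlas) <- mcols
  atlas$region_id <- sprintf("region_%06d", seq_along(atlas))
  atlas
}

#' Two-way Venn counts over an atlas
#'
#' Counts atlas regions carried only by source `a`, by both, and only by `b`,
#' mirroring the promoter/enhancer intersection diagrams drawn from merged
#' peak landscapes.
#'
#' @param atlas Output of [build_atlas()].
#' @param a,b Source labels present in the atlas.
#' @return Named integer vector `c(only_a, shared, only_b)`.
#' @export
venn_counts <- function(atlas, a, b) {
  mc <- S4Vectors::mcols(atlas)
  for (lab in c(a, b)) {
    if (!lab %in% names(mc)) stop("unknown atlas label: ", lab)
  }
  ma <- mc[[a]]
  mb <- mc[[b]]
  c(only_a = sum(ma & !mb), shared = sum(ma & mb), only_b = sum(!ma & mb))
}

#' Fraction of query regions overlapping a reference set
#'
#' Used throughout for "percentage of regions that overlap" statements
#' (e.g. enhancer-cluster overlap with transcription-factor peaks). A query
#' region counts as overlapping if it shares >= 1 bp with any reference
#' region.
#'
#' @param query Non-empty `GRanges`.
#' @param reference `GRanges` (may be empty, giving 0).
#' @return Fraction in \[0, 1\].
#' @export
overlap_fraction <- function(query, reference) {
  if (length(query) == 0L) {
    stop("overlap_fraction() is undefined for an empty query set")
  }
  if (length(reference) == 0L) return(0)
  mean(overlaps_any(query, reference))
}

#' Distance from an interval to the nearest point (e.g. a TSS)
#'
#' Distances follow the BED convention of the rest of the package: a point
#' inside the region scores 0; a point beyond the region is measured from the
#' last included base (`end`), so `chr1:[100,200)` vs position 250 (0-based)
#' gives 250 - 199 = 51. Points on other chromosomes are ignored; if no point
#' shares a chromosome the result is `Inf`.
#'
#' @param gr `GRanges` of query intervals.
#' @param points `data.frame` with columns `chrom` and `position` (0-based).
#' @return Numeric vector of distances (bp), one per interval.
#' @export
distance_to_nearest_point <- function(gr, points) {
  stopifnot(is.data.frame(points), all(c("chrom", "position") %in% names(points)))
  chroms <- as.character(GenomicRanges::seqnames(gr))
  # 1-based coordinates of the first/last included base
  s1 <- GenomicRanges::start(gr)
  e1 <- GenomicRanges::end(gr)
  pts <- split(points$position + 1, points$chrom)  # to 1-based
  vapply(seq_along(gr), function(i) {
    p <- pts[[chroms[i]]]
    if (is.null(p) || length(p) == 0L) return(Inf)
    d <- ifelse(p < s1[i], s1[i] - p, ifelse(p > e1[i], p - e1[i], 0))
    min(d)
  }, numeric(1))
}
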