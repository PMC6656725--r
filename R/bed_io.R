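#' Read a BED3/BED6 file into a GRanges
#'
#' Peak files are consumed as plain BED (tab-separated, no header). Coordinates
#' on disk are 0-based half-open; the returned [GenomicRanges::GRanges] uses
#' the usual 1-based closed convention, so a BED line `chr1 0 100` becomes
#' `chr1:1-100`. `track`, `browser` and `#` comment lines are skipped. Strand
#' is taken from column 6 when present, otherwise left unstranded (`*`); name
#' and score (columns 4-5) are preserved as metadata columns.
#'
#' @param path Path to a BED file.
#' @param label Optional source label stored in `metadata(gr)$label` (defaults
#'   to the file name without extension).
#' @return A `GRanges` sorted by (chrom, start, end).
#' @export
read_bed <- function(path, label = NULL) {
  if (!file.exists(path)) {
    stop("BED file does not exist: ", path)
  }
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::metadata(gr)$label <- label %||% sub("\\.[^.]*$", "", basename(path))
    return(gr)
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- idx[which(nf < 3L)[1L]]
    stop("Malformed BED line ", bad, " in ", path, ": fewer than 3 fields")
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(is.na(start0) | is.na(end0) |
                 start0 != floor(start0) | end0 != floor(end0))
  if (length(bad) > 0L) {
    stop("Malformed BED line ", idx[bad[1L]], " in ", path,
         ": non-integer coordinates")
  }
  bad <- which(start0 < 0 | start0 >= end0)
  if (length(bad) > 0L) {
    stop("Malformed BED line ", idx[bad[1L]], " in ", path,
         ": requires 0 <= start < end")
  }
  name <- ifelse(nf >= 4L, vapply(fields, function(f) f[min(4L, length(f))],
                                  character(1)), NA_character_)
  score <- rep(NA_real_, length(fields))
  has5 <- nf >= 5L
  if (any(has5)) {
    score[has5] <- suppressWarnings(as.numeric(
      vapply(fields[has5], `[[`, character(1), 5L)))
  }
  strand <- rep("*", length(fields))
  has6 <- nf >= 6L
  if (any(has6)) {
    s6 <- vapply(fields[has6], `[[`, character(1), 6L)
    s6[!s6 %in% c("+", "-")] <- "*"
    strand[has6] <- s6
  }
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1, end = end0),
    strand = strand,
    name = name,
    score = score
  )
  gr <- sort_intervals(gr)
  S4Vectors::metadata(gr)$label <- label %||% sub("\\.[^.]*$", "", basename(path))
  gr
}

#' Write a GRanges as BED
#'
#' Emits BED3 by default; `name`/`score`/strand columns are appended (BED6)
#' when `bed6 = TRUE`. Coordinates are converted back to 0-based half-open.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @param bed6 Write name, score and strand columns.
#' @export
write_bed <- function(gr, path, bed6 = FALSE) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  if (bed6) {
    nm <- if (!is.null(gr$name)) gr$name else rep(".", length(gr))
    sc <- if (!is.null(gr$score)) gr$score else rep(0, length(gr))
    nm[is.na(nm)] <- "."
    sc[is.na(sc)] <- 0
    df$name <- nm
    df$score <- sc
    df$strand <- as.character(GenomicRanges::strand(gr))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
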