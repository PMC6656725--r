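#' Transcription-factor co-binding and motif positional density
#'
#' Quantifies how often EOMES-bound regions carry RUNX3 peaks (including
#' pre-positioned RUNX3 binding in naive cells, the pioneer-factor
#' signature) and locates the best motif match per region for positional
#' density plots around region centers.
#'
#' @name cobinding
NULL

#' Co-binding fractions of a factor's peaks with a second factor
#'
#' `frac_any` is the fraction of query regions overlapping the union of the
#' two reference peak sets; `frac_naive_prebound` is the fraction overlapping
#' the naive-condition set alone (regions where the second factor was bound
#' before the transition), so `frac_naive_prebound <= frac_any`.
#'
#' @param eomes_regions Non-empty `GRanges` of query (EOMES) regions.
#' @param runx3_naive,runx3_tim `GRanges` of reference (RUNX3) peaks in the
#'   naive and memory conditions.
#' @return Named numeric vector `c(frac_any, frac_naive_prebound)`.
#' @export
cobinding_fractions <- function(eomes_regions, runx3_naive, runx3_tim) {
  if (length(eomes_regions) == 0L) stop("query peak set is empty")
  both <- suppressWarnings(c(GenomicRanges::granges(runx3_naive),
                             GenomicRanges::granges(runx3_tim)))
  frac_any <- if (length(both) == 0L) 0 else
    overlap_fraction(eomes_regions, both)
  frac_naive <- if (length(runx3_naive) == 0L) 0 else
    overlap_fraction(eomes_regions, runx3_naive)
  c(frac_any = frac_any, frac_naive_prebound = frac_naive)
}

#' Read a JASPAR-format position frequency matrix
#'
#' Supports the plain-text JASPAR PFM layout: a `>` header line with the
#' motif id, then four rows in A, C, G, T order, each optionally prefixed by
#' the base letter and wrapped in brackets. Counts are converted to
#' column probabilities.
#'
#' @param path Path to the PFM file.
#' @param background Background base probabilities (default uniform).
#' @param pseudo Pseudo-probability added before renormalization
#'   (default 0.01); JASPAR matrices contain zeros.
#' @return A `pwm` object (see [make_pwm()]).
#' @export
read_jaspar <- function(path, background = rep(0.25, 4), pseudo = 0.01) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  header <- grep("^>", lines)
  if (length(header) != 1L || length(lines) < header + 4L) {
    stop("not a single-motif JASPAR PFM file: ", path)
  }
  motif_id <- strsplit(sub("^>", "", lines[header]), "\\s+")[[1]][1]
  rows <- lines[(header + 1):(header + 4)]
  parse_row <- function(r) {
    r <- gsub("^[ACGTacgt]\\s*", "", r)
    r <- gsub("[][]", " ", r)
    as.numeric(strsplit(trimws(r), "\\s+")[[1]])
  }
  mat <- t(vapply(rows, parse_row, numeric(length(parse_row(rows[1])))))
  if (any(is.na(mat)) || nrow(mat) != 4L) stop("malformed PFM rows in ", path)
  probs <- t(t(mat) / colSums(mat))  # per-position probabilities
  make_pwm(t(probs), motif_id = motif_id, background = background,
           pseudo = pseudo)
}

#' Construct a position weight matrix object
#'
#' @param matrix L x 4 matrix of base probabilities (columns A, C, G, T);
#'   rows must sum to 1 within 1e-6 and L >= 4.
#' @param motif_id Identifier string.
#' @param background Background probabilities (default uniform).
#' @param pseudo Pseudo-probability added to entries before the log-odds
#'   transform (default 0.01).
#' @return List of class `pwm` with the probability matrix and a
#'   `log2`-odds score matrix.
#' @export
make_pwm <- function(matrix, motif_id = "motif", background = rep(0.25, 4),
                     pseudo = 0.01) {
  matrix <- as.matrix(matrix)
  stopifnot(ncol(matrix) == 4L, nrow(matrix) >= 4L,
            all(abs(rowSums(matrix) - 1) < 1e-6),
            length(background) == 4L, all(background > 0), pseudo > 0)
  colnames(matrix) <- c("A", "C", "G", "T")
  padded <- matrix + pseudo
  padded <- padded / rowSums(padded)
  logodds <- log2(sweep(padded, 2L, background, `/`))
  structure(list(motif_id = motif_id, matrix = matrix,
                 background = background, pseudo = pseudo,
                 logodds = logodds, length = nrow(matrix)),
            class = "pwm")
}

#' Consensus sequence of a PWM
#' @param pwm A `pwm` object.
#' @return Character string of per-position argmax bases.
#' @export
pwm_consensus <- function(pwm) {
  paste(c("A", "C", "G", "T")[apply(pwm$matrix, 1L, which.max)],
        collapse = "")
}

seq_to_codes <- function(sequence) {
  codes <- match(strsplit(toupper(sequence), "")[[1]],
                 c("A", "C", "G", "T"))
  codes[is.na(codes)] <- 5L  # N and anything else scores as background
  codes
}

score_all_offsets <- function(codes, logodds) {
  L <- nrow(logodds)
  n_off <- length(codes) - L + 1L
  lo <- cbind(logodds, 0)  # column 5: N contributes 0 log-odds
  win <- matrix(codes[outer(seq_len(n_off), 0:(L - 1L), `+`)], nrow = n_off)
  sc <- matrix(lo[cbind(rep(seq_len(L), each = n_off), as.vector(win))],
               nrow = n_off)
  rowSums(sc)
}

revcomp <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

#' Best motif match in a sequence
#'
#' Scans every offset on both strands (reverse-complement scan) with the
#' log2-odds PWM; `N` bases contribute 0 log-odds. Ties are broken to the
#' smallest offset, preferring the + strand.
#'
#' @param sequence DNA string over ACGTN, at least as long as the motif.
#' @param pwm A [make_pwm()] object.
#' @return List with `offset` (0-based match start on the + strand
#'   coordinates of the input), `strand`, and `score` (bits).
#' @export
pwm_best_hit <- function(sequence, pwm) {
  L <- pwm$length
  len <- nchar(sequence)
  if (len < L) stop("sequence shorter than the motif (", L, " bp)")
  fwd <- score_all_offsets(seq_to_codes(sequence), pwm$logodds)
  rev_scores <- score_all_offsets(seq_to_codes(revcomp(sequence)),
                                  pwm$logodds)
  # a hit at offset j on the reverse-complement corresponds to original
  # offset len - L - j
  rev_by_orig <- rev(rev_scores)
  best_f <- max(fwd)
  best_r <- max(rev_by_orig)
  if (best_f >= best_r) {
    list(offset = which.max(fwd) - 1L, strand = "+", score = best_f)
  } else {
    list(offset = which.max(rev_by_orig) - 1L, strand = "-", score = best_r)
  }
}

#' Positional density of best motif hits around sequence centers
#'
#' For each sequence the single best hit is located and the center of the
#' matched L-mer, relative to the sequence center, is histogrammed. Hits
#' whose centers fall outside +/- `window` are discarded, so the counts sum
#' to the number of sequences with an in-window best hit.
#'
#' @param sequences Character vector of DNA sequences (typically region
#'   centers +/- `window`).
#' @param pwm A [make_pwm()] object.
#' @param window Half-width in bp (default 250).
#' @param bin_width Histogram bin width in bp (default 10).
#' @param score_min Optional minimum best-hit score; lower-scoring sequences
#'   are dropped (default `-Inf`: the best site is always kept).
#' @return `data.frame` with columns `bin_start`, `bin_end`, `count`, plus
#'   attribute `n_scored`.
#' @export
positional_density <- function(sequences, pwm, window = 250L,
                               bin_width = 10L, score_min = -Inf) {
  hits <- lapply(sequences, pwm_best_hit, pwm = pwm)
  L <- pwm$length
  centers <- vapply(seq_along(hits), function(i) {
    hits[[i]]$offset + (L - 1) / 2 - (nchar(sequences[i]) - 1) / 2
  }, numeric(1))
  scores <- vapply(hits, `[[`, numeric(1), "score")
  keep <- scores >= score_min & abs(centers) <= window
  edges <- seq(-window, window, by = bin_width)
  if (edges[length(edges)] < window) edges <- c(edges, window)
  h <- hist(centers[keep], breaks = edges, plot = FALSE)
  out <- data.frame(bin_start = edges[-length(edges)],
                    bin_end = edges[-1],
                    count = h$counts)
  attr(out, "n_scored") <- sum(keep)
  out
}
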