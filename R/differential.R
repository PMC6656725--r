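#' Differential chromatin activity by exact Poisson testing
#'
#' The differential test mirrors the custom scheme used for histone-mark and
#' accessibility atlases: replicate counts are pooled per condition, both
#' pooled libraries are scaled down to the lowest total library size, each
#' region gets a log2 fold-change and a two-sided exact Poisson p-value, an
#' optional conditional-binomial "proportion of library" filter is applied,
#' and p-values are FDR-adjusted (Benjamini-Hochberg).
#'
#' @name differential-activity
NULL

#' Differential-test configuration
#'
#' @param pseudocount Pseudocount added to both normalized counts in the
#'   log2 fold-change (default 1).
#' @param fdr_alpha FDR threshold for calling a region differential
#'   (default 0.05; 0.001 is used for the transgenic accessibility
#'   comparison).
#' @param lfc_threshold Absolute log2 fold-change a call must exceed
#'   (default 0 for chromatin; 1 for expression tables).
#' @param use_proportion_filter Also require the conditional-binomial
#'   library-proportion test to pass (default `FALSE`; used for ATAC).
#' @param alternative `"two.sided"` (default) or `"one.sided"` Poisson test.
#' @return A list of class `diff_config`.
#' @export
diff_config <- function(pseudocount = 1, fdr_alpha = 0.05,
                        lfc_threshold = 0, use_proportion_filter = FALSE,
                        alternative = c("two.sided", "one.sided")) {
  stopifnot(pseudocount > 0, fdr_alpha > 0, fdr_alpha < 1, lfc_threshold >= 0)
  alternative <- match.arg(alternative)
  structure(list(pseudocount = pseudocount, fdr_alpha = fdr_alpha,
                 lfc_threshold = lfc_threshold,
                 use_proportion_filter = use_proportion_filter,
                 alternative = alternative),
            class = "diff_config")
}

#' Assemble a count matrix object
#'
#' @param counts Integer matrix, regions x samples.
#' @param region_ids Character vector of region identifiers.
#' @param sample_ids Character vector of sample identifiers.
#' @param condition Character vector mapping each sample to its condition.
#' @param library_sizes Positive totals per sample; defaults to column sums.
#' @return A list of class `count_matrix`.
#' @export
count_matrix <- function(counts, region_ids = rownames(counts),
                         sample_ids = colnames(counts),
                         condition, library_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(region_ids)) region_ids <- sprintf("region_%06d", seq_len(nrow(counts)))
  if (is.null(sample_ids)) sample_ids <- sprintf("sample_%d", seq_len(ncol(counts)))
  stopifnot(length(region_ids) == nrow(counts),
            length(sample_ids) == ncol(counts),
            length(condition) == ncol(counts),
            all(counts >= 0))
  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  stopifnot(length(library_sizes) == ncol(counts), all(library_sizes > 0))
  dimnames(counts) <- list(region_ids, sample_ids)
  structure(list(counts = counts, region_ids = region_ids,
                 sample_ids = sample_ids, condition = as.character(condition),
                 library_sizes = as.numeric(library_sizes)),
            class = "count_matrix")
}

#' Count fragments over atlas regions
#'
#' Each fragment contributes 1 to every atlas region it overlaps by >= 1 bp
#' (because atlas regions are disjoint, a fragment spanning a gap can hit at
#' most the two flanking regions). Library size defaults to the sample's
#' total fragment count.
#'
#' @param atlas Non-overlapping `GRanges` (see [build_atlas()]).
#' @param fragments Named list of `GRanges`, one per sample.
#' @param condition Condition label per sample (same order as `fragments`).
#' @param library_sizes Optional true library totals per sample.
#' @return A [count_matrix()].
#' @export
count_fragments <- function(atlas, fragments, condition,
                            library_sizes = NULL) {
  stopifnot(length(fragments) >= 1L, length(condition) == length(fragments))
  counts <- vapply(fragments, function(fr) {
    count_overlaps(atlas, fr)
  }, integer(length(atlas)))
  counts <- matrix(counts, nrow = length(atlas))
  if (is.null(library_sizes)) library_sizes <- lengths(fragments)
  rid <- if (!is.null(atlas$region_id)) atlas$region_id else
    sprintf("region_%06d", seq_along(atlas))
  count_matrix(counts, region_ids = rid,
               sample_ids = names(fragments) %||%
                 sprintf("sample_%d", seq_along(fragments)),
               condition = condition, library_sizes = library_sizes)
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Normalize counts to the lowest total library size
#'
#' Each count k from a sample with library size N becomes
#' `round(k * Nmin / N)` with ties rounded half away from zero; samples
#' already at the minimum are unchanged.
#'
#' @param counts Matrix (regions x samples) or vector of counts.
#' @param library_sizes Positive library totals, one per column.
#' @return Normalized integer counts with the input shape.
#' @export
normalize_to_lowest <- function(counts, library_sizes) {
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  nmin <- min(library_sizes)
  scale <- nmin / library_sizes
  if (is.matrix(counts)) {
    stopifnot(ncol(counts) == length(library_sizes))
    out <- round_half_away(sweep(counts, 2L, scale, `*`))
  } else {
    stopifnot(length(counts) == length(library_sizes))
    out <- round_half_away(counts * scale)
  }
  storage.mode(out) <- "integer"
  out
}

#' Two-sided exact Poisson p-value for a pair of normalized counts
#'
#' Under the null both conditions share the rate `lambda = (n_a + n_b) / 2`;
#' the p-value is `min(1, 2 * min(Pr[X <= min], Pr[X >= max]))` for
#' X ~ Poisson(lambda). Symmetric in its arguments; (0, 0) returns 1.
#' Vectorized over pairs.
#'
#' @param n_a,n_b Non-negative normalized counts.
#' @param alternative `"two.sided"` (default) doubles the smaller tail;
#'   `"one.sided"` returns the smaller tail itself.
#' @return p-values in (0, 1\].
#' @export
poisson_two_sided_p <- function(n_a, n_b, alternative = "two.sided") {
  if (any(n_a < 0) || any(n_b < 0)) stop("counts must be non-negative")
  lambda <- (n_a + n_b) / 2
  lo <- pmin(n_a, n_b)
  hi <- pmax(n_a, n_b)
  lower <- stats::ppois(lo, lambda)
  upper <- stats::ppois(hi - 1, lambda, lower.tail = FALSE)
  tail <- pmin(lower, upper)
  p <- if (alternative == "two.sided") pmin(1, 2 * tail) else pmin(1, tail)
  p[lambda == 0] <- 1
  p
}

#' Conditional-binomial library-proportion p-value
#'
#' The statistical content of the library-proportion filter: conditional on
#' the total `k_a + k_b`, the raw count `k_a` is Binomial(k_a + k_b,
#' N_a / (N_a + N_b)) under the null of equal per-library proportions. The
#' p-value doubles the smaller exact tail and is capped at 1; (0, 0)
#' returns 1. Vectorized.
#'
#' @param k_a,k_b Raw (un-normalized) counts.
#' @param N_a,N_b Library sizes.
#' @return p-values in (0, 1\].
#' @export
proportion_filter_p <- function(k_a, k_b, N_a, N_b) {
  if (any(N_a <= 0) || any(N_b <= 0)) stop("library sizes must be positive")
  if (any(k_a < 0) || any(k_b < 0)) stop("counts must be non-negative")
  n <- k_a + k_b
  pr <- N_a / (N_a + N_b)
  lower <- stats::pbinom(k_a, n, pr)
  upper <- stats::pbinom(k_a - 1, n, pr, lower.tail = FALSE)
  p <- pmin(1, 2 * pmin(lower, upper))
  p[n == 0] <- 1
  p
}

#' Log2 fold-change with pseudocount
#'
#' @param n_a,n_b Normalized counts.
#' @param pseudocount Positive constant added to both (default 1), keeping
#'   (0, 0) at 0.
#' @return `log2((n_a + c) / (n_b + c))`.
#' @export
log2_fold_change <- function(n_a, n_b, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  log2((n_a + pseudocount) / (n_b + pseudocount))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param p p-values in \[0, 1\].
#' @return q-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differential regions between two conditions
#'
#' Replicate counts are pooled (summed) per condition, library sizes are
#' summed likewise, both pooled columns are normalized to the lowest pooled
#' library, and each region receives a log2 fold-change (A over B, in the
#' order conditions first appear), a Poisson p-value, optionally a
#' library-proportion p-value on the raw pooled counts, and BH q-values.
#' A region is called `up`/`down` when every applied q-value is below
#' `fdr_alpha` and |log2FC| exceeds `lfc_threshold`.
#'
#' @param m A [count_matrix()] with exactly two conditions.
#' @param cfg A [diff_config()].
#' @return `data.frame` with columns `region_id`, `n_a`, `n_b`, `log2fc`,
#'   `p_poisson`, `p_proportion`, `q`, `q_proportion`, `direction`.
#' @export
call_differential <- function(m, cfg = diff_config()) {
  stopifnot(inherits(m, "count_matrix"))
  conds <- unique(m$condition)
  if (length(conds) != 2L) {
    stop("call_differential() compares exactly two conditions; got ",
         length(conds), ". Run pairwise comparisons for multi-way designs.")
  }
  a_cols <- m$condition == conds[1]
  b_cols <- m$condition == conds[2]
  raw_a <- rowSums(m$counts[, a_cols, drop = FALSE])
  raw_b <- rowSums(m$counts[, b_cols, drop = FALSE])
  lib_a <- sum(m$library_sizes[a_cols])
  lib_b <- sum(m$library_sizes[b_cols])
  norm <- normalize_to_lowest(cbind(raw_a, raw_b), c(lib_a, lib_b))
  n_a <- norm[, 1]
  n_b <- norm[, 2]
  lfc <- log2_fold_change(n_a, n_b, cfg$pseudocount)
  p_pois <- poisson_two_sided_p(n_a, n_b, alternative = cfg$alternative)
  q <- bh_adjust(p_pois)
  if (cfg$use_proportion_filter) {
    p_prop <- proportion_filter_p(raw_a, raw_b, lib_a, lib_b)
    q_prop <- bh_adjust(p_prop)
  } else {
    p_prop <- rep(NA_real_, length(p_pois))
    q_prop <- rep(NA_real_, length(p_pois))
  }
  sig <- q < cfg$fdr_alpha & abs(lfc) > cfg$lfc_threshold
  if (cfg$use_proportion_filter) sig <- sig & q_prop < cfg$fdr_alpha
  direction <- ifelse(sig & lfc > 0, "up", ifelse(sig & lfc < 0, "down", "ns"))
  data.frame(region_id = m$region_ids,
             n_a = n_a, n_b = n_b, log2fc = lfc,
             p_poisson = p_pois, p_proportion = p_prop,
             q = q, q_proportion = q_prop,
             direction = direction,
             row.names = NULL, stringsAsFactors = FALSE)
}
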