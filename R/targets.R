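#' Regulatory-potential target inference
#'
#' Re-implementation of the documented core of the BETA target-prediction
#' approach: each gene accumulates exponentially decaying contributions from
#' binding-region centers within a window of its TSS, and the score
#' distributions of up-, down-regulated and static genes are compared with
#' two-sample Kolmogorov-Smirnov tests to call an activating or repressive
#' function. Any divergence from the external package's internals is an
#' approximation of this package (see README).
#'
#' @name target-inference
NULL

#' Regulatory potential of genes given binding regions
#'
#' For each TSS, `S = sum over peaks with |center - tss| <= window of
#' exp(-(0.5 + 4 * Delta))` with `Delta = |center - tss| / window`. Peak
#' position is the interval midpoint. A TSS-centered peak contributes
#' `exp(-0.5)`; a peak at the window edge contributes `exp(-4.5)`.
#'
#' @param tss TSS table (see [read_tss()]).
#' @param peaks `GRanges` of binding regions.
#' @param window Half-width of the scoring window in bp (default 1e5).
#' @return `data.frame` with columns `gene_id`, `score`,
#'   `n_peaks_in_window`.
#' @export
regulatory_potential <- function(tss, peaks, window = 1e5) {
  stopifnot(window > 0)
  tss <- validate_tss(tss)
  # peak centers in 0-based coordinates: midpoint of [start0, end0)
  centers <- (GenomicRanges::start(peaks) - 1 + GenomicRanges::end(peaks)) / 2
  pk <- split(centers, as.character(GenomicRanges::seqnames(peaks)))
  score <- numeric(nrow(tss))
  npk <- integer(nrow(tss))
  for (i in seq_len(nrow(tss))) {
    cc <- pk[[tss$chrom[i]]]
    if (is.null(cc)) next
    delta <- abs(cc - tss$position[i]) / window
    inw <- delta <= 1
    npk[i] <- sum(inw)
    score[i] <- sum(exp(-(0.5 + 4 * delta[inw])))
  }
  data.frame(gene_id = tss$gene_id, score = score,
             n_peaks_in_window = npk, stringsAsFactors = FALSE)
}

#' Two-sample Kolmogorov-Smirnov statistic and p-value
#'
#' `D` is the supremum over the pooled sample points of the absolute
#' difference of the two empirical CDFs. The default p-value comes from the
#' asymptotic Kolmogorov distribution evaluated at
#' `sqrt(n_x * n_y / (n_x + n_y)) * D`; with `exact = TRUE` (n_x + n_y
#' small, no ties) the exact p from [stats::ks.test()] is used instead.
#'
#' @param x,y Non-empty numeric vectors.
#' @param exact Use the exact small-sample null distribution (default
#'   `FALSE`).
#' @return List with `D` and `p.value`.
#' @export
ks_statistic <- function(x, y, exact = FALSE) {
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  pooled <- sort(unique(c(x, y)))
  Fx <- vapply(pooled, function(t) mean(x <= t), numeric(1))
  Fy <- vapply(pooled, function(t) mean(y <= t), numeric(1))
  D <- max(abs(Fx - Fy))
  if (exact) {
    p <- suppressWarnings(stats::ks.test(x, y, exact = TRUE)$p.value)
  } else {
    neff <- length(x) * length(y) / (length(x) + length(y))
    p <- kolmogorov_sf(sqrt(neff) * D)
  }
  list(D = D, p.value = p)
}

# survival function of the Kolmogorov distribution:
# Q(t) = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 t^2)
kolmogorov_sf <- function(t) {
  if (t <= 0) return(1)
  k <- seq_len(100)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  min(1, max(p, 0))
}

#' Activating/repressive inference from regulatory-potential scores
#'
#' Genes are ranked by descending regulatory potential; cumulative-fraction
#' curves over the rank axis are computed per expression group, and the
#' score distributions of the up- and down-regulated groups are each
#' compared with the static background by a KS test. The reported direction
#' is the sign of the static-minus-group mean-rank shift (positive when the
#' group sits at better ranks, i.e. higher scores, than static genes).
#'
#' @param scores Output of [regulatory_potential()].
#' @param up_genes,down_genes,static_genes Disjoint character vectors of
#'   gene ids, each with at least `min_n` entries present in `scores`.
#' @param min_n Minimum group size (default 10).
#' @param exact Passed to [ks_statistic()].
#' @return List with `ks` (`data.frame`: group, D, p, direction) and
#'   `curves` (`data.frame`: gene_id, group, rank, cum_fraction).
#' @export
activating_repressive <- function(scores, up_genes, down_genes, static_genes,
                                  min_n = 10L, exact = FALSE) {
  groups <- list(up = up_genes, down = down_genes, static = static_genes)
  for (i in 1:2) {
    for (j in (i + 1):3) {
      if (length(intersect(groups[[i]], groups[[j]])) > 0L) {
        stop("gene groups must be disjoint (",
             names(groups)[i], " vs ", names(groups)[j], ")")
      }
    }
  }
  sc <- stats::setNames(scores$score, scores$gene_id)
  get <- function(g) {
    g <- intersect(g, names(sc))
    if (length(g) < min_n) stop("group has fewer than ", min_n, " scored genes")
    sc[g]
  }
  xs <- lapply(groups, get)
  # rank axis: all scored genes, best score = rank 1; ties by gene id
  ord <- order(-scores$score, scores$gene_id)
  ranked <- scores$gene_id[ord]
  rank_of <- stats::setNames(seq_along(ranked), ranked)
  curves <- do.call(rbind, lapply(names(xs), function(g) {
    rk <- sort(rank_of[names(xs[[g]])])
    data.frame(gene_id = names(rk), group = g, rank = as.integer(rk),
               cum_fraction = seq_along(rk) / length(rk),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  one <- function(g) {
    ks <- ks_statistic(xs[[g]], xs$static, exact = exact)
    shift <- mean(rank_of[names(xs$static)]) - mean(rank_of[names(xs[[g]])])
    data.frame(group = g, D = ks$D, p = ks$p.value,
               direction = sign(shift), stringsAsFactors = FALSE)
  }
  list(ks = rbind(one("up"), one("down")), curves = curves)
}

#' Predicted direct target genes
#'
#' Differentially expressed genes whose regulatory-potential score exceeds
#' the given quantile of the static-gene score distribution. The external
#' package's internal cutoff is not documented; this explicit quantile rule
#' is deterministic given its inputs.
#'
#' @param scores Output of [regulatory_potential()].
#' @param up_genes,down_genes Differentially expressed gene ids.
#' @param static_genes Background gene ids.
#' @param score_quantile Quantile of the static score distribution a target
#'   must exceed (default 0.5).
#' @return Character vector of predicted target gene ids (sorted).
#' @export
predicted_targets <- function(scores, up_genes, down_genes, static_genes,
                              score_quantile = 0.5) {
  sc <- stats::setNames(scores$score, scores$gene_id)
  cutoff <- stats::quantile(sc[intersect(static_genes, names(sc))],
                            probs = score_quantile, names = FALSE)
  de <- intersect(union(up_genes, down_genes), names(sc))
  sort(de[sc[de] > cutoff])
}
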