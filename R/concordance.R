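#' Cross-dataset enhancer concordance
#'
#' Combines differential calls for enhancer activity from two conventional
#' memory models (an LCMV infection model and a Listeria infection model)
#' with the innate-memory comparison, classifies each enhancer into one of
#' six concordance clusters, and summarises composition and associated gene
#' expression shifts.
#'
#' Cluster semantics: C1 = more active in conventional memory only,
#' C2 = more active in both, C3 = more active in innate memory only;
#' C4-C6 mirror these for regions losing activity.
#'
#' @name concordance
NULL

#' Consensus memory status across the two conventional-memory datasets
#'
#' A region is consensus `up`/`down` when at least one dataset is
#' significant (q < alpha) in that direction and the other dataset is not
#' significant in the opposite direction; everything else (including
#' significant contradictions) is `none`. A strict variant requires both
#' datasets significant with the same sign. Vectorized.
#'
#' @param lcmv_lfc,lcmv_q,listeria_lfc,listeria_q Per-region log2
#'   fold-changes and q-values from the two datasets.
#' @param alpha Significance threshold on q (default 0.05).
#' @param rule `"any"` (default) or `"both"`.
#' @return Character vector in `{up, down, none}`.
#' @export
consensus_tm_status <- function(lcmv_lfc, lcmv_q, listeria_lfc, listeria_q,
                                alpha = 0.05, rule = c("any", "both")) {
  rule <- match.arg(rule)
  s1 <- ifelse(lcmv_q < alpha, ifelse(lcmv_lfc > 0, "up", "down"), "none")
  s2 <- ifelse(listeria_q < alpha, ifelse(listeria_lfc > 0, "up", "down"),
               "none")
  if (rule == "both") {
    unname(ifelse(s1 == s2 & s1 != "none", s1, "none"))
  } else {
    out <- rep("none", length(s1))
    out[(s1 == "up" & s2 != "down") | (s2 == "up" & s1 != "down")] <- "up"
    out[(s1 == "down" & s2 != "up") | (s2 == "down" & s1 != "up")] <- "down"
    unname(out)
  }
}

#' Assign six-way concordance clusters
#'
#' Maps the (conventional-memory status, innate-memory status) pair onto the
#' cluster table: (up, none) -> C1, (up, up) -> C2, (none, up) -> C3,
#' (down, none) -> C4, (down, down) -> C5, (none, down) -> C6, and
#' (none, none) -> none. Contradictory pairs -- (up, down) or (down, up) --
#' are dropped to `none` with a warning; the concordance heatmap has no such
#' category. Vectorized.
#'
#' @param tm,tim Status vectors in `{up, down, none}`.
#' @return Character vector in `{C1..C6, none}`.
#' @export
assign_cluster <- function(tm, tim) {
  stopifnot(length(tm) == length(tim),
            all(tm %in% c("up", "down", "none")),
            all(tim %in% c("up", "down", "none")))
  key <- paste(tm, tim, sep = ".")
  map <- c(up.none = "C1", up.up = "C2", none.up = "C3",
           down.none = "C4", down.down = "C5", none.down = "C6",
           none.none = "none", up.down = "none", down.up = "none")
  n_conflict <- sum(key %in% c("up.down", "down.up"))
  if (n_conflict > 0L) {
    warning(n_conflict, " region(s) with contradictory memory/innate-memory ",
            "signs dropped to 'none'")
  }
  unname(map[key])
}

#' Composition of the concordance clusters
#'
#' Counts and percentages over C1-C3 (more-active side) and C4-C6
#' (less-active side); `none` regions are excluded. Percentages per side sum
#' to 100.
#'
#' @param labels Cluster labels from [assign_cluster()].
#' @return `data.frame` with columns `side`, `cluster`, `count`, `percent`.
#' @export
composition <- function(labels) {
  more <- labels[labels %in% c("C1", "C2", "C3")]
  less <- labels[labels %in% c("C4", "C5", "C6")]
  if (length(more) == 0L && length(less) == 0L) {
    stop("no labeled regions on either side")
  }
  one_side <- function(lab, side, clusters) {
    counts <- vapply(clusters, function(cl) sum(lab == cl), integer(1))
    data.frame(side = side, cluster = clusters, count = as.integer(counts),
               percent = if (length(lab) > 0) 100 * counts / length(lab)
                         else rep(NA_real_, 3L),
               stringsAsFactors = FALSE)
  }
  rbind(one_side(more, "more_active", c("C1", "C2", "C3")),
        one_side(less, "less_active", c("C4", "C5", "C6")))
}

#' Median-of-replicates log2 fold-change for one region
#'
#' Heatmap variant of the fold-change: every replicate is normalized to the
#' lowest library, the per-condition medians of the normalized counts are
#' taken, and the log2 ratio (with pseudocount) of the medians is returned.
#' Robust to a single outlying replicate.
#'
#' @param counts_a,counts_b Raw replicate counts for the region.
#' @param lib_a,lib_b Library sizes matching the replicates.
#' @param pseudocount Pseudocount (default 1).
#' @return A single log2 ratio.
#' @export
median_replicate_lfc <- function(counts_a, counts_b, lib_a, lib_b,
                                 pseudocount = 1) {
  stopifnot(length(counts_a) == length(lib_a),
            length(counts_b) == length(lib_b),
            length(counts_a) >= 1, length(counts_b) >= 1)
  libs <- c(lib_a, lib_b)
  norm <- normalize_to_lowest(c(counts_a, counts_b), libs)
  na <- norm[seq_along(counts_a)]
  nb <- norm[length(counts_a) + seq_along(counts_b)]
  log2_fold_change(stats::median(na), stats::median(nb), pseudocount)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test of paired observations. Zero differences are
#' dropped (Wilcoxon's original treatment). For n <= `exact_max` pairs the
#' exact null distribution is computed by convolution over the observed
#' (possibly tied, midranked) ranks, so the exact p-value remains valid
#' under ties; above that a normal approximation with continuity and tie
#' correction is used. The two-sided p doubles the smaller tail
#' (capped at 1).
#'
#' @param x,y Paired numeric vectors (same genes/items, same length, n >= 5).
#' @param exact_max Largest n for the exact path (default 25).
#' @return List with `statistic` (W = sum of positive ranks), `n` (pairs
#'   after dropping zeros), `p.value` and `method`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 25L) {
  stopifnot(length(x) == length(y))
  if (length(x) < 5L) stop("signed-rank test needs at least 5 pairs")
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0L) {
    return(list(statistic = 0, n = 0L, p.value = 1, method = "degenerate"))
  }
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    # exact distribution of W over all 2^n sign assignments, via convolution
    # on doubled ranks (midranks can be half-integers)
    r2 <- round(2 * r)
    total <- sum(r2)
    f <- numeric(total + 1)  # f[s + 1] = #assignments with doubled-W = s
    f[1] <- 1
    for (rk in r2) {
      g <- f
      g[(rk + 1):(total + 1)] <- g[(rk + 1):(total + 1)] + f[1:(total + 1 - rk)]
      f <- g
    }
    f <- f / 2^n
    w2 <- round(2 * W)
    lower <- sum(f[1:(w2 + 1)])
    upper <- sum(f[(w2 + 1):(total + 1)])
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = W, n = n, p.value = p, method = method)
}

#' Expression shift of cluster-associated genes
#'
#' For each concordance cluster, compares the paired expression log2
#' fold-changes of its associated genes between the conventional-memory and
#' innate-memory comparisons with a two-sided Wilcoxon signed-rank test.
#'
#' @param tm_gene_lfc,tim_gene_lfc Named numeric vectors of per-gene log2
#'   fold-changes (names are gene ids) for the two comparisons.
#' @param cluster_gene_sets Named list mapping cluster label to a character
#'   vector of gene ids.
#' @param min_n Minimum genes per cluster (default 5).
#' @return `data.frame` with columns `cluster`, `n`, `W`, `p`,
#'   `median_shift` (median of tm - tim).
#' @export
cluster_expression_shift <- function(tm_gene_lfc, tim_gene_lfc,
                                     cluster_gene_sets, min_n = 5L) {
  res <- lapply(names(cluster_gene_sets), function(cl) {
    genes <- intersect(cluster_gene_sets[[cl]],
                       intersect(names(tm_gene_lfc), names(tim_gene_lfc)))
    if (length(genes) < min_n) {
      stop("cluster ", cl, " has fewer than ", min_n, " paired genes")
    }
    x <- tm_gene_lfc[genes]
    y <- tim_gene_lfc[genes]
    w <- wilcoxon_signed_rank(x, y)
    data.frame(cluster = cl, n = length(genes), W = w$statistic,
               p = w$p.value, median_shift = stats::median(x - y),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Transcription-factor overlap per concordance cluster
#'
#' Percentage of regions in each cluster that overlap (>= 1 bp) the ChIP-seq
#' peaks of each factor.
#'
#' @param cluster_regions Named list of `GRanges`, one per cluster.
#' @param tf_peaks Named list of `GRanges`, one per factor.
#' @return `data.frame` with columns `cluster`, `factor`, `percent`.
#' @export
cluster_tf_overlap <- function(cluster_regions, tf_peaks) {
  stopifnot(length(cluster_regions) >= 1L)
  if (any(vapply(cluster_regions, length, integer(1)) == 0L)) {
    stop("clusters must be non-empty")
  }
  grid <- expand.grid(cluster = names(cluster_regions),
                      factor = names(tf_peaks),
                      stringsAsFactors = FALSE)
  grid$percent <- mapply(function(cl, tf) {
    100 * overlap_fraction(cluster_regions[[cl]], tf_peaks[[tf]])
  }, grid$cluster, grid$factor)
  grid
}
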