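# Brute-force reference implementations used as independent oracles.
# Deliberately naive (O(n^2) or direct summation) and kept separate from the
# package's own code paths.

make_gr <- function(chrom, start0, end0, strand = "*") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0),
                         strand = strand)
}

gr_to_df0 <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

random_intervals <- function(n, n_chrom = 2, max_pos = 1000, max_len = 60) {
  chrom <- paste0("chr", sample(n_chrom, n, replace = TRUE))
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  make_gr(chrom, start, start + len)
}

# 0-based half-open overlap in bp
overlap_bp <- function(s1, e1, s2, e2) max(0, min(e1, e2) - max(s1, s2))

# transitive-closure merge via all-pairs union-find
oracle_merge <- function(gr, min_overlap = 1) {
  df <- gr_to_df0(gr)
  n <- nrow(df)
  if (n == 0) return(df)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (df$chrom[i] == df$chrom[j] &&
          overlap_bp(df$start[i], df$end[i], df$start[j], df$end[j]) >=
            min_overlap) {
        parent[find(j)] <- find(i)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  out <- do.call(rbind, lapply(split(seq_len(n), comp), function(ix) {
    data.frame(chrom = df$chrom[ix[1]], start = min(df$start[ix]),
               end = max(df$end[ix]), stringsAsFactors = FALSE)
  }))
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}

# per-region membership by all-pairs scan
oracle_membership <- function(atlas, set) {
  a <- gr_to_df0(atlas)
  s <- gr_to_df0(set)
  vapply(seq_len(nrow(a)), function(i) {
    any(s$chrom == a$chrom[i] &
          pmin(s$end, a$end[i]) - pmax(s$start, a$start[i]) >= 1)
  }, logical(1))
}

# direct-summation Poisson tail p-value (upper tail summed to convergence)
oracle_poisson_p <- function(n_a, n_b) {
  if (n_a + n_b == 0) return(1)
  lambda <- (n_a + n_b) / 2
  pmf <- function(k) exp(-lambda + k * log(lambda) - lgamma(k + 1))
  lower <- sum(pmf(0:min(n_a, n_b)))
  hi <- max(n_a, n_b)
  ks <- hi:(hi + 2000)
  upper <- sum(pmf(ks))
  min(1, 2 * min(lower, upper))
}

# direct-summation conditional binomial p-value
oracle_binom_p <- function(k_a, k_b, N_a, N_b) {
  n <- k_a + k_b
  if (n == 0) return(1)
  pr <- N_a / (N_a + N_b)
  pmf <- vapply(0:n, function(k) {
    exp(lchoose(n, k) + k * log(pr) + (n - k) * log(1 - pr))
  }, numeric(1))
  lower <- sum(pmf[1:(k_a + 1)])
  upper <- sum(pmf[(k_a + 1):(n + 1)])
  min(1, 2 * min(lower, upper))
}

# closed-form BH step-up
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * n / seq_len(n))))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

# O(n^2) tau-b via explicit pair enumeration
oracle_kendall <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
    }
  }
  n0 <- n * (n - 1) / 2
  tie_term <- function(v) {
    t <- table(v)
    sum(t * (t - 1) / 2)
  }
  (C - D) / sqrt((n0 - tie_term(x)) * (n0 - tie_term(y)))
}

# sup over all pooled evaluation points of |F_x - F_y|
oracle_ks_D <- function(x, y) {
  pts <- c(x, y)
  max(vapply(pts, function(t) abs(mean(x <= t) - mean(y <= t)), numeric(1)))
}

# exact signed-rank two-sided p by full 2^n sign enumeration
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  W_all <- apply(signs, 1, function(s) sum(r[s]))
  lower <- mean(W_all <= W_obs)
  upper <- mean(W_all >= W_obs)
  min(1, 2 * min(lower, upper))
}
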