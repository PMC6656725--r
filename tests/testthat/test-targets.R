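test_that("regulatory potential follows the exponential decay closed form", {
  tss <- data.frame(gene_id = "g1", chrom = "chr1", position = 500000,
                    strand = "+", stringsAsFactors = FALSE)
  # no peaks in the window
  rp <- regulatory_potential(tss, make_gr("chr1", 1e6, 1e6 + 200))
  expect_equal(rp$score, 0)
  expect_equal(rp$n_peaks_in_window, 0L)
  # peak centered exactly on the TSS: exp(-0.5)
  rp <- regulatory_potential(tss, make_gr("chr1", 499900, 500100))
  expect_equal(rp$score, exp(-0.5), tolerance = 1e-12)
  # peak centered at the window edge: exp(-4.5)
  rp <- regulatory_potential(tss, make_gr("chr1", 599900, 600100))
  expect_equal(rp$score, exp(-4.5), tolerance = 1e-12)
  # additive over peaks, decreasing in distance
  both <- regulatory_potential(tss, make_gr("chr1", c(499900, 599900),
                                            c(500100, 600100)))
  expect_equal(both$score, exp(-0.5) + exp(-4.5), tolerance = 1e-12)
  near <- regulatory_potential(tss, make_gr("chr1", 509900, 510100))$score
  far <- regulatory_potential(tss, make_gr("chr1", 549900, 550100))$score
  expect_gt(near, far)
})

test_that("the KS statistic equals the pooled-point sup oracle", {
  r <- ks_statistic(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$D, 0)
  expect_equal(r$p.value, 1)
  expect_equal(ks_statistic(c(1, 2), c(3, 4))$D, 1)
  expect_error(ks_statistic(numeric(0), 1), "empty")

  set.seed(83)
  for (rep in 1:30) {
    nx <- sample(3:50, 1); ny <- sample(3:50, 1)
    x <- sample(rnorm(30), nx, replace = TRUE)  # ties happen
    y <- sample(rnorm(30), ny, replace = TRUE)
    r <- ks_statistic(x, y)
    expect_equal(r$D, oracle_ks_D(x, y), tolerance = 1e-12)
    expect_equal(r$D, ks_statistic(y, x)$D)  # symmetry
    # D from the standard implementation agrees
    expect_equal(r$D,
                 unname(suppressWarnings(stats::ks.test(x, y))$statistic),
                 tolerance = 1e-12)
  }
  # asymptotic p agrees with the standard implementation on clean data
  set.seed(89)
  x <- rnorm(80); y <- rnorm(90, 0.4)
  expect_equal(ks_statistic(x, y)$p.value,
               stats::ks.test(x, y, exact = FALSE)$p.value,
               tolerance = 1e-9)
  # KS is invariant under a common strictly monotone transform
  expect_equal(ks_statistic(exp(x), exp(y))$D, ks_statistic(x, y)$D)
})

test_that("activating function is detected when targets have more peaks", {
  set.seed(97)
  n_genes <- 120
  tss <- data.frame(gene_id = sprintf("g%03d", 1:n_genes), chrom = "chr1",
                    position = seq(2e5, by = 3e5, length.out = n_genes),
                    strand = "+", stringsAsFactors = FALSE)
  up <- tss$gene_id[1:30]
  down <- tss$gene_id[31:60]
  static <- tss$gene_id[61:120]
  # up genes get 3x more nearby peaks than the rest
  n_peaks <- ifelse(tss$gene_id %in% up, 6, 2)
  centers <- unlist(lapply(seq_len(n_genes), function(i) {
    tss$position[i] + round(runif(n_peaks[i], -5e4, 5e4))
  }))
  peaks <- make_gr("chr1", centers - 100, centers + 100)
  rp <- regulatory_potential(tss, peaks)
  out <- activating_repressive(rp, up, down, static)
  expect_lt(out$ks$p[out$ks$group == "up"], 0.01)
  expect_equal(out$ks$direction[out$ks$group == "up"], 1)
  # swapping up and down swaps the two results exactly
  sw <- activating_repressive(rp, down, up, static)
  expect_equal(sw$ks$D, out$ks$D[c(2, 1)])
  expect_equal(sw$ks$p, out$ks$p[c(2, 1)])
  # gene order invariance
  perm <- activating_repressive(rp[sample(nrow(rp)), ], up, down, static)
  expect_equal(perm$ks, out$ks)
  expect_error(activating_repressive(rp, up, c(down, up[1]), static),
               "disjoint")
})

test_that("predicted targets apply the static-quantile cutoff exactly", {
  scores <- data.frame(gene_id = sprintf("g%02d", 1:20),
                       score = c(seq(2, 3, length.out = 10),
                                 seq(0, 1, length.out = 10)),
                       n_peaks_in_window = 1L, stringsAsFactors = FALSE)
  de_up <- scores$gene_id[1:5]
  de_down <- scores$gene_id[6:10]
  static <- scores$gene_id[11:20]
  # all DE genes above every static gene
  expect_equal(predicted_targets(scores, de_up, de_down, static, 0.5),
               sort(c(de_up, de_down)))
  # quantile 1.0 with the static maximum above every DE score
  scores2 <- scores
  scores2$score[20] <- 10
  expect_equal(predicted_targets(scores2, de_up, de_down, static, 1.0),
               character(0))
  # random instances match the brute-force filter
  set.seed(101)
  for (rep in 1:10) {
    sc <- data.frame(gene_id = sprintf("g%02d", 1:40),
                     score = runif(40, 0, 5),
                     n_peaks_in_window = 1L, stringsAsFactors = FALSE)
    ix <- sample(40)
    up <- sc$gene_id[ix[1:8]]; down <- sc$gene_id[ix[9:16]]
    st <- sc$gene_id[ix[17:40]]
    qq <- runif(1)
    cutoff <- quantile(sc$score[sc$gene_id %in% st], qq, names = FALSE)
    want <- sort(sc$gene_id[sc$gene_id %in% c(up, down) & sc$score > cutoff])
    expect_equal(predicted_targets(sc, up, down, st, qq), want)
  }
})

test_that("simulated expression tables drive significant target inference", {
  cfg <- sim_config(seed = 103, n_genes = 400L, n_promoters = 300L,
                    n_enhancers = 600L, n_diff_more = 60L, n_diff_less = 60L,
                    n_up_genes = 40L, n_down_genes = 40L,
                    chrom_sizes = c(chr1 = 25e6, chr2 = 20e6))
  ann <- simulate_annotation(cfg)
  ls <- simulate_peak_landscape(cfg, ann)
  ex <- simulate_expression(cfg, ann$tss, eomes_peaks = ls$peaks$eomes_tim)
  tim <- ex$expression[ex$expression$comparison == "tim", ]
  up <- tim$gene_id[tim$q < 0.05 & tim$log2fc > 1]
  down <- tim$gene_id[tim$q < 0.05 & tim$log2fc < -1]
  static <- setdiff(tim$gene_id, c(up, down))
  # thresholding recovers the planted groups exactly
  expect_setequal(up, ex$truth$gene_id[ex$truth$group == "up"])
  expect_setequal(down, ex$truth$gene_id[ex$truth$group == "down"])
  rp <- regulatory_potential(ann$tss, ls$peaks$eomes_tim)
  out <- activating_repressive(rp, up, down, static)
  expect_lt(out$ks$p[out$ks$group == "up"], 0.01)
})
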