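test_that("the consensus rule needs one significant dataset and no conflict", {
  # enumerate the rule table: status per dataset in {up, down, none}
  lfc_of <- c(up = 2, down = -2, none = 0.1)
  q_of <- c(up = 0.001, down = 0.001, none = 0.5)
  combos <- expand.grid(s1 = names(lfc_of), s2 = names(lfc_of),
                        stringsAsFactors = FALSE)
  got <- consensus_tm_status(lfc_of[combos$s1], q_of[combos$s1],
                             lfc_of[combos$s2], q_of[combos$s2])
  want <- with(combos, ifelse(
    (s1 == "up" & s2 != "down") | (s2 == "up" & s1 != "down"), "up",
    ifelse((s1 == "down" & s2 != "up") | (s2 == "down" & s1 != "up"),
           "down", "none")))
  expect_equal(got, want)
  # contradictory significant signs yield none
  expect_equal(consensus_tm_status(2, 0.001, -2, 0.001), "none")
  # strict variant needs both
  strict <- consensus_tm_status(lfc_of[combos$s1], q_of[combos$s1],
                                lfc_of[combos$s2], q_of[combos$s2],
                                rule = "both")
  expect_equal(strict, ifelse(combos$s1 == combos$s2 & combos$s1 != "none",
                              combos$s1, "none"))
})

test_that("cluster assignment covers the full 3x3 status grid", {
  grid <- expand.grid(tm = c("up", "down", "none"),
                      tim = c("up", "down", "none"),
                      stringsAsFactors = FALSE)
  got <- suppressWarnings(assign_cluster(grid$tm, grid$tim))
  key <- paste(grid$tm, grid$tim)
  want <- c("up none" = "C1", "up up" = "C2", "none up" = "C3",
            "down none" = "C4", "down down" = "C5", "none down" = "C6",
            "none none" = "none", "up down" = "none", "down up" = "none")
  expect_equal(got, unname(want[key]))
  expect_warning(assign_cluster("up", "down"), "contradictory")
})

test_that("composition reports per-side percentages that sum to 100", {
  labs <- c(rep("C2", 10), "none")
  comp <- composition(labs)
  expect_equal(comp$percent[comp$cluster == "C2"], 100)
  expect_equal(comp$percent[comp$side == "more_active" &
                              comp$cluster != "C2"], c(0, 0))

  labs <- c("C1", "C2", "C3", "C4", "C5", "C6")
  comp <- composition(labs)
  expect_true(all(abs(comp$percent - 100 / 3) < 1e-9))
  for (s in unique(comp$side)) {
    expect_equal(sum(comp$percent[comp$side == s]), 100)
  }
  expect_error(composition(rep("none", 5)), "no labeled regions")
})

test_that("planted composition is recovered exactly from true labels", {
  cfg <- sim_config(seed = 11)
  ann <- simulate_annotation(cfg)
  ls <- simulate_peak_landscape(cfg, ann)
  truth <- ls$truth
  labels <- assign_cluster(
    tm = ifelse(truth$lcmv == "null", "none", truth$lcmv),
    tim = ifelse(truth$tim == "null", "none", truth$tim))
  comp <- composition(labels)
  expect_equal(comp$percent[comp$side == "more_active"], c(55, 34, 11))
  expect_equal(comp$percent[comp$side == "less_active"], c(57, 36, 7))
})

test_that("median-of-replicates fold-change is robust to one outlier", {
  # identical replicates reduce to the pooled ratio
  expect_equal(median_replicate_lfc(c(20, 20), c(5, 5),
                                    c(1e6, 1e6), c(1e6, 1e6)),
               log2_fold_change(20, 5))
  # outlier replicate leaves the median untouched
  expect_equal(median_replicate_lfc(c(10, 100, 10), c(10, 10, 10),
                                    rep(1e6, 3), rep(1e6, 3)), 0)
  set.seed(53)
  for (rep in 1:20) {
    na <- sample(1:4, 1); nb <- sample(1:4, 1)
    ca <- rpois(na, 60); cb <- rpois(nb, 60)
    la <- runif(na, 5e5, 2e6); lb <- runif(nb, 5e5, 2e6)
    nmin <- min(c(la, lb))
    norm_a <- sign(ca) * floor(abs(ca * nmin / la) + 0.5)
    norm_b <- sign(cb) * floor(abs(cb * nmin / lb) + 0.5)
    want <- log2((median(norm_a) + 1) / (median(norm_b) + 1))
    expect_equal(median_replicate_lfc(ca, cb, la, lb), want)
  }
})

test_that("the signed-rank exact p equals full sign enumeration", {
  # all pairs identical: p = 1 by convention
  expect_equal(wilcoxon_signed_rank(rep(1, 6), rep(1, 6))$p.value, 1)
  # n = 6, all positive differences: W at the extreme, p = 2/64
  r <- wilcoxon_signed_rank(7:12, 1:6)
  expect_equal(r$statistic, 21)
  expect_equal(r$p.value, 2 / 64)

  set.seed(59)
  for (n in c(6, 9, 12)) {
    for (rep in 1:5) {
      x <- rnorm(n); y <- rnorm(n)
      # include ties in |d| half the time
      if (rep %% 2 == 0) {
        d <- sample(c(-2, -1, 1, 2), n, replace = TRUE)
        y <- x - d
      }
      got <- wilcoxon_signed_rank(x, y)
      expect_equal(got$method, "exact")
      expect_equal(got$p.value, oracle_signed_rank_p(x - y))
    }
  }
})

test_that("exact and approximate signed-rank p agree near the cutover", {
  set.seed(61)
  for (rep in 1:10) {
    x <- rnorm(25); y <- rnorm(25, 0.3)
    exact <- wilcoxon_signed_rank(x, y, exact_max = 25)$p.value
    approx <- wilcoxon_signed_rank(x, y, exact_max = 0)$p.value
    expect_lt(abs(exact - approx), 0.01)
  }
  # cross-check the clean-data exact path against stats::wilcox.test
  x <- c(1.1, 2.3, -0.7, 4.2, 0.9, -1.8, 3.3, 2.2)
  y <- c(0.2, 1.1, 0.4, 2.0, -0.35, 0.5, 1.2, 3.0)
  expect_equal(wilcoxon_signed_rank(x, y)$p.value,
               wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value)
})

test_that("cluster expression shift runs per cluster and enforces n >= 5", {
  genes <- sprintf("g%02d", 1:30)
  tm <- setNames(rnorm(30, 1), genes)
  tim <- setNames(rnorm(30, 0.2), genes)
  sets <- list(C1 = genes[1:10], C2 = genes[11:30])
  out <- cluster_expression_shift(tm, tim, sets)
  expect_equal(out$cluster, c("C1", "C2"))
  expect_equal(out$n, c(10L, 20L))
  expect_true(all(out$p > 0 & out$p <= 1))
  expect_error(cluster_expression_shift(tm, tim, list(Cx = genes[1:3])),
               "fewer than")
})

test_that("TF overlap percentages reflect planted cluster preference", {
  c1 <- make_gr("chr1", c(0, 1000), c(500, 1500))
  c2 <- make_gr("chr1", c(10000, 20000), c(10500, 20500))
  tf_all_c2 <- make_gr("chr1", c(10000, 20000), c(10500, 20500))
  out <- cluster_tf_overlap(list(C1 = c1, C2 = c2),
                            list(TF = tf_all_c2,
                                 EMPTY = GenomicRanges::GRanges()))
  expect_equal(out$percent[out$cluster == "C2" & out$factor == "TF"], 100)
  expect_equal(out$percent[out$cluster == "C1" & out$factor == "TF"], 0)
  expect_true(all(out$percent[out$factor == "EMPTY"] == 0))

  # planted landscape: EOMES prefers the clusters gained in innate memory
  cfg <- sim_config(seed = 19)
  ann <- simulate_annotation(cfg)
  ls <- simulate_peak_landscape(cfg, ann)
  truth <- ls$truth
  cl_gr <- function(cl) {
    d <- truth[truth$cluster %in% cl, ]
    make_gr(d$chrom, d$start, d$end)
  }
  ov <- cluster_tf_overlap(list(C1 = cl_gr("C1"), C2 = cl_gr("C2"),
                                C3 = cl_gr("C3")),
                           list(EOMES = ls$peaks$eomes_tim))
  pct <- setNames(ov$percent, ov$cluster)
  expect_gt(pct["C2"], pct["C1"])
  expect_gt(pct["C3"], pct["C1"])
})
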