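test_that("fragment counting credits every region a fragment touches", {
  atlas <- build_atlas(list(x = make_gr("chr1", c(0, 200), c(100, 300))))
  frags <- list(
    s1 = make_gr("chr1", c(10, 50, 150), c(20, 250, 180)),
    s2 = make_gr("chr1", 250, 260))
  cm <- count_fragments(atlas, frags, condition = c("a", "b"))
  # fragment [50,250) spans the gap and hits both regions
  expect_equal(unname(cm$counts[, 1]), c(2L, 1L))
  expect_equal(unname(cm$counts[, 2]), c(0L, 1L))
  expect_equal(cm$library_sizes, c(3, 1))

  set.seed(31)
  for (rep in 1:10) {
    atlas <- build_atlas(list(x = random_intervals(30)))
    fr <- random_intervals(80)
    cm <- count_fragments(atlas, list(s = fr), condition = "a")
    a <- gr_to_df0(atlas)
    f <- gr_to_df0(fr)
    want <- vapply(seq_len(nrow(a)), function(i) {
      sum(f$chrom == a$chrom[i] &
            pmin(f$end, a$end[i]) - pmax(f$start, a$start[i]) >= 1)
    }, numeric(1))
    expect_equal(unname(cm$counts[, 1]), as.integer(want))
  }
})

test_that("normalization scales to the lowest library, half away from zero", {
  expect_equal(normalize_to_lowest(c(10, 10), c(1e6, 1e6)), c(10L, 10L))
  expect_equal(normalize_to_lowest(matrix(c(10, 10), 1), c(1e6, 2e6))[1, ],
               c(10L, 5L))
  expect_equal(normalize_to_lowest(c(1, 0), c(2.5e6, 1e6)), c(0L, 0L))
  expect_equal(normalize_to_lowest(c(5, 0), c(2e6, 1e6)), c(3L, 0L))  # 2.5 up
  expect_error(normalize_to_lowest(c(1, 1), c(0, 1)), "positive")
})

test_that("the Poisson test is symmetric, exact and conservative", {
  expect_equal(poisson_two_sided_p(0, 0), 1)
  expect_equal(poisson_two_sided_p(7, 7), 1)
  expect_equal(poisson_two_sided_p(10, 0), oracle_poisson_p(10, 0),
               tolerance = 1e-12)
  expect_equal(poisson_two_sided_p(10, 0), 2 * exp(-5), tolerance = 1e-4)
  set.seed(37)
  for (rep in 1:50) {
    a <- rpois(1, 40); b <- rpois(1, 40)
    expect_equal(poisson_two_sided_p(a, b), poisson_two_sided_p(b, a))
    expect_equal(poisson_two_sided_p(a, b), oracle_poisson_p(a, b),
                 tolerance = 1e-12)
    p <- poisson_two_sided_p(a, b)
    expect_true(p > 0 && p <= 1)
  }
  expect_error(poisson_two_sided_p(-1, 2), "non-negative")
})

test_that("the proportion filter is the exact conditional binomial", {
  expect_equal(proportion_filter_p(0, 0, 1e6, 1e6), 1)
  expect_equal(proportion_filter_p(5, 5, 1e6, 1e6), 1)
  expect_equal(proportion_filter_p(10, 0, 1e6, 1e6), 2 * 0.5^10,
               tolerance = 1e-12)
  set.seed(41)
  for (rep in 1:50) {
    ka <- rpois(1, 30); kb <- rpois(1, 30)
    Na <- runif(1, 5e5, 2e6); Nb <- runif(1, 5e5, 2e6)
    expect_equal(proportion_filter_p(ka, kb, Na, Nb),
                 oracle_binom_p(ka, kb, Na, Nb), tolerance = 1e-12)
    expect_equal(proportion_filter_p(ka, kb, Na, Nb),
                 proportion_filter_p(kb, ka, Nb, Na), tolerance = 1e-12)
  }
})

test_that("log2 fold-change is the pseudocounted ratio and antisymmetric", {
  expect_equal(log2_fold_change(0, 0), 0)
  expect_equal(log2_fold_change(15, 3, 1), 2)
  set.seed(43)
  a <- rpois(20, 50); b <- rpois(20, 50)
  expect_equal(log2_fold_change(a, b), -log2_fold_change(b, a))
})

test_that("BH adjustment equals the closed-form step-up", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(47)
  for (rep in 1:25) {
    p <- runif(sample(5:80, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_equal(order(q[order(p)]), seq_along(p))  # monotone in p
  }
})

test_that("differential calls are invariant to ordering and library scaling", {
  sim <- simulate_count_matrix(400, sim_config(seed = 3), seed = 99)
  res <- call_differential(sim$counts)

  # region order invariance
  perm <- sample(nrow(sim$counts$counts))
  m2 <- count_matrix(sim$counts$counts[perm, ],
                     region_ids = sim$counts$region_ids[perm],
                     condition = sim$counts$condition,
                     library_sizes = sim$counts$library_sizes)
  res2 <- call_differential(m2)
  expect_equal(res2[order(res2$region_id), ],
               res[order(res$region_id), ], ignore_attr = TRUE)

  # sample order invariance (swap columns within conditions)
  cfg3 <- sim_config(seed = 3, replicates = 2L)
  sim3 <- simulate_count_matrix(200, cfg3, seed = 77)
  sperm <- c(2, 1, 4, 3)
  m3 <- count_matrix(sim3$counts$counts[, sperm],
                     region_ids = sim3$counts$region_ids,
                     condition = sim3$counts$condition[sperm],
                     library_sizes = sim3$counts$library_sizes[sperm])
  expect_equal(call_differential(m3), call_differential(sim3$counts),
               ignore_attr = TRUE)

  # rescaling every library by a common factor changes nothing: only the
  # library-size ratios enter the normalization
  m4 <- count_matrix(sim$counts$counts,
                     region_ids = sim$counts$region_ids,
                     condition = sim$counts$condition,
                     library_sizes = 2 * sim$counts$library_sizes)
  expect_equal(call_differential(m4), res, ignore_attr = TRUE)
  res_filt <- call_differential(sim$counts,
                                diff_config(use_proportion_filter = TRUE))
  m5 <- count_matrix(sim$counts$counts,
                     region_ids = sim$counts$region_ids,
                     condition = sim$counts$condition,
                     library_sizes = 3 * sim$counts$library_sizes)
  expect_equal(call_differential(m5, diff_config(use_proportion_filter = TRUE)),
               res_filt, ignore_attr = TRUE)
})

test_that("identical pooled counts give zero calls; 3 conditions error", {
  counts <- matrix(rep(c(10, 25, 40), 2), ncol = 2)
  m <- count_matrix(counts, condition = c("a", "b"),
                    library_sizes = c(1e6, 1e6))
  res <- call_differential(m)
  expect_true(all(res$direction == "ns"))
  expect_true(all(res$p_poisson == 1))

  m3 <- count_matrix(cbind(counts, counts[, 1]),
                     condition = c("a", "b", "c"),
                     library_sizes = rep(1e6, 3))
  expect_error(call_differential(m3), "pairwise")
})

test_that("the proportion filter gates calls when enabled", {
  sim <- simulate_count_matrix(500, sim_config(seed = 8), seed = 123)
  res_plain <- call_differential(sim$counts, diff_config())
  res_filt <- call_differential(sim$counts,
                                diff_config(use_proportion_filter = TRUE))
  called_plain <- res_plain$region_id[res_plain$direction != "ns"]
  called_filt <- res_filt$region_id[res_filt$direction != "ns"]
  expect_true(all(called_filt %in% called_plain))
  expect_false(any(is.na(res_filt$p_proportion)))
})
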