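test_that("read_bed parses BED3/BED6 and rejects malformed coordinates", {
  f <- tempfile(fileext = ".bed")
  on.exit(unlink(f))

  writeLines(character(0), f)
  expect_length(read_bed(f), 0)

  writeLines("chr1\t0\t100", f)
  gr <- read_bed(f)
  expect_equal(GenomicRanges::start(gr), 1)
  expect_equal(GenomicRanges::end(gr), 100)
  expect_equal(as.character(GenomicRanges::strand(gr)), "*")

  writeLines(c("track name=x", "# comment",
               "chr2\t10\t20\tpeak1\t7.5\t-",
               "chr1\t5\t15\tpeak2\t1\t+"), f)
  gr <- read_bed(f)
  expect_equal(as.character(GenomicRanges::seqnames(gr)), c("chr1", "chr2"))
  expect_equal(gr$name, c("peak2", "peak1"))
  expect_equal(as.character(GenomicRanges::strand(gr)), c("+", "-"))

  writeLines("chr1\t100\t100", f)
  expect_error(read_bed(f), "line 1")
  writeLines(c("chr1\t0\t10", "chr1\tfoo\t20"), f)
  expect_error(read_bed(f), "line 2")
})

test_that("BED write/read round-trips losslessly", {
  gr <- make_gr(c("chr1", "chr1", "chr2"), c(0, 500, 9), c(100, 800, 10))
  f <- tempfile(fileext = ".bed")
  on.exit(unlink(f))
  write_bed(gr, f)
  back <- read_bed(f)
  expect_equal(gr_to_df0(back), gr_to_df0(gr))
})

test_that("merging fuses overlapping but not book-ended intervals", {
  expect_equal(gr_to_df0(merge_intervals(make_gr("chr1", c(0, 5), c(10, 20)))),
               data.frame(chrom = "chr1", start = 0, end = 20))
  # gap 0, overlap 0 bp: stays separate under the 1 bp rule
  bk <- merge_intervals(make_gr("chr1", c(0, 10), c(10, 20)))
  expect_length(bk, 2)
})

test_that("merge matches the union-find pairwise oracle on random sets", {
  set.seed(42)
  for (rep in 1:40) {
    gr <- random_intervals(60)
    got <- gr_to_df0(merge_intervals(gr))
    want <- oracle_merge(gr)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
  # larger single instance, and a min_overlap > 1 case
  gr <- random_intervals(1000, n_chrom = 3, max_pos = 5000)
  expect_equal(`rownames<-`(gr_to_df0(merge_intervals(gr)), NULL),
               `rownames<-`(oracle_merge(gr), NULL))
  gr <- random_intervals(80, max_pos = 400)
  expect_equal(`rownames<-`(gr_to_df0(merge_intervals(gr, 10)), NULL),
               `rownames<-`(oracle_merge(gr, 10), NULL))
})

test_that("merge is idempotent and order-invariant", {
  set.seed(7)
  for (rep in 1:10) {
    gr <- random_intervals(50)
    m1 <- merge_intervals(gr)
    expect_equal(gr_to_df0(merge_intervals(m1)), gr_to_df0(m1))
    perm <- gr[sample(length(gr))]
    expect_equal(gr_to_df0(merge_intervals(perm)), gr_to_df0(m1))
  }
})

test_that("atlas membership flags match the brute-force overlap check", {
  # single set: atlas is the merged set, all memberships true
  a <- make_gr("chr1", c(0, 50), c(100, 150))
  atl <- build_atlas(list(A = a))
  expect_equal(gr_to_df0(atl), gr_to_df0(merge_intervals(a)))
  expect_true(all(atl$A))

  # the two-set example: one spanning region, both members
  atl <- build_atlas(list(A = make_gr("chr1", 0, 100),
                          B = make_gr("chr1", 50, 150)))
  expect_equal(gr_to_df0(atl), data.frame(chrom = "chr1", start = 0, end = 150))
  expect_true(atl$A && atl$B)

  set.seed(11)
  for (rep in 1:20) {
    sets <- list(A = random_intervals(30), B = random_intervals(25),
                 C = random_intervals(35))
    atl <- build_atlas(sets)
    for (lab in names(sets)) {
      expect_equal(S4Vectors::mcols(atl)[[lab]],
                   oracle_membership(atl, sets[[lab]]))
    }
    # non-overlapping output covering exactly the union of inputs
    df <- gr_to_df0(atl)
    by_chr <- split(df, df$chrom)
    for (b in by_chr) {
      if (nrow(b) > 1) expect_true(all(b$start[-1] >= b$end[-nrow(b)]))
    }
    pooled <- GenomicRanges::reduce(do.call(c, unname(sets)),
                                    min.gapwidth = 0L)
    expect_equal(sum(df$end - df$start),
                 sum(GenomicRanges::width(pooled)))
  }

  expect_error(build_atlas(list(A = a, A = a)), "duplicate")
})

test_that("venn counts enumerate membership patterns and sum correctly", {
  atl <- build_atlas(list(A = make_gr("chr1", 0, 100),
                          B = make_gr("chr2", 0, 100)))
  expect_equal(venn_counts(atl, "A", "B"),
               c(only_a = 1L, shared = 0L, only_b = 1L))
  same <- make_gr("chr1", c(0, 200), c(100, 300))
  atl <- build_atlas(list(A = same, B = same))
  expect_equal(venn_counts(atl, "A", "B"),
               c(only_a = 0L, shared = 2L, only_b = 0L))
  expect_error(venn_counts(atl, "A", "Z"), "unknown")

  set.seed(13)
  for (rep in 1:10) {
    sets <- list(A = random_intervals(25), B = random_intervals(25),
                 C = random_intervals(25))
    atl <- build_atlas(sets)
    v <- venn_counts(atl, "A", "B")
    ma <- S4Vectors::mcols(atl)$A
    mb <- S4Vectors::mcols(atl)$B
    expect_equal(unname(v),
                 c(sum(ma & !mb), sum(ma & mb), sum(!ma & mb)))
    expect_equal(sum(v), sum(ma | mb))
  }
})

test_that("overlap fraction counts query regions and grows with the reference", {
  q <- make_gr("chr1", c(0, 100, 200, 300), c(50, 150, 250, 350))
  expect_equal(overlap_fraction(q, q), 1.0)
  expect_equal(overlap_fraction(q, make_gr("chr2", 0, 1000)), 0.0)
  expect_equal(overlap_fraction(q, make_gr("chr1", c(0, 100), c(50, 150))), 0.5)
  expect_error(overlap_fraction(GenomicRanges::GRanges(), q), "empty")

  set.seed(17)
  ref <- random_intervals(10)
  prev <- overlap_fraction(q, ref)
  for (rep in 1:5) {
    ref <- c(ref, random_intervals(5))
    cur <- overlap_fraction(q, ref)
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("point distances use the last included base", {
  gr <- make_gr("chr1", 100, 200)
  expect_equal(distance_to_nearest_point(
    gr, data.frame(chrom = "chr1", position = 150)), 0)
  expect_equal(distance_to_nearest_point(
    gr, data.frame(chrom = "chr1", position = 250)), 51)
  expect_equal(distance_to_nearest_point(
    gr, data.frame(chrom = "chr1", position = 50)), 50)
  expect_equal(distance_to_nearest_point(
    gr, data.frame(chrom = "chr9", position = 150)), Inf)
})
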