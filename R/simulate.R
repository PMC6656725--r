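#' Synthetic study generator with planted ground truth
#'
#' Generates a complete miniature study -- genome annotation, peak
#' landscapes for histone marks and transcription factors, Poisson count
#' matrices with planted log2 effects, motif-bearing sequences, expression
#' tables and bivariate cell intensities -- whose every planted truth is
#' recorded, so each pipeline stage can be scored without external data.
#' All generation is a pure function of the configuration (which carries the
#' seed); the caller's RNG state is left untouched.
#'
#' @name synthetic-data
NULL

# run code under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Defaults define the study conditions the generator emulates. The
#' `"small"` preset shrinks the study's region counts roughly tenfold for
#' fast tests; `"paper_scale"` matches the printed magnitudes (9,814
#' promoters, 20,103 enhancers, and an activity atlas near 29,414 regions).
#' Differential enhancers split 55/34/11 (gains) and 57/36/7 (losses)
#' across the concordance clusters; 65% of EOMES regions carry RUNX3 in
#' naive and/or memory cells with 43% already RUNX3-bound in the naive
#' state.
#'
#' @param seed Integer master seed; stage generators derive child seeds
#'   from it.
#' @param preset `"small"` (default) or `"paper_scale"`.
#' @param ... Overrides for any configuration field.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, preset = c("small", "paper_scale"), ...) {
  preset <- match.arg(preset)
  base <- list(
    seed = as.integer(seed),
    chrom_sizes = c(chr1 = 40e6, chr2 = 35e6, chr3 = 25e6),
    n_genes = 1000L,
    n_promoters = 981L,
    n_enhancers = 2010L,
    min_tss_spacing = 20000L,
    tss_exclusion = 8000L,        # enhancer centers stay this far from TSSs
    h3k27ac_fraction = 0.95,
    n_diff_more = 200L,
    n_diff_less = 200L,
    cluster_composition_more = c(C1 = 0.55, C2 = 0.34, C3 = 0.11),
    cluster_composition_less = c(C4 = 0.57, C5 = 0.36, C6 = 0.07),
    effect_fraction = 0.1,
    effect_log2fc = 2,
    mu_range = c(20, 500),
    library_sizes = c(1.0e6, 1.2e6),
    replicates = 1L,
    overdispersion = 0,
    peak_jitter = 50L,
    tf_peak_width = 200L,
    cobound_any_fraction = 0.65,
    prebound_runx3_fraction = 0.43,
    eomes_background_fraction = 0.05,
    n_sequences = 500L,
    seq_window = 250L,
    gc_content = 0.42,
    motif_offset_sd = 20,
    plant_fraction = 1,
    n_up_genes = 100L,
    n_down_genes = 100L,
    n_cells = 2000L,
    tau_targets = c(control = 0.5, mutant = 0.2),
    cell_meanlog = 6,
    cell_sdlog = 0.8
  )
  if (preset == "paper_scale") {
    base$chrom_sizes <- c(chr1 = 150e6, chr2 = 140e6, chr3 = 130e6,
                          chr4 = 120e6, chr5 = 110e6)
    base$n_genes <- 12000L
    base$n_promoters <- 9814L
    base$n_enhancers <- 20103L
    base$n_diff_more <- 1000L
    base$n_diff_less <- 1100L
    base$n_sequences <- 2000L
  }
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(base))
  if (length(unknown) > 0L) {
    stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "))
  }
  base[names(overrides)] <- overrides
  stopifnot(base$effect_fraction >= 0, base$effect_fraction < 1,
            abs(sum(base$cluster_composition_more) - 1) < 1e-9,
            abs(sum(base$cluster_composition_less) - 1) < 1e-9,
            all(abs(base$tau_targets) < 1))
  structure(base, class = "sim_config")
}

# exact integer split of n by proportions (largest remainder)
proportion_counts <- function(n, props) {
  raw <- n * props
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  stats::setNames(as.integer(counts), names(props))
}

#' Simulate a genome annotation (TSS table)
#'
#' TSS positions are uniform within each chromosome subject to a minimum
#' pairwise spacing; strands are Bernoulli(0.5). Genes are allotted to
#' chromosomes proportionally to size.
#'
#' @param cfg A [sim_config()].
#' @return List with `tss` (data.frame: gene_id, chrom, position, strand)
#'   and `chrom_sizes`.
#' @export
simulate_annotation <- function(cfg) {
  with_seed(cfg$seed + 101L, {
    sizes <- cfg$chrom_sizes
    n_per <- proportion_counts(cfg$n_genes, sizes / sum(sizes))
    spacing <- cfg$min_tss_spacing
    edge <- 50000  # keep windows clear of chromosome ends
    rows <- lapply(names(sizes), function(ch) {
      n <- n_per[[ch]]
      if (n == 0L) return(NULL)
      usable <- sizes[[ch]] - 2 * edge - (n - 1) * spacing
      if (usable <= 0) {
        stop("infeasible packing: ", n, " genes at ", spacing,
             " bp spacing do not fit on ", ch)
      }
      pos <- sort(round(stats::runif(n, 0, usable))) +
        edge + (seq_len(n) - 1) * spacing
      data.frame(chrom = ch, position = pos, stringsAsFactors = FALSE)
    })
    tss <- do.call(rbind, rows)
    tss$gene_id <- sprintf("gene_%05d", seq_len(nrow(tss)))
    tss$strand <- ifelse(stats::runif(nrow(tss)) < 0.5, "+", "-")
    list(tss = tss[, c("gene_id", "chrom", "position", "strand")],
         chrom_sizes = sizes)
  })
}

# uniform enhancer centers avoiding TSS neighbourhoods and one another
sample_enhancer_centers <- function(n, chrom_sizes, tss, exclusion,
                                    min_gap = 2000) {
  sizes <- chrom_sizes
  tss_by <- split(tss$position, tss$chrom)
  placed <- stats::setNames(vector("list", length(sizes)), names(sizes))
  out_ch <- character(n)
  out_pos <- numeric(n)
  got <- 0L
  attempts <- 0L
  while (got < n) {
    attempts <- attempts + 1L
    if (attempts > 200L * n) stop("could not place enhancers; relax geometry")
    ch <- sample(names(sizes), 1L, prob = sizes / sum(sizes))
    pos <- round(stats::runif(1, exclusion, sizes[[ch]] - exclusion))
    tp <- tss_by[[ch]]
    if (!is.null(tp) && min(abs(tp - pos)) < exclusion) next
    pp <- placed[[ch]]
    if (!is.null(pp) && length(pp) > 0L && min(abs(pp - pos)) < min_gap) next
    got <- got + 1L
    out_ch[got] <- ch
    out_pos[got] <- pos
    placed[[ch]] <- c(pp, pos)
  }
  data.frame(chrom = out_ch, center = out_pos, stringsAsFactors = FALSE)
}

jitter_peaks <- function(gr, jitter, min_width = 50L) {
  if (jitter == 0L || length(gr) == 0L) return(GenomicRanges::granges(gr))
  s <- GenomicRanges::start(gr) +
    sample(seq(-jitter, jitter), length(gr), replace = TRUE)
  e <- GenomicRanges::end(gr) +
    sample(seq(-jitter, jitter), length(gr), replace = TRUE)
  s <- pmax(s, 1L)
  e <- pmax(e, s + min_width - 1L)
  sort_intervals(GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                        IRanges::IRanges(s, e)))
}

#' Simulate the peak landscape with planted regulatory truth
#'
#' Places H3K4me3 peaks inside strand-aware promoter windows and H3K4me1
#' peaks well away from every TSS (so annotation can recover the planted
#' classes exactly), overlays H3K27ac on a configured fraction of each,
#' assigns differential/cluster labels to enhancer loci at the configured
#' composition, and plants EOMES peaks in the clusters gained in innate
#' memory (C2/C3) with RUNX3 co-binding -- including naive-state
#' pre-positioning for the configured pioneer fraction. Per-condition peak
#' sets get independent +/- `peak_jitter` bp boundary noise.
#'
#' @param cfg A [sim_config()].
#' @param annotation Output of [simulate_annotation()].
#' @return List with `peaks` (named list of `GRanges`: h3k4me3/h3k4me1/
#'   h3k27ac per condition, and eomes_tim/runx3_naive/runx3_tim) and
#'   `truth` (data.frame of loci with planted flags and labels).
#' @export
simulate_peak_landscape <- function(cfg, annotation) {
  tss <- annotation$tss
  with_seed(cfg$seed + 202L, {
    if (cfg$n_promoters > nrow(tss)) {
      stop("n_promoters exceeds the number of simulated genes")
    }
    # --- promoter loci: one H3K4me3 peak inside each selected gene window
    prom_genes <- sort(sample(nrow(tss), cfg$n_promoters))
    pg <- tss[prom_genes, ]
    w <- round(stats::runif(nrow(pg), 800, 1500))
    win_lo <- ifelse(pg$strand == "+", pg$position - 5000, pg$position - 2000)
    win_hi <- ifelse(pg$strand == "+", pg$position + 2000, pg$position + 5000)
    centers <- round(stats::runif(nrow(pg), win_lo + w / 2 + 150,
                                  win_hi - w / 2 - 150))
    prom <- data.frame(chrom = pg$chrom,
                       start = round(centers - w / 2),
                       end = round(centers + w / 2),
                       reg_class = "promoter",
                       gene_id = pg$gene_id,
                       stringsAsFactors = FALSE)
    # --- enhancer loci: clear of every TSS neighbourhood
    ec <- sample_enhancer_centers(cfg$n_enhancers, annotation$chrom_sizes,
                                  tss, cfg$tss_exclusion)
    ew <- round(stats::runif(nrow(ec), 600, 1200))
    enh <- data.frame(chrom = ec$chrom,
                      start = round(ec$center - ew / 2),
                      end = round(ec$center + ew / 2),
                      reg_class = "enhancer",
                      gene_id = NA_character_,
                      stringsAsFactors = FALSE)
    loci <- rbind(prom, enh)
    loci$locus_id <- sprintf("locus_%06d", seq_len(nrow(loci)))
    loci$h3k27ac <- stats::runif(nrow(loci)) < cfg$h3k27ac_fraction
    # --- differential truth on H3K27ac+ enhancer loci
    loci$lcmv <- "null"; loci$listeria <- "null"; loci$tim <- "null"
    loci$cluster <- "none"
    cand <- which(loci$reg_class == "enhancer" & loci$h3k27ac)
    n_diff <- cfg$n_diff_more + cfg$n_diff_less
    if (n_diff > length(cand)) stop("not enough enhancer loci for n_diff")
    diff_idx <- sample(cand, n_diff)
    more_idx <- diff_idx[seq_len(cfg$n_diff_more)]
    less_idx <- diff_idx[cfg$n_diff_more + seq_len(cfg$n_diff_less)]
    cm <- proportion_counts(cfg$n_diff_more, cfg$cluster_composition_more)
    cl <- proportion_counts(cfg$n_diff_less, cfg$cluster_composition_less)
    loci$cluster[more_idx] <- rep(names(cm), cm)
    loci$cluster[less_idx] <- rep(names(cl), cl)
    rules <- list(C1 = c("up", "up", "null"), C2 = c("up", "up", "up"),
                  C3 = c("null", "null", "up"),
                  C4 = c("down", "down", "null"),
                  C5 = c("down", "down", "down"),
                  C6 = c("null", "null", "down"))
    for (cl_name in names(rules)) {
      ix <- loci$cluster == cl_name
      loci$lcmv[ix] <- rules[[cl_name]][1]
      loci$listeria[ix] <- rules[[cl_name]][2]
      loci$tim[ix] <- rules[[cl_name]][3]
    }
    # --- transcription-factor truth
    loci$eomes <- loci$cluster %in% c("C2", "C3")
    bg <- which(loci$reg_class == "enhancer" & !loci$eomes)
    n_bg <- round(cfg$eomes_background_fraction * length(bg))
    loci$eomes[sample(bg, n_bg)] <- TRUE
    u <- stats::runif(nrow(loci))
    loci$runx3_naive <- loci$eomes & u < cfg$prebound_runx3_fraction
    loci$runx3_tim <- loci$eomes & u < cfg$cobound_any_fraction
    # --- emit peak sets
    gr_of <- function(df) {
      if (nrow(df) == 0L) return(GenomicRanges::GRanges())
      sort_intervals(GenomicRanges::GRanges(
        df$chrom, IRanges::IRanges(df$start + 1, df$end)))
    }
    tf_gr <- function(flag) {
      df <- loci[flag, , drop = FALSE]
      if (nrow(df) == 0L) return(GenomicRanges::GRanges())
      ctr <- (df$start + df$end) / 2 +
        sample(c(-1, 1), nrow(df), replace = TRUE) *
        round(stats::runif(nrow(df), 20, 60))
      hw <- cfg$tf_peak_width / 2
      sort_intervals(GenomicRanges::GRanges(
        df$chrom, IRanges::IRanges(round(ctr - hw) + 1, round(ctr + hw))))
    }
    j <- cfg$peak_jitter
    peaks <- list(
      h3k4me3 = list(naive = jitter_peaks(gr_of(prom), j),
                     tim = jitter_peaks(gr_of(prom), j)),
      h3k4me1 = list(naive = jitter_peaks(gr_of(enh), j),
                     tim = jitter_peaks(gr_of(enh), j)),
      h3k27ac = list(
        naive = jitter_peaks(gr_of(loci[loci$h3k27ac, ]), j),
        tim = jitter_peaks(gr_of(loci[loci$h3k27ac, ]), j)),
      eomes_tim = tf_gr(loci$eomes),
      runx3_naive = tf_gr(loci$runx3_naive),
      runx3_tim = tf_gr(loci$runx3_tim)
    )
    list(peaks = peaks, truth = loci)
  })
}

#' Simulate a Poisson count matrix with planted effects
#'
#' Region counts are Poisson with rate `(N_s / N_min) * mu_r *
#' 2^(beta_r * memory_s)`, where `mu_r` is log-uniform over `mu_range`,
#' `beta_r = +/- effect_log2fc` for a planted fraction of regions (split
#' evenly between up and down) and 0 elsewhere, and `memory_s` indicates
#' the memory condition. Setting `overdispersion > 0` draws gamma-mixed
#' rates (gamma-Poisson) to probe robustness to model misspecification.
#'
#' @param n_regions Number of regions.
#' @param cfg A [sim_config()] supplying effect size/fraction, library
#'   sizes, replicates and overdispersion.
#' @param seed Seed for this draw (defaults to `cfg$seed + 303`).
#' @param labels Optional per-region labels in `{up, down, null}`
#'   overriding the random planting (length `n_regions`).
#' @return List with `counts` (a [count_matrix()], conditions `memory` then
#'   `naive`) and `truth` (data.frame: region_id, label, beta, mu).
#' @export
simulate_count_matrix <- function(n_regions, cfg = sim_config(),
                                  seed = cfg$seed + 303L, labels = NULL) {
  with_seed(seed, {
    if (is.null(labels)) {
      labels <- rep("null", n_regions)
      n_eff <- round(cfg$effect_fraction * n_regions)
      if (n_eff > 0) {
        idx <- sample(n_regions, n_eff)
        labels[idx] <- rep(c("up", "down"), length.out = n_eff)
      }
    }
    stopifnot(length(labels) == n_regions)
    beta <- ifelse(labels == "up", cfg$effect_log2fc,
                   ifelse(labels == "down", -cfg$effect_log2fc, 0))
    mu <- exp(stats::runif(n_regions, log(cfg$mu_range[1]),
                           log(cfg$mu_range[2])))
    reps <- cfg$replicates
    libs <- rep(cfg$library_sizes, each = reps)
    n_min <- min(cfg$library_sizes)
    cond <- rep(c("memory", "naive"), each = reps)
    lam <- outer(mu, libs / n_min) *
      2^(beta %o% as.numeric(cond == "memory"))
    if (cfg$overdispersion > 0) {
      shape <- 1 / cfg$overdispersion
      lam <- matrix(stats::rgamma(length(lam), shape = shape,
                                  scale = lam / shape), nrow = n_regions)
    }
    counts <- matrix(stats::rpois(length(lam), lam), nrow = n_regions)
    rid <- sprintf("region_%06d", seq_len(n_regions))
    cm <- count_matrix(counts, region_ids = rid,
                       sample_ids = paste(cond, seq_along(cond), sep = "_"),
                       condition = cond, library_sizes = libs)
    list(counts = cm,
         truth = data.frame(region_id = rid, label = labels, beta = beta,
                            mu = mu, stringsAsFactors = FALSE))
  })
}

#' Simulate count matrices for the three memory comparisons
#'
#' One count matrix per comparison (`lcmv`, `listeria`, `tim`) over the
#' H3K27ac-positive enhancer loci of a simulated landscape, with effects
#' planted according to each locus's truth label for that comparison.
#'
#' @param landscape Output of [simulate_peak_landscape()].
#' @param cfg A [sim_config()].
#' @return Named list of [simulate_count_matrix()] results; each `truth`
#'   gains a `locus_id` column.
#' @export
simulate_counts <- function(landscape, cfg) {
  loci <- landscape$truth
  enh <- loci[loci$reg_class == "enhancer" & loci$h3k27ac, , drop = FALSE]
  comparisons <- c("lcmv", "listeria", "tim")
  out <- lapply(seq_along(comparisons), function(i) {
    cmp <- comparisons[i]
    lab <- ifelse(enh[[cmp]] == "up", "up",
                  ifelse(enh[[cmp]] == "down", "down", "null"))
    r <- simulate_count_matrix(nrow(enh), cfg,
                               seed = cfg$seed + 303L + i, labels = lab)
    r$truth$locus_id <- enh$locus_id
    r$counts$region_ids <- enh$locus_id
    rownames(r$counts$counts) <- enh$locus_id
    r$truth$region_id <- enh$locus_id
    r
  })
  stats::setNames(out, comparisons)
}

#' Synthetic T-box-like PWM (EOMES surrogate)
#'
#' High-information synthetic matrix over the canonical T-box core
#' `AGGTGTGA`, padded to 10 positions. Not a database matrix; built for
#' plant-and-recover testing.
#'
#' @param p Probability of the consensus base at each position
#'   (default 0.94).
#' @return A [make_pwm()] object.
#' @export
default_tbox_pwm <- function(p = 0.94) {
  consensus_pwm("CAGGTGTGAA", p = p, motif_id = "synthetic_tbox")
}

#' Synthetic Runt-like PWM (RUNX surrogate)
#' @param p Consensus-base probability (default 0.94).
#' @return A [make_pwm()] object.
#' @export
default_runx_pwm <- function(p = 0.94) {
  consensus_pwm("TGTGGTTT", p = p, motif_id = "synthetic_runx")
}

#' PWM from a consensus string
#' @param consensus DNA string over ACGT.
#' @param p Probability of the consensus base per position.
#' @param motif_id Identifier.
#' @return A [make_pwm()] object.
#' @export
consensus_pwm <- function(consensus, p = 0.94, motif_id = "consensus") {
  bases <- strsplit(toupper(consensus), "")[[1]]
  stopifnot(all(bases %in% c("A", "C", "G", "T")), length(bases) >= 4)
  m <- matrix((1 - p) / 3, nrow = length(bases), ncol = 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  m[cbind(seq_along(bases), match(bases, colnames(m)))] <- p
  make_pwm(m, motif_id = motif_id)
}

#' Simulate motif-bearing sequences
#'
#' IID background at the configured GC content; the motif consensus is
#' embedded (reverse-complemented with probability 0.5) at offsets drawn
#' from Normal(center, `motif_offset_sd`), clipped to the valid range, in a
#' `plant_fraction` of sequences. Sequence length is `2 * seq_window + L -
#' 1`, so a centrally planted motif center sits exactly at the sequence
#' center.
#'
#' @param cfg A [sim_config()].
#' @param pwm A [make_pwm()] object (default [default_tbox_pwm()]).
#' @return List with `sequences` (named character vector) and `truth`
#'   (data.frame: seq_id, planted, offset, strand).
#' @export
simulate_sequences <- function(cfg, pwm = default_tbox_pwm()) {
  with_seed(cfg$seed + 404L, {
    L <- pwm$length
    len <- 2L * cfg$seq_window + L - 1L
    n <- cfg$n_sequences
    gc <- cfg$gc_content
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    cons <- pwm_consensus(pwm)
    center_off <- (len - L) / 2
    seqs <- character(n)
    planted <- stats::runif(n) < cfg$plant_fraction
    offs <- rep(NA_integer_, n)
    strands <- rep(NA_character_, n)
    for (i in seq_len(n)) {
      s <- sample(names(probs), len, replace = TRUE, prob = probs)
      if (planted[i]) {
        o <- round(stats::rnorm(1, center_off, cfg$motif_offset_sd))
        o <- max(0L, min(len - L, o))
        strand <- if (stats::runif(1) < 0.5) "+" else "-"
        ins <- if (strand == "+") cons else revcomp(cons)
        s[(o + 1):(o + L)] <- strsplit(ins, "")[[1]]
        offs[i] <- o
        strands[i] <- strand
      }
      seqs[i] <- paste(s, collapse = "")
    }
    ids <- sprintf("seq_%05d", seq_len(n))
    names(seqs) <- ids
    list(sequences = seqs,
         truth = data.frame(seq_id = ids, planted = planted, offset = offs,
                            strand = strands, stringsAsFactors = FALSE))
  })
}

#' Simulate gene expression tables for the memory comparisons
#'
#' Up/down genes receive log2 fold-changes ~ Normal(+/-2, 0.5) with
#' adjusted p ~ Uniform(0, 0.01); static genes ~ Normal(0, 0.3) with
#' adjusted p ~ Uniform(0.2, 1), so thresholding at q < 0.05 and |lfc| > 1
#' recovers the groups exactly. When EOMES peaks are supplied, up/down
#' genes are preferentially drawn from genes with at least one peak within
#' 100 kb of their TSS (true targets), so target inference has signal to
#' find.
#'
#' @param cfg A [sim_config()].
#' @param tss TSS table from [simulate_annotation()].
#' @param eomes_peaks Optional `GRanges` of factor peaks.
#' @return List with `expression` (data.frame: gene_id, log2fc, q per the
#'   `tm` and `tim` comparisons, long format with a `comparison` column)
#'   and `truth` (data.frame: gene_id, group, true_target).
#' @export
simulate_expression <- function(cfg, tss, eomes_peaks = NULL) {
  with_seed(cfg$seed + 505L, {
    genes <- tss$gene_id
    n <- length(genes)
    stopifnot(cfg$n_up_genes + cfg$n_down_genes < n)
    if (!is.null(eomes_peaks) && length(eomes_peaks) > 0L) {
      rp <- regulatory_potential(tss, eomes_peaks)
      bound <- rp$gene_id[rp$n_peaks_in_window > 0]
      pool_de <- if (length(bound) >= cfg$n_up_genes + cfg$n_down_genes)
        bound else genes
    } else {
      pool_de <- genes
    }
    de <- sample(pool_de, cfg$n_up_genes + cfg$n_down_genes)
    up <- de[seq_len(cfg$n_up_genes)]
    down <- de[cfg$n_up_genes + seq_len(cfg$n_down_genes)]
    group <- ifelse(genes %in% up, "up",
                    ifelse(genes %in% down, "down", "static"))
    # DE effects: Normal(+/-2, 0.5) truncated beyond the |lfc| = 1 calling
    # threshold so the planted groups are identifiable by construction
    rtnorm_above <- function(k, mean, sd, lo) {
      p_lo <- stats::pnorm(lo, mean, sd)
      stats::qnorm(stats::runif(k, p_lo, 1), mean, sd)
    }
    draw <- function(comparison) {
      lfc <- stats::rnorm(n, 0, 0.3)
      lfc[group == "up"] <- rtnorm_above(sum(group == "up"), 2, 0.5, 1 + 1e-6)
      lfc[group == "down"] <- -rtnorm_above(sum(group == "down"), 2, 0.5,
                                            1 + 1e-6)
      q <- ifelse(group == "static", stats::runif(n, 0.2, 1),
                  stats::runif(n, 0, 0.01))
      data.frame(comparison = comparison, gene_id = genes, log2fc = lfc,
                 q = q, stringsAsFactors = FALSE)
    }
    expr <- rbind(draw("tm"), draw("tim"))
    truth <- data.frame(gene_id = genes, group = group,
                        true_target = genes %in% de &
                          !is.null(eomes_peaks),
                        stringsAsFactors = FALSE)
    list(expression = expr, truth = truth)
  })
}

#' Simulate bivariate single-cell intensities with target Kendall tau
#'
#' Gaussian copula with `rho = sin(pi * tau / 2)` (the exact Kendall-Pearson
#' relation for the bivariate normal) and lognormal marginals emulating
#' fluorescence intensities; one group per configured tau target.
#'
#' @param cfg A [sim_config()].
#' @return List with `cells` (data.frame: cell_id, group, marker_a,
#'   marker_b) and `truth` (data.frame: group, tau, n).
#' @export
simulate_cells <- function(cfg) {
  with_seed(cfg$seed + 606L, {
    out <- lapply(names(cfg$tau_targets), function(g) {
      tau <- cfg$tau_targets[[g]]
      rho <- sin(pi * tau / 2)
      n <- cfg$n_cells
      z1 <- stats::rnorm(n)
      z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
      data.frame(cell_id = sprintf("%s_cell_%05d", g, seq_len(n)),
                 group = g,
                 marker_a = stats::qlnorm(stats::pnorm(z1),
                                          cfg$cell_meanlog, cfg$cell_sdlog),
                 marker_b = stats::qlnorm(stats::pnorm(z2),
                                          cfg$cell_meanlog, cfg$cell_sdlog),
                 stringsAsFactors = FALSE)
    })
    list(cells = do.call(rbind, out),
         truth = data.frame(group = names(cfg$tau_targets),
                            tau = as.numeric(cfg$tau_targets),
                            n = cfg$n_cells, stringsAsFactors = FALSE))
  })
}

#' Simulate the complete study
#'
#' Convenience wrapper chaining all generators.
#'
#' @param cfg A [sim_config()].
#' @return List with `annotation`, `landscape`, `count_sets`, `sequences`,
#'   `expression`, `cells` and `config`.
#' @export
simulate_study <- function(cfg = sim_config()) {
  annotation <- simulate_annotation(cfg)
  landscape <- simulate_peak_landscape(cfg, annotation)
  count_sets <- simulate_counts(landscape, cfg)
  sequences <- simulate_sequences(cfg)
  expression <- simulate_expression(cfg, annotation$tss,
                                    eomes_peaks = landscape$peaks$eomes_tim)
  cells <- simulate_cells(cfg)
  list(annotation = annotation, landscape = landscape,
       count_sets = count_sets, sequences = sequences,
       expression = expression, cells = cells, config = cfg)
}
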