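read_tbl <- function(start, end, strand = "+", library = "untreated",
                     count = 1L, chrom = "chr1", length = NULL,
                     first_nt = "U") {
  tibble::tibble(
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    strand = strand, length = length %||% (end - start),
    first_nt = first_nt, library = library, count = as.integer(count)
  )
}

test_that("reads merge within pad and split beyond it", {
  # gaps of 150 vs 250 bp with pad 200
  close_reads <- read_tbl(c(0, 174), c(24, 198), count = c(6, 6))
  far_reads <- read_tbl(c(0, 274), c(24, 298), count = c(6, 6))
  l1 <- call_srna_loci(close_reads, mincov_rpmm = 0)
  l2 <- call_srna_loci(far_reads, mincov_rpmm = 0)
  expect_equal(nrow(l1), 1)
  expect_equal(nrow(l2), 2)
  expect_equal(l1$start, 0L)
  expect_equal(l1$end, 198L)
})

test_that("the RPMM coverage threshold is applied at the boundary", {
  # total 1e6 reads -> threshold at mincov 10 is exactly 10 reads
  filler <- read_tbl(1e5, 1e5 + 24, count = 1e6 - 19, chrom = "chr2")
  island9 <- read_tbl(rep(0, 9), rep(24, 9))
  island10 <- read_tbl(rep(5000, 10), rep(5024, 10))
  loci <- call_srna_loci(dplyr::bind_rows(filler, island9, island10))
  expect_setequal(loci$chrom[loci$chrom == "chr1"], "chr1")
  chr1 <- dplyr::filter(loci, chrom == "chr1")
  expect_equal(nrow(chr1), 1)         # the 9-read island is discarded
  expect_equal(chr1$start, 5000L)
  expect_equal(chr1$total_count, 10)  # exactly at threshold is kept
})

test_that("strandedness is called at the cutoff", {
  reads <- read_tbl(rep(0, 20), rep(24, 20),
                    strand = c(rep("+", 17), rep("-", 3)))
  loci <- call_srna_loci(reads, mincov_rpmm = 0)
  expect_equal(loci$strand_fraction, 0.85)
  expect_true(loci$stranded)
  reads2 <- read_tbl(rep(0, 20), rep(24, 20),
                     strand = c(rep("+", 15), rep("-", 5)))
  expect_false(call_srna_loci(reads2, mincov_rpmm = 0)$stranded)
  # exactly at the cutoff counts as stranded
  reads3 <- read_tbl(rep(0, 20), rep(24, 20),
                     strand = c(rep("+", 16), rep("-", 4)))
  expect_true(call_srna_loci(reads3, mincov_rpmm = 0)$stranded)
})

test_that("dicer_call reflects the modal read length", {
  reads <- dplyr::bind_rows(
    read_tbl(rep(0, 6), rep(24, 6)),            # 24 nt
    read_tbl(rep(30, 4), rep(65, 4))            # 35 nt
  )
  loci <- call_srna_loci(reads, mincov_rpmm = 0)
  expect_equal(loci$major_length, 24)
  expect_true(loci$dicer_call)
  reads_long <- dplyr::bind_rows(
    read_tbl(rep(0, 4), rep(24, 4)),
    read_tbl(rep(30, 6), rep(65, 6))
  )
  expect_false(call_srna_loci(reads_long, mincov_rpmm = 0)$dicer_call)
})

test_that("locus calling is idempotent on its own output", {
  withr::local_seed(37)
  starts <- sort(sample.int(50000, 300))
  reads <- read_tbl(starts, starts + sample(20:26, 300, replace = TRUE),
                    count = sample(1:5, 300, replace = TRUE))
  loci <- call_srna_loci(reads, mincov_rpmm = 0)
  again <- call_srna_loci(
    tibble::tibble(
      chrom = loci$chrom, start = loci$start, end = loci$end,
      strand = loci$strand, length = loci$major_length,
      library = "untreated", count = loci$total_count
    ),
    mincov_rpmm = 0
  )
  expect_equal(again$start, loci$start)
  expect_equal(again$end, loci$end)
  expect_equal(nrow(again), nrow(loci))
})

test_that("per-library counts are split by overlap", {
  reads <- dplyr::bind_rows(
    read_tbl(c(0, 50), c(24, 74), library = "untreated", count = c(2, 3)),
    read_tbl(100, 124, library = "oxidized", count = 7)
  )
  loci <- call_srna_loci(reads, mincov_rpmm = 0)
  expect_equal(nrow(loci), 1)
  expect_equal(loci$count_untreated, 5)
  expect_equal(loci$count_oxidized, 7)
})

test_that("read profiles count length x first nucleotide with T as U", {
  reads <- tibble::tibble(
    chrom = "chr1", start = 0L, end = 24L, strand = "+",
    length = 24L, first_nt = "T", library = "untreated", count = 1L
  )
  prof <- profile_reads(reads, "untreated")
  expect_equal(prof$U[prof$length == 24], 1)
  expect_equal(sum(prof$A + prof$C + prof$G + prof$U), 1)
})

test_that("profile row sums equal a brute-force length histogram", {
  withr::local_seed(43)
  n <- 500
  reads <- tibble::tibble(
    chrom = "chr1", start = 0L, end = 30L, strand = "+",
    length = sample(18:30, n, replace = TRUE),
    first_nt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    library = "untreated", count = sample(1:3, n, replace = TRUE)
  )
  prof <- profile_reads(reads)
  hist <- tapply(reads$count, factor(reads$length, levels = 18:35), sum)
  hist[is.na(hist)] <- 0
  expect_equal(prof$A + prof$C + prof$G + prof$U, unname(as.numeric(hist)))
})

test_that("enrichment flags follow the printed rules", {
  de_ox <- tibble::tibble(
    feature_id = c("l1", "l2", "l3"),
    log2fc = c(2, -3, 0.1), fdr = c(0.001, 1e-4, 0.5)
  )
  de_tr <- tibble::tibble(
    feature_id = c("l1", "l2", "l3"),
    log2fc = c(1.5, 0, 0), fdr = c(0.01, 0.9, 0.9)
  )
  fl <- classify_srna_enrichment(de_ox, de_tr)
  expect_true(fl$dual_enriched[1])
  expect_true(fl$retained[1])
  expect_true(fl$depleted[2])
  expect_false(fl$retained[2])
  # enriched by neither, not depleted -> retained by default
  expect_true(fl$retained[3])
  fl2 <- classify_srna_enrichment(de_ox, de_tr, drop_unenriched = TRUE)
  expect_false(fl2$retained[3])
  expect_error(
    classify_srna_enrichment(de_ox, de_tr[1:2, ]),
    "same loci"
  )
})

test_that("origin assignment follows the TE > expressed-gene > unannotated hierarchy", {
  tes <- tibble::tibble(te_id = c("te1", "te2"), chrom = "chr1",
                        start = c(100L, 1000L), end = c(300L, 1200L))
  genes <- tibble::tibble(gene_id = c("gE", "gN"), chrom = "chr1",
                          start = c(2000L, 3000L), end = c(2500L, 3500L))
  loci <- tibble::tibble(
    locus_id = c("inTE", "inExprGene", "inSilentGene", "nowhere"),
    chrom = "chr1",
    start = c(150L, 2100L, 3100L, 5000L),
    end = c(250L, 2200L, 3200L, 5100L)
  )
  out <- assign_origin(loci, tes, expressed_te_ids = character(0),
                       genes = genes, expressed_gene_ids = "gE")
  expect_equal(as.character(out$origin),
               c("TE_nonexpressed", "genic", "unannotated", "unannotated"))
  expect_equal(attr(out, "n_nonexpressed_gene_overlap"), 1L)
})

test_that("conflicting TE overlaps resolve by larger overlap, ties to expressed", {
  tes <- tibble::tibble(te_id = c("big", "small"), chrom = "chr1",
                        start = c(100L, 260L), end = c(280L, 400L))
  loci <- tibble::tibble(locus_id = "l", chrom = "chr1",
                         start = 200L, end = 300L)
  # overlap with big = 80, small = 40 -> big wins even though small is expressed
  out <- assign_origin(loci, tes, expressed_te_ids = "small",
                       genes = tibble::tibble(gene_id = character(),
                                              chrom = character(),
                                              start = integer(), end = integer()),
                       expressed_gene_ids = character(0))
  expect_equal(out$host_te_id, "big")
  expect_equal(as.character(out$origin), "TE_nonexpressed")

  # exact tie -> expressed wins
  tes2 <- tibble::tibble(te_id = c("a", "b"), chrom = "chr1",
                         start = c(150L, 250L), end = c(250L, 350L))
  loci2 <- tibble::tibble(locus_id = "l", chrom = "chr1",
                          start = 200L, end = 300L)
  out2 <- assign_origin(loci2, tes2, expressed_te_ids = "b",
                        genes = tibble::tibble(gene_id = character(),
                                               chrom = character(),
                                               start = integer(), end = integer()),
                        expressed_gene_ids = character(0))
  expect_equal(out2$host_te_id, "b")
  expect_equal(as.character(out2$origin), "TE_expressed")
})

test_that("planted origins are recovered exactly on synthetic truth loci", {
  cfg <- small_config(seed = 11)
  sim <- generate_genome(cfg)
  srna <- withr::with_seed(cfg$seed + 2L,
                           mycoTE:::generate_srna_impl(sim, cfg))
  truth <- dplyr::filter(srna$locus_truth, !is_mito)
  out <- assign_origin(
    dplyr::select(truth, locus_id, chrom, start, end),
    sim$tes,
    expressed_te_ids = sim$truth$te$te_id[sim$truth$te$expressed],
    genes = sim$genes,
    expressed_gene_ids = sim$truth$gene$gene_id[sim$truth$gene$expressed]
  )
  expect_equal(as.character(out$origin), truth$origin)
})

test_that("shuffling is seed-deterministic and preserves the length multiset", {
  withr::local_seed(3)
  loci <- random_intervals(40, max_pos = 8000, prefix = "s") |>
    dplyr::rename(locus_id = id)
  tes <- random_intervals(20, max_pos = 9000, prefix = "t") |>
    dplyr::rename(te_id = id)
  gl <- tibble::tibble(chrom = c("chr1", "chr2"), length = c(20000L, 15000L))
  r1 <- shuffle_null_distance(loci, tes, gl, seed = 99)
  r2 <- shuffle_null_distance(loci, tes, gl, seed = 99)
  expect_identical(r1$shuffled_loci, r2$shuffled_loci)
  expect_equal(sort(r1$shuffled_loci$end - r1$shuffled_loci$start),
               sort(loci$end - loci$start))
  expect_true(all(r1$shuffled_loci$start >= 0))
  lens <- gl$length[match(r1$shuffled_loci$chrom, gl$chrom)]
  expect_true(all(r1$shuffled_loci$end <= lens))
  expect_error(
    shuffle_null_distance(
      tibble::tibble(locus_id = "x", chrom = "chr1", start = 0L, end = 50000L),
      tes, gl
    ),
    "longer than every chromosome"
  )
})

test_that("loci planted inside TEs are detected as closer than shuffled", {
  withr::local_seed(8)
  tes <- tibble::tibble(
    te_id = sprintf("t%d", 1:30), chrom = "chr1",
    start = seq(0L, 290000L, by = 10000L),
    end = seq(0L, 290000L, by = 10000L) + 800L
  )
  loci <- tibble::tibble(
    locus_id = sprintf("s%d", 1:30), chrom = "chr1",
    start = tes$start + 100L, end = tes$start + 300L
  )
  gl <- tibble::tibble(chrom = "chr1", length = 300000L)
  res <- shuffle_null_distance(loci, tes, gl, seed = 1)
  expect_equal(res$test$median_observed, 0)
  expect_lt(res$test$p, 0.01)
  expect_gt(res$test$median_shuffled, 0)
})

test_that("per-superfamily sRNA production matches a brute-force overlap scan", {
  tes <- tibble::tibble(
    te_id = sprintf("t%d", 1:8), chrom = "chr1",
    start = seq(0L, 7000L, by = 1000L),
    end = seq(0L, 7000L, by = 1000L) + 500L,
    superfamily = "LTR/Gypsy", k = 0.05
  )
  loci <- tibble::tibble(locus_id = "l", chrom = "chr1",
                         start = 100L, end = 200L)
  prod <- te_srna_production(loci, tes)
  expect_equal(prod$superfamily$pct_producing, 12.5)
  expect_equal(prod$superfamily$n_producing, 1L)
  expect_equal(prod$bins$kimura_bin, 5L)

  none <- te_srna_production(
    tibble::tibble(locus_id = character(), chrom = character(),
                   start = integer(), end = integer()),
    tes
  )
  expect_equal(none$superfamily$n_producing, 0L)
  expect_equal(none$superfamily$pct_producing, 0)

  withr::local_seed(21)
  loci_r <- random_intervals(50, chroms = "chr1", max_pos = 8000,
                             prefix = "s") |> dplyr::rename(locus_id = id)
  prod_r <- te_srna_production(loci_r, tes)
  bf <- vapply(seq_len(nrow(tes)), function(i) {
    any(loci_r$start < tes$end[i] & loci_r$end > tes$start[i])
  }, logical(1))
  expect_equal(prod_r$superfamily$n_producing, sum(bf))
})
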