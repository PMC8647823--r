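make_records <- function(...) {
  tibble::tibble(...)
}

test_that("symmetric CpG records merge by coverage-weighted mean", {
  rec <- make_records(
    chrom = "chr1", pos = c(100L, 101L), strand = c("+", "-"),
    meth_freq = c(0.8, 0.6), coverage = c(10L, 30L)
  )
  m <- merge_symmetric_cg(rec)
  expect_equal(nrow(m), 1)
  expect_equal(m$pos, 100L)
  expect_equal(m$meth_freq, 0.65)
  expect_equal(m$coverage, 40L)

  eq <- merge_symmetric_cg(make_records(
    chrom = "chr1", pos = c(10L, 11L), strand = c("+", "-"),
    meth_freq = c(0.2, 0.4), coverage = c(5L, 5L)
  ))
  expect_equal(eq$meth_freq, 0.3)
})

test_that("singleton records pass through; minus singletons map to the plus C", {
  plus_only <- merge_symmetric_cg(make_records(
    chrom = "chr1", pos = 50L, strand = "+", meth_freq = 0.9, coverage = 5L
  ))
  expect_equal(plus_only$pos, 50L)
  expect_equal(plus_only$meth_freq, 0.9)
  expect_equal(plus_only$n_strands, 1L)

  minus_only <- merge_symmetric_cg(make_records(
    chrom = "chr1", pos = 51L, strand = "-", meth_freq = 0.7, coverage = 8L
  ))
  expect_equal(minus_only$pos, 50L)
})

test_that("duplicate strand records at one position are rejected", {
  expect_error(
    merge_symmetric_cg(make_records(
      chrom = "chr1", pos = c(10L, 10L), strand = c("+", "+"),
      meth_freq = c(0.1, 0.2), coverage = c(3L, 4L)
    )),
    "duplicate"
  )
})

test_that("merging conserves total methylated-read mass", {
  withr::local_seed(3)
  pos <- sort(sample.int(10000, 200)) * 2L
  rec <- dplyr::bind_rows(
    make_records(chrom = "chr1", pos = pos, strand = "+",
                 meth_freq = runif(200), coverage = sample.int(50, 200, replace = TRUE)),
    make_records(chrom = "chr1", pos = pos + 1L, strand = "-",
                 meth_freq = runif(200), coverage = sample.int(50, 200, replace = TRUE))
  )
  m <- merge_symmetric_cg(rec)
  expect_equal(sum(m$meth_freq * m$coverage),
               sum(rec$meth_freq * rec$coverage))
  expect_equal(nrow(m), 200)
})

test_that("locus scores are medians with the even-count mean rule", {
  sites <- tibble::tibble(
    chrom = "chr1", pos = c(10L, 20L, 30L, 100L, 110L),
    meth_freq = c(0.1, 0.9, 0.95, 0.2, 0.8)
  )
  loci <- tibble::tibble(
    locus_id = c("odd", "even", "empty"),
    chrom = "chr1", start = c(0L, 95L, 500L), end = c(50L, 150L, 600L)
  )
  s <- score_loci(sites, loci)
  expect_equal(s$mcg_score[1], 0.9)
  expect_equal(s$mcg_score[2], 0.5)
  expect_true(is.na(s$mcg_score[3]))
  expect_false(s$defined[3])
  expect_error(
    score_loci(sites, tibble::tibble(locus_id = "bad", chrom = "chr1",
                                     start = 10L, end = 10L)),
    "malformed"
  )
})

test_that("half-open interval excludes a site exactly at the locus end", {
  sites <- tibble::tibble(chrom = "chr1", pos = c(99L, 100L), meth_freq = c(0.2, 0.9))
  s <- score_loci(sites, tibble::tibble(locus_id = "l", chrom = "chr1",
                                        start = 50L, end = 100L))
  expect_equal(s$n_sites, 1L)
  expect_equal(s$mcg_score, 0.2)
})

test_that("score_loci matches the sort-based median oracle on random loci", {
  withr::local_seed(17)
  sites <- tibble::tibble(
    chrom = sample(c("chr1", "chr2"), 3000, replace = TRUE),
    pos = sample.int(50000, 3000),
    meth_freq = runif(3000)
  ) |> dplyr::distinct(chrom, pos, .keep_all = TRUE)
  loci <- random_intervals(1000, max_pos = 50000, max_len = 800, prefix = "loc") |>
    dplyr::rename(locus_id = id)
  s <- score_loci(sites, loci)
  for (i in sample.int(nrow(loci), 60)) {
    inside <- sites$chrom == loci$chrom[i] &
      sites$pos >= loci$start[i] & sites$pos < loci$end[i]
    expect_equal(s$mcg_score[i], oracle_median(sites$meth_freq[inside]),
                 info = loci$locus_id[i])
    expect_equal(s$n_sites[i], sum(inside))
  }
})

test_that("site classification uses strict thresholds and sums to one", {
  sites <- tibble::tibble(meth_freq = c(0.9, 0.1, 0.5))
  f <- classify_sites(sites)
  expect_equal(unlist(f[1, 1:3], use.names = FALSE), c(1, 1, 1) / 3)

  boundary <- classify_sites(tibble::tibble(meth_freq = rep(0.8, 4)))
  expect_equal(boundary$frac_high, 0)
  expect_equal(boundary$frac_intermediate, 1)

  expect_error(classify_sites(tibble::tibble(meth_freq = numeric())), "no sites")
  expect_error(classify_sites(sites, hi = 0.2, lo = 0.8), "greater")

  withr::local_seed(2)
  rnd <- classify_sites(tibble::tibble(meth_freq = runif(500)))
  expect_equal(rnd$frac_high + rnd$frac_low + rnd$frac_intermediate, 1)
})

test_that("metagene profile is flat for a constant methylation field", {
  sites <- tibble::tibble(chrom = "chr1", pos = 0:9999, meth_freq = 0.7)
  loci <- tibble::tibble(locus_id = "l1", chrom = "chr1",
                         start = 4000L, end = 6000L, strand = "+")
  prof <- metagene_profile(loci, sites)
  body <- dplyr::filter(prof, segment == "body")
  expect_true(all(body$mean_mcg == 0.7))
  expect_true(all(dplyr::filter(prof, segment == "upstream")$mean_mcg == 0.7))
})

test_that("a site at the start of a plus-strand locus lands in body bin 0", {
  sites <- tibble::tibble(chrom = "chr1", pos = 1000L, meth_freq = 0.4)
  loci <- tibble::tibble(locus_id = "l", chrom = "chr1",
                         start = 1000L, end = 2000L, strand = "+")
  prof <- metagene_profile(loci, sites)
  hit <- dplyr::filter(prof, n > 0)
  expect_equal(hit$segment, factor("body", levels = levels(prof$segment)))
  expect_equal(hit$bin, 0L)

  # for a minus-strand locus the same site is the 3' end: last body bin
  prof_m <- metagene_profile(
    dplyr::mutate(loci, strand = "-"), sites
  )
  hit_m <- dplyr::filter(prof_m, n > 0)
  expect_equal(hit_m$bin, 49L)
})

test_that("metagene profile equals brute-force per-bin averaging", {
  withr::local_seed(23)
  sites <- tibble::tibble(
    chrom = "chr1", pos = sort(sample.int(30000, 4000)),
    meth_freq = runif(4000)
  )
  loci <- tibble::tibble(
    locus_id = c("a", "b"), chrom = "chr1",
    start = c(5000L, 16000L), end = c(8000L, 17500L),
    strand = c("+", "-")
  )
  flank <- 2000L; body_bins <- 50L; flank_bin <- 100L
  prof <- metagene_profile(loci, sites, flank, body_bins, flank_bin)

  # brute force: per site per locus, compute segment/bin directly
  acc <- list()
  for (i in 1:2) {
    s <- loci$start[i]; e <- loci$end[i]; minus <- loci$strand[i] == "-"
    for (j in seq_len(nrow(sites))) {
      p <- sites$pos[j]
      if (p >= s && p < e) {
        rel <- if (minus) (e - 1 - p) else p - s
        acc[[length(acc) + 1]] <- c(seg = "body",
                                    bin = min(floor(body_bins * rel / (e - s)),
                                              body_bins - 1),
                                    f = sites$meth_freq[j])
      } else if (p < s && s - p <= flank) {
        off <- s - 1 - p
        bin <- if (minus) off %/% flank_bin else (flank %/% flank_bin) - 1 - off %/% flank_bin
        acc[[length(acc) + 1]] <- c(seg = if (minus) "downstream" else "upstream",
                                    bin = bin, f = sites$meth_freq[j])
      } else if (p >= e && p - e < flank) {
        off <- p - e
        bin <- if (minus) (flank %/% flank_bin) - 1 - off %/% flank_bin else off %/% flank_bin
        acc[[length(acc) + 1]] <- c(seg = if (minus) "upstream" else "downstream",
                                    bin = bin, f = sites$meth_freq[j])
      }
    }
  }
  bf <- tibble::tibble(
    segment = vapply(acc, `[[`, character(1), "seg"),
    bin = as.integer(vapply(acc, `[[`, character(1), "bin")),
    f = as.numeric(vapply(acc, `[[`, character(1), "f"))
  ) |>
    dplyr::group_by(segment, bin) |>
    dplyr::summarise(mean_mcg = mean(f), n = dplyr::n(), .groups = "drop")
  cmp <- dplyr::inner_join(
    dplyr::mutate(prof, segment = as.character(segment)),
    bf, by = c("segment", "bin"), suffix = c("", "_bf")
  )
  expect_gt(nrow(cmp), 50)
  expect_equal(cmp$mean_mcg, cmp$mean_mcg_bf)
  expect_equal(cmp$n, cmp$n_bf)
  # bins absent from the brute-force table saw no sites
  rest <- dplyr::anti_join(
    dplyr::mutate(prof, segment = as.character(segment)),
    bf, by = c("segment", "bin")
  )
  expect_true(all(rest$n == 0))
})

test_that("gene methylation labels use a strict threshold and reject NA", {
  sc <- tibble::tibble(locus_id = c("g1", "g2"), mcg_score = c(0.9, 0.5))
  out <- classify_gene_methylation(sc)
  expect_equal(as.character(out$methylation_class), c("high", "low"))
  expect_error(
    classify_gene_methylation(tibble::tibble(mcg_score = NA_real_)),
    "undefined"
  )
})
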