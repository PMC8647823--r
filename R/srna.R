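#' Call small RNA loci from pooled aligned reads
#'
#' A simplified island-based sRNA locus caller driven by the printed
#' clustering parameters: reads from all libraries are pooled, intervals
#' whose gap is at most `pad` bp are merged into islands, and islands whose
#' pooled read count falls below `mincov_rpmm` reads-per-million-mapped
#' (converted to an absolute threshold using the pooled total) are
#' discarded. Each locus records its majority-strand share (stranded iff
#' `>= strand_cutoff`), its modal read length weighted by count
#' (`dicer_call` iff within `[dicermin, dicermax]`, the range of Dicer
#' products), and per-library counts. Secondary-structure (fold-size)
#' analysis of the published clusterer is deliberately not performed.
#'
#' @param reads A data frame with `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `library` and `count`; `length` defaults to
#'   `end - start`.
#' @param pad Maximum merge gap in bp (default 200).
#' @param mincov_rpmm Minimum pooled coverage in reads per million mapped
#'   (default 10).
#' @param dicermin,dicermax Dicer product length range (defaults 20, 27).
#' @param strand_cutoff Majority-strand share needed to call a locus
#'   stranded (default 0.8).
#'
#' @return A tibble with one row per retained locus: `locus_id`, `chrom`,
#'   `start`, `end`, `n_reads`, `total_count`, one `count_<library>` column
#'   per library, `strand_fraction`, `strand`, `stranded`, `major_length`,
#'   `dicer_call`. Re-clustering the returned intervals is a no-op
#'   (islands are separated by more than `pad`).
#' @export
call_srna_loci <- function(reads, pad = 200L, mincov_rpmm = 10,
                           dicermin = 20L, dicermax = 27L,
                           strand_cutoff = 0.8) {
  check_columns(reads, c("chrom", "start", "end", "strand", "library", "count"))
  check_intervals(reads)
  if (any(reads$count < 1)) rlang::abort("`count` must be >= 1")
  total <- sum(reads$count)
  if (total == 0) rlang::abort("total mapped reads is zero")
  min_count <- mincov_rpmm * total / 1e6
  if (!"length" %in% names(reads)) {
    reads <- dplyr::mutate(reads, length = .data$end - .data$start)
  }

  clustered <- reads |>
    dplyr::arrange(.data$chrom, .data$start, .data$end) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(
      run_end = cummax(.data$end),
      new_island = dplyr::row_number() == 1 |
        .data$start - dplyr::lag(.data$run_end, default = 0L) > pad,
      island = cumsum(.data$new_island)
    ) |>
    dplyr::ungroup()

  loci <- clustered |>
    dplyr::group_by(.data$chrom, .data$island) |>
    dplyr::summarise(
      start = min(.data$start),
      end = max(.data$end),
      n_reads = dplyr::n(),
      total_count = sum(.data$count),
      plus = sum(.data$count[.data$strand == "+"]),
      major_length = weighted_mode(.data$length, .data$count),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$total_count >= min_count) |>
    dplyr::mutate(
      strand_fraction = pmax(.data$plus, .data$total_count - .data$plus) /
        .data$total_count,
      strand = dplyr::if_else(.data$plus >= .data$total_count - .data$plus, "+", "-"),
      stranded = .data$strand_fraction >= strand_cutoff,
      dicer_call = .data$major_length >= dicermin & .data$major_length <= dicermax,
      locus_id = sprintf("%s:%d-%d", .data$chrom, .data$start, .data$end)
    )

  lib_counts <- clustered |>
    dplyr::group_by(.data$chrom, .data$island, .data$library) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    tidyr::pivot_wider(
      names_from = "library", values_from = "count",
      names_prefix = "count_", values_fill = 0
    )

  loci |>
    dplyr::left_join(lib_counts, by = c("chrom", "island")) |>
    dplyr::select(
      "locus_id", "chrom", "start", "end", "n_reads", "total_count",
      dplyr::starts_with("count_"), "strand_fraction", "strand",
      "stranded", "major_length", "dicer_call"
    ) |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Read length x first-nucleotide profile
#'
#' Tabulates read counts by read length and 5' nucleotide (T reported as
#' U), the standard diagnostic for Dicer processing (length peak) and
#' Argonaute sorting (5' U/A bias).
#'
#' @param reads A read table with `length` (or `start`/`end`), `first_nt`
#'   and `count`; optionally filtered to one `library`.
#' @param library Optional library label to filter on.
#' @param length_range Lengths tabulated (default 18:35; reads outside are
#'   dropped).
#' @return A tibble `(length, A, C, G, U)` of summed counts covering the
#'   whole `length_range`; row sums are reads per length.
#' @export
profile_reads <- function(reads, library = NULL, length_range = 18:35) {
  check_columns(reads, c("first_nt", "count"))
  r <- tibble::as_tibble(reads)
  if (!is.null(library)) {
    check_columns(r, "library")
    r <- dplyr::filter(r, .data$library == !!library)
  }
  if (!"length" %in% names(r)) {
    check_columns(r, c("start", "end"))
    r <- dplyr::mutate(r, length = .data$end - .data$start)
  }
  r <- r |>
    dplyr::mutate(
      first_nt = toupper(.data$first_nt),
      first_nt = dplyr::if_else(.data$first_nt == "T", "U", .data$first_nt)
    ) |>
    dplyr::filter(.data$length %in% length_range, .data$first_nt %in% c("A", "C", "G", "U"))
  r |>
    dplyr::group_by(.data$length, .data$first_nt) |>
    dplyr::summarise(n = sum(.data$count), .groups = "drop") |>
    tidyr::complete(
      length = as.integer(length_range),
      first_nt = c("A", "C", "G", "U"),
      fill = list(n = 0)
    ) |>
    tidyr::pivot_wider(names_from = "first_nt", values_from = "n") |>
    dplyr::arrange(.data$length)
}

#' Classify sRNA loci by treatment enrichment
#'
#' Combines per-locus differential results for the two sRNA-stabilisation
#' assays — periodate (NaIO4) oxidation, which spares 2'-O-methylated
#' sRNAs, and TraPR purification of Argonaute-loaded sRNAs — each compared
#' against the untreated library. A locus is enriched in a treatment iff
#' `log2fc > lfc_threshold` and `fdr < fdr_threshold` there, and depleted
#' iff `log2fc < -lfc_threshold` with `fdr < fdr_threshold` in either
#' treatment. By default the retained set drops only depleted loci;
#' `drop_unenriched = TRUE` additionally drops loci enriched by neither
#' treatment.
#'
#' @param de_oxidized,de_trapr Differential results (`feature_id`,
#'   `log2fc`, `fdr`) for oxidized-vs-untreated and trapr-vs-untreated over
#'   the same loci.
#' @param lfc_threshold Fold-change threshold (default 0: any significant
#'   increase counts as enrichment).
#' @param fdr_threshold FDR threshold (default 0.05).
#' @param drop_unenriched See above (default `FALSE`).
#' @return A tibble `(feature_id, oxidized_enriched, trapr_enriched,
#'   dual_enriched, depleted, retained)`.
#' @export
classify_srna_enrichment <- function(de_oxidized, de_trapr, lfc_threshold = 0,
                                     fdr_threshold = 0.05,
                                     drop_unenriched = FALSE) {
  check_columns(de_oxidized, c("feature_id", "log2fc", "fdr"))
  check_columns(de_trapr, c("feature_id", "log2fc", "fdr"))
  if (!setequal(de_oxidized$feature_id, de_trapr$feature_id) ||
      nrow(de_oxidized) != nrow(de_trapr)) {
    rlang::abort("the two comparisons must cover the same loci")
  }
  ox <- tibble::as_tibble(de_oxidized)
  tr <- tibble::as_tibble(de_trapr)[match(de_oxidized$feature_id, de_trapr$feature_id), ]
  out <- tibble::tibble(
    feature_id = ox$feature_id,
    oxidized_enriched = ox$log2fc > lfc_threshold & ox$fdr < fdr_threshold,
    trapr_enriched = tr$log2fc > lfc_threshold & tr$fdr < fdr_threshold,
    depleted = (ox$log2fc < -lfc_threshold & ox$fdr < fdr_threshold) |
      (tr$log2fc < -lfc_threshold & tr$fdr < fdr_threshold)
  )
  out$dual_enriched <- out$oxidized_enriched & out$trapr_enriched
  out$retained <- if (drop_unenriched) {
    (out$oxidized_enriched | out$trapr_enriched) & !out$depleted
  } else {
    !out$depleted
  }
  out
}

#' Assign the genomic origin of sRNA loci
#'
#' Hierarchical origin assignment: a locus overlapping (>= 1 bp) a
#' classified TE copy is `TE_expressed` or `TE_nonexpressed` according to
#' that copy's expression flag (on multiple TE overlaps the larger overlap
#' wins; exact ties go to the expressed copy); otherwise a locus
#' overlapping an expressed gene is `genic`; everything else is
#' `unannotated`. Overlaps with non-expressed genes deliberately fall
#' through to `unannotated` (counted in the `n_nonexpressed_gene_overlap`
#' attribute).
#'
#' @param loci sRNA loci (`locus_id`, `chrom`, `start`, `end`).
#' @param tes Classified TE copies (`te_id`, `chrom`, `start`, `end`).
#' @param expressed_te_ids Character vector of expressed TE copy ids.
#' @param genes Gene intervals (`gene_id`, `chrom`, `start`, `end`).
#' @param expressed_gene_ids Character vector of expressed gene ids.
#' @return The locus tibble with `origin` (factor: `TE_expressed`,
#'   `TE_nonexpressed`, `genic`, `unannotated`), `host_te_id` and
#'   `host_gene_id` columns.
#' @export
assign_origin <- function(loci, tes, expressed_te_ids, genes,
                          expressed_gene_ids) {
  check_intervals(loci); check_columns(loci, "locus_id")
  check_intervals(tes); check_columns(tes, "te_id")
  check_intervals(genes); check_columns(genes, "gene_id")

  n <- nrow(loci)
  origin <- rep("unannotated", n)
  host_te <- rep(NA_character_, n)
  host_gene <- rep(NA_character_, n)

  hits <- GenomicRanges::findOverlaps(as_granges0(loci), as_granges0(tes))
  if (length(hits) > 0) {
    ov <- tibble::tibble(
      li = S4Vectors::queryHits(hits),
      ti = S4Vectors::subjectHits(hits),
      width = IRanges::width(IRanges::pintersect(
        IRanges::IRanges(loci$start[S4Vectors::queryHits(hits)] + 1L,
                         loci$end[S4Vectors::queryHits(hits)]),
        IRanges::IRanges(tes$start[S4Vectors::subjectHits(hits)] + 1L,
                         tes$end[S4Vectors::subjectHits(hits)])
      ))
    ) |>
      dplyr::mutate(expressed = tes$te_id[.data$ti] %in% expressed_te_ids) |>
      dplyr::group_by(.data$li) |>
      # larger overlap wins; exact tie -> expressed copy
      dplyr::arrange(dplyr::desc(.data$width), dplyr::desc(.data$expressed),
                     .by_group = TRUE) |>
      dplyr::slice(1) |>
      dplyr::ungroup()
    origin[ov$li] <- ifelse(ov$expressed, "TE_expressed", "TE_nonexpressed")
    host_te[ov$li] <- tes$te_id[ov$ti]
  }

  open <- origin == "unannotated"
  ghits <- GenomicRanges::findOverlaps(as_granges0(loci), as_granges0(genes))
  gli <- S4Vectors::queryHits(ghits)
  ggi <- S4Vectors::subjectHits(ghits)
  g_expr <- genes$gene_id[ggi] %in% expressed_gene_ids
  n_nonexpr <- length(unique(gli[open[gli] & !g_expr]))
  keep <- open[gli] & g_expr
  if (any(keep)) {
    first <- !duplicated(gli[keep])
    origin[gli[keep][first]] <- "genic"
    host_gene[gli[keep][first]] <- genes$gene_id[ggi[keep][first]]
  }

  out <- dplyr::mutate(
    tibble::as_tibble(loci),
    origin = factor(origin, levels = c(
      "TE_expressed", "TE_nonexpressed", "genic", "unannotated"
    )),
    host_te_id = host_te,
    host_gene_id = host_gene
  )
  attr(out, "n_nonexpressed_gene_overlap") <- n_nonexpr
  out
}

#' Shuffled-locus null for sRNA-to-TE distances
#'
#' Tests whether sRNA loci sit closer to TEs than expected by chance. Each
#' locus is re-placed uniformly at random `n_sets` times — chromosome drawn
#' with probability proportional to length (among chromosomes the locus
#' fits on), start uniform so the locus fits, length preserved — and the
#' distance to the nearest TE is compared between observed and shuffled
#' loci with a Kruskal-Wallis H test.
#'
#' @param loci sRNA loci (`locus_id`, `chrom`, `start`, `end`).
#' @param tes TE copies (`te_id`, `chrom`, `start`, `end`).
#' @param genome_lengths A tibble `(chrom, length)` for the assembly.
#' @param n_sets Number of shuffle sets (default 1).
#' @param seed Optional integer; fixes the shuffle for reproducibility.
#' @return An object of class `mycote_shuffle_null` with elements
#'   `observed` and `shuffled` (distance tibbles) and `test`; [tidy()]
#'   returns the pooled distance table, [glance()] the test summary.
#' @export
shuffle_null_distance <- function(loci, tes, genome_lengths, n_sets = 1L,
                                  seed = NULL) {
  check_intervals(loci); check_columns(loci, "locus_id")
  check_intervals(tes); check_columns(tes, "te_id")
  check_columns(genome_lengths, c("chrom", "length"))
  widths <- loci$end - loci$start
  if (any(max(genome_lengths$length) < widths)) {
    rlang::abort("a locus is longer than every chromosome")
  }

  shuffle_once <- function() {
    chrom <- character(nrow(loci))
    start <- integer(nrow(loci))
    for (i in seq_len(nrow(loci))) {
      fits <- genome_lengths$length >= widths[i]
      pr <- genome_lengths$length * fits
      ci <- sample.int(nrow(genome_lengths), 1, prob = pr)
      chrom[i] <- genome_lengths$chrom[ci]
      start[i] <- floor(stats::runif(1, 0, genome_lengths$length[ci] - widths[i] + 1))
    }
    tibble::tibble(
      locus_id = loci$locus_id, chrom = chrom,
      start = start, end = start + widths
    )
  }
  do_shuffles <- function() {
    purrr::map(seq_len(n_sets), function(s) {
      dplyr::mutate(shuffle_once(), set = s)
    }) |> dplyr::bind_rows()
  }
  shuffled <- if (is.null(seed)) do_shuffles() else withr::with_seed(seed, do_shuffles())

  dist_of <- function(x) {
    nt <- nearest_te(
      dplyr::rename(x, gene_id = "locus_id"), tes
    )
    tibble::tibble(locus_id = nt$gene_id, distance = nt$distance)
  }
  obs_d <- dist_of(loci)
  shuf_d <- dist_of(shuffled)
  kw <- kw_h_test(list(
    obs_d$distance[!is.na(obs_d$distance)],
    shuf_d$distance[!is.na(shuf_d$distance)]
  ))
  structure(
    list(
      observed = obs_d,
      shuffled = dplyr::mutate(shuf_d, set = shuffled$set),
      shuffled_loci = shuffled,
      test = tibble::tibble(
        statistic = kw$statistic, p = kw$p,
        n_observed = sum(!is.na(obs_d$distance)),
        n_shuffled = sum(!is.na(shuf_d$distance)),
        median_observed = stats::median(obs_d$distance, na.rm = TRUE),
        median_shuffled = stats::median(shuf_d$distance, na.rm = TRUE)
      )
    ),
    class = "mycote_shuffle_null"
  )
}

#' @export
print.mycote_shuffle_null <- function(x, ...) {
  cat(sprintf(
    "Shuffled-locus null: H = %.3f, p = %.3g\n  observed median distance %.0f bp (n = %d); shuffled %.0f bp (n = %d)\n",
    x$test$statistic, x$test$p, x$test$median_observed, x$test$n_observed,
    x$test$median_shuffled, x$test$n_shuffled
  ))
  invisible(x)
}

#' Per-superfamily sRNA production by TE copies
#'
#' Summarises which TE copies produce sRNA: a copy produces sRNA iff at
#' least one retained sRNA locus overlaps it. Reports, per superfamily,
#' the number of overlapping sRNA loci, the fraction of copies producing
#' sRNA, and (when a `k` column is present on `tes`) the breakdown of
#' sRNA-producing copies by Kimura divergence bin.
#'
#' @param loci Retained sRNA loci (`chrom`, `start`, `end`).
#' @param tes TE copies (`te_id`, `chrom`, `start`, `end`, `superfamily`,
#'   optionally `k`).
#' @param max_bin Kimura bins run 0..`max_bin` (default 40).
#' @return A list with `superfamily` — tibble `(superfamily, n_copies,
#'   n_producing, pct_producing, n_srna_loci)` — and `bins` — tibble
#'   `(superfamily, kimura_bin, n_loci)` (empty when `k` is absent).
#' @export
te_srna_production <- function(loci, tes, max_bin = 40L) {
  check_intervals(tes); check_columns(tes, c("te_id", "superfamily"))
  produces <- rep(FALSE, nrow(tes))
  n_loci_per_te <- rep(0L, nrow(tes))
  if (nrow(loci) > 0) {
    check_intervals(loci)
    hits <- GenomicRanges::findOverlaps(as_granges0(tes), as_granges0(loci))
    tab <- table(factor(S4Vectors::queryHits(hits), levels = seq_len(nrow(tes))))
    n_loci_per_te <- as.integer(tab)
    produces <- n_loci_per_te > 0
  }
  te_tbl <- dplyr::mutate(
    tibble::as_tibble(tes),
    produces = produces, n_loci = n_loci_per_te
  )
  superfam <- te_tbl |>
    dplyr::group_by(.data$superfamily) |>
    dplyr::summarise(
      n_copies = dplyr::n(),
      n_producing = sum(.data$produces),
      pct_producing = 100 * sum(.data$produces) / dplyr::n(),
      n_srna_loci = sum(.data$n_loci),
      .groups = "drop"
    )
  bins <- if ("k" %in% names(te_tbl)) {
    te_tbl |>
      dplyr::filter(.data$produces, !is.na(.data$k)) |>
      dplyr::mutate(
        kimura_bin = pmin(pmax(floor(100 * .data$k), 0L), max_bin)
      ) |>
      dplyr::group_by(.data$superfamily, .data$kimura_bin) |>
      dplyr::summarise(n_loci = sum(.data$n_loci), .groups = "drop")
  } else {
    tibble::tibble(
      superfamily = character(), kimura_bin = integer(), n_loci = integer()
    )
  }
  list(superfamily = superfam, bins = bins)
}
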