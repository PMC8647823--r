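#' Merge symmetric CpG methylation calls
#'
#' CpG methylation is symmetric: the cytosines on the plus and minus strand
#' of one CpG dinucleotide report the same underlying methylation state.
#' This merges the two strand records of each CpG into a single site keyed
#' by the 0-based position of the plus-strand C. The merged frequency is the
#' coverage-weighted mean of the strand frequencies and coverages are
#' summed; records without a partner pass through unchanged.
#'
#' @param records A data frame of per-cytosine calls with columns `chrom`,
#'   `pos` (0-based), `strand` (`"+"`/`"-"`), `meth_freq` in `[0, 1]` and
#'   `coverage` (reads, >= 1). A minus-strand record at position `p` is the
#'   partner of a plus-strand record at `p - 1`.
#'
#' @return A tibble of merged sites `(chrom, pos, meth_freq, coverage,
#'   n_strands)` sorted by position; `pos` is always the plus-strand C.
#'   Merging conserves the methylated-read mass: `sum(meth_freq * coverage)`
#'   is unchanged.
#' @export
merge_symmetric_cg <- function(records) {
  check_columns(records, c("chrom", "pos", "strand", "meth_freq", "coverage"))
  if (any(records$meth_freq < 0 | records$meth_freq > 1)) {
    rlang::abort("`meth_freq` must lie in [0, 1]")
  }
  if (any(records$coverage < 1)) {
    rlang::abort("`coverage` must be >= 1")
  }
  if (!all(records$strand %in% c("+", "-"))) {
    rlang::abort("`strand` must be '+' or '-'")
  }
  dup <- records |>
    dplyr::count(.data$chrom, .data$pos, .data$strand) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    rlang::abort(sprintf(
      "duplicate records at %s:%d (%s): one record per cytosine expected",
      dup$chrom[1], dup$pos[1], dup$strand[1]
    ))
  }

  records |>
    dplyr::mutate(
      site_pos = dplyr::if_else(.data$strand == "-", .data$pos - 1L, .data$pos)
    ) |>
    dplyr::group_by(.data$chrom, pos = .data$site_pos) |>
    dplyr::summarise(
      meth_freq = sum(.data$meth_freq * .data$coverage) / sum(.data$coverage),
      coverage = sum(.data$coverage),
      n_strands = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$chrom, .data$pos)
}

#' Score per-locus CpG methylation (mCG score)
#'
#' The mCG score of an interval is the median of the merged per-site
#' methylation frequencies falling inside it (the `bedtools map -median`
#' convention). Intervals are 0-based half-open; a site exactly at the
#' interval end is excluded. An interval with no sites is flagged
#' `defined = FALSE` (`mcg_score = NA`) — never scored 0 — and should be
#' excluded from downstream comparisons.
#'
#' @param sites Merged sites from [merge_symmetric_cg()] (`chrom`, `pos`,
#'   `meth_freq`).
#' @param loci A data frame of intervals with columns `locus_id`, `chrom`,
#'   `start`, `end` (0-based half-open).
#'
#' @return A tibble `(locus_id, mcg_score, n_sites, defined)`, one row per
#'   input locus in input order.
#' @export
score_loci <- function(sites, loci) {
  check_columns(sites, c("chrom", "pos", "meth_freq"))
  check_columns(loci, "locus_id")
  check_intervals(loci)
  if (anyDuplicated(loci$locus_id)) {
    rlang::abort("duplicated `locus_id` in `loci`")
  }

  site_gr <- GenomicRanges::GRanges(
    sites$chrom, IRanges::IRanges(sites$pos + 1L, width = 1L)
  )
  hits <- GenomicRanges::findOverlaps(as_granges0(loci), site_gr)
  by_locus <- split(
    sites$meth_freq[S4Vectors::subjectHits(hits)],
    factor(S4Vectors::queryHits(hits), levels = seq_len(nrow(loci)))
  )
  tibble::tibble(
    locus_id = loci$locus_id,
    mcg_score = unname(purrr::map_dbl(by_locus, function(v) {
      if (length(v) == 0) NA_real_ else stats::median(v)
    })),
    n_sites = unname(lengths(by_locus)),
    defined = unname(lengths(by_locus) > 0)
  )
}

#' Classify site-level methylation into high / low / intermediate fractions
#'
#' Summarises the bimodality of CpG methylation: the fraction of sites with
#' frequency strictly above `hi`, strictly below `lo`, and in between
#' (inclusive at both thresholds).
#'
#' @param sites Merged sites with a `meth_freq` column.
#' @param hi,lo Strict thresholds (defaults 0.8 / 0.2).
#'
#' @return A one-row tibble `(frac_high, frac_low, frac_intermediate,
#'   n_sites)`; the three fractions sum to 1.
#' @export
classify_sites <- function(sites, hi = 0.8, lo = 0.2) {
  check_columns(sites, "meth_freq")
  if (hi <= lo) rlang::abort("`hi` must be greater than `lo`")
  n <- nrow(sites)
  if (n == 0) rlang::abort("no sites: fractions undefined")
  f <- sites$meth_freq
  tibble::tibble(
    frac_high = sum(f > hi) / n,
    frac_low = sum(f < lo) / n,
    frac_intermediate = sum(f >= lo & f <= hi) / n,
    n_sites = n
  )
}

#' Metagene methylation profile over loci and flanks
#'
#' Averages per-site methylation into positional bins across a set of loci:
#' fixed-width bins over `flank` bp upstream and downstream, and
#' `body_bins` length-scaled bins over the locus body. Minus-strand loci
#' are reversed so that "upstream" is always the 5' side.
#'
#' @param loci Intervals with `locus_id`, `chrom`, `start`, `end` and
#'   optionally `strand` (unstranded treated as `+`).
#' @param sites Merged sites (`chrom`, `pos`, `meth_freq`).
#' @param flank Flank size in bp (default 2000).
#' @param body_bins Number of scaled bins over the body (default 50).
#' @param flank_bin Width of each flank bin in bp (default 100).
#'
#' @return A tibble `(segment, bin, mean_mcg, n)` where `segment` is
#'   `"upstream"`, `"body"` or `"downstream"` and `bin` counts 5' to 3'
#'   within each segment. `mean_mcg` is the mean over all sites pooled
#'   across loci (`NA` where `n = 0`). The attribute `n_skipped` counts
#'   loci shorter than 1 bp.
#' @export
metagene_profile <- function(loci, sites, flank = 2000L, body_bins = 50L,
                             flank_bin = 100L) {
  check_columns(loci, c("locus_id", "chrom", "start", "end"))
  check_columns(sites, c("chrom", "pos", "meth_freq"))
  n_skipped <- sum(loci$end - loci$start < 1)
  if (n_skipped > 0) {
    rlang::warn(sprintf("skipping %d locus/loci shorter than 1 bp", n_skipped))
    loci <- dplyr::filter(loci, .data$end - .data$start >= 1)
  }
  strand <- if ("strand" %in% names(loci)) loci$strand else rep("+", nrow(loci))
  strand[!strand %in% c("+", "-")] <- "+"
  n_flank_bins <- as.integer(flank %/% flank_bin)

  # map every (locus, site) pair landing in [start - flank, end + flank)
  win <- tibble::tibble(
    chrom = loci$chrom,
    start = pmax(loci$start - flank, 0L),
    end = loci$end + flank
  )
  hits <- GenomicRanges::findOverlaps(
    as_granges0(win),
    GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(sites$pos + 1L, width = 1L))
  )
  li <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  pos <- sites$pos[si]
  freq <- sites$meth_freq[si]
  ls <- loci$start[li]; le <- loci$end[li]; str <- strand[li]
  width <- le - ls

  in_body <- pos >= ls & pos < le
  left <- pos < ls
  right <- pos >= le

  segment <- character(length(pos))
  bin <- integer(length(pos))

  # body: relative position from the 5' end
  rel <- ifelse(str == "+", pos - ls, (le - 1L) - pos)
  bin[in_body] <- pmin(
    as.integer(floor(body_bins * rel[in_body] / width[in_body])),
    body_bins - 1L
  )
  segment[in_body] <- "body"

  # flanks: genomic left flank is upstream for + loci, downstream for -
  off_left <- ls - 1L - pos       # 0 at the base adjacent to the locus
  off_right <- pos - le
  keep_left <- left & off_left < flank
  keep_right <- right & off_right < flank

  plus <- str == "+"
  seg_left <- ifelse(plus, "upstream", "downstream")
  seg_right <- ifelse(plus, "downstream", "upstream")
  segment[keep_left] <- seg_left[keep_left]
  segment[keep_right] <- seg_right[keep_right]
  # bins count 5' -> 3' within each segment
  bin[keep_left] <- ifelse(
    plus[keep_left],
    n_flank_bins - 1L - off_left[keep_left] %/% flank_bin,  # upstream of +
    off_left[keep_left] %/% flank_bin                        # downstream of -
  )
  bin[keep_right] <- ifelse(
    plus[keep_right],
    off_right[keep_right] %/% flank_bin,                     # downstream of +
    n_flank_bins - 1L - off_right[keep_right] %/% flank_bin  # upstream of -
  )

  keep <- in_body | keep_left | keep_right
  obs <- tibble::tibble(segment = segment[keep], bin = bin[keep], freq = freq[keep])

  grid <- dplyr::bind_rows(
    tibble::tibble(segment = "upstream", bin = seq_len(n_flank_bins) - 1L),
    tibble::tibble(segment = "body", bin = seq_len(body_bins) - 1L),
    tibble::tibble(segment = "downstream", bin = seq_len(n_flank_bins) - 1L)
  )
  out <- obs |>
    dplyr::group_by(.data$segment, .data$bin) |>
    dplyr::summarise(mean_mcg = mean(.data$freq), n = dplyr::n(), .groups = "drop") |>
    dplyr::right_join(grid, by = c("segment", "bin")) |>
    dplyr::mutate(
      n = dplyr::if_else(is.na(.data$n), 0L, as.integer(.data$n)),
      segment = factor(.data$segment, levels = c("upstream", "body", "downstream"))
    ) |>
    dplyr::arrange(.data$segment, .data$bin)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Label genes as highly or lowly methylated
#'
#' @param scores Per-gene mCG scores from [score_loci()]; only defined
#'   scores are accepted (undefined loci must be filtered out first —
#'   an undefined score is not evidence of low methylation).
#' @param threshold A gene is `high` iff `mcg_score > threshold` (strict;
#'   default 0.5).
#'
#' @return The input tibble with a `methylation_class` factor column
#'   (`"low"` / `"high"`).
#' @export
classify_gene_methylation <- function(scores, threshold = 0.5) {
  check_columns(scores, "mcg_score")
  if (anyNA(scores$mcg_score)) {
    rlang::abort("undefined mcg_score passed; filter undefined loci first")
  }
  dplyr::mutate(
    tibble::as_tibble(scores),
    methylation_class = factor(
      dplyr::if_else(.data$mcg_score > threshold, "high", "low"),
      levels = c("low", "high")
    )
  )
}
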