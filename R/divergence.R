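#' Kimura two-parameter divergence of a TE copy from its consensus
#'
#' Estimates the Kimura (1980) two-parameter distance between a transposable
#' element copy and its family consensus from a gapped pairwise alignment.
#' Transition (`P`) and transversion (`Q`) proportions are counted over
#' alignment columns where both sequences carry an unambiguous base
#' (`A`/`C`/`G`/`T`); gap and ambiguity columns are skipped. The distance is
#'
#' \deqn{K = -\tfrac{1}{2} \ln\left[(1 - 2P - Q)\sqrt{1 - 2Q}\right]}
#'
#' With `cpg_adjust = TRUE` (the RepeatMasker-style CpG correction used for
#' repeat landscapes), a transition observed at a column whose consensus base
#' participates in a CpG dinucleotide on the (gap-stripped) consensus
#' contributes only weight 1/10 to the transition count. This discounts the
#' hypermutable, methylation-driven C-to-T / G-to-A transitions at CpG sites
#' so that `K` tracks neutral divergence, i.e. copy age.
#'
#' @param consensus_aln Aligned consensus sequence (single string; gaps `-`).
#' @param copy_aln Aligned copy sequence of the same length.
#' @param cpg_adjust Down-weight transitions at consensus CpG columns (1/10)?
#'
#' @return A one-row tibble with columns `p` (weighted transition
#'   proportion), `q` (transversion proportion), `k` (substitutions/site),
#'   `k_pct` (`100 * k`, the Kimura-percent scale used for landscape bins),
#'   `n_sites` and `cpg_adjusted`.
#'
#' @details Alignments where the estimator is undefined — `1 - 2P - Q <= 0`
#'   or `1 - 2Q <= 0` — raise a saturation error: the copy is too diverged
#'   for the two-parameter model to return a finite distance. An alignment
#'   with no countable columns raises an empty-alignment error.
#'
#' @examples
#' kimura_distance("ACGTACGT", "ACGTACGT")        # k = 0
#' kimura_distance("AAAACCCC", "AAAGCCCC")        # one transition
#' @seealso [kimura_divergence()] for a whole alignment table,
#'   [build_landscape()] for the divergence landscape.
#' @export
kimura_distance <- function(consensus_aln, copy_aln, cpg_adjust = TRUE) {
  stopifnot(length(consensus_aln) == 1, length(copy_aln) == 1)
  cons <- strsplit(toupper(consensus_aln), "", fixed = TRUE)[[1]]
  copy <- strsplit(toupper(copy_aln), "", fixed = TRUE)[[1]]
  if (length(cons) != length(copy)) {
    rlang::abort("aligned sequences must have equal length")
  }
  if (length(cons) == 0) {
    rlang::abort("empty alignment: no sites to count")
  }

  bases <- c("A", "C", "G", "T")
  valid <- cons %in% bases & copy %in% bases
  n_sites <- sum(valid)
  if (n_sites == 0) {
    rlang::abort("empty alignment: no countable columns (all gaps/ambiguous)")
  }

  # CpG context on the gap-stripped consensus: both the C and the G column
  # of each consensus CpG are flagged
  in_cpg <- cpg_context_columns(cons)

  diff <- valid & cons != copy
  transition <- diff & (
    (cons == "A" & copy == "G") | (cons == "G" & copy == "A") |
    (cons == "C" & copy == "T") | (cons == "T" & copy == "C")
  )
  transversion <- diff & !transition

  ts_weight <- rep(1, length(cons))
  if (cpg_adjust) ts_weight[in_cpg] <- 0.1

  p <- sum(ts_weight[transition]) / n_sites
  q <- sum(transversion) / n_sites

  arg1 <- 1 - 2 * p - q
  arg2 <- 1 - 2 * q
  if (arg1 <= 0 || arg2 <= 0) {
    rlang::abort(
      sprintf("saturated alignment (P = %.4f, Q = %.4f): K2P distance undefined", p, q),
      class = "mycote_saturation_error"
    )
  }
  k <- -0.5 * log(arg1 * sqrt(arg2))

  tibble::tibble(
    p = p, q = q, k = k, k_pct = 100 * k,
    n_sites = n_sites, cpg_adjusted = cpg_adjust
  )
}

# internal: flag alignment columns whose consensus base is part of a CpG on
# the gap-stripped consensus sequence
cpg_context_columns <- function(cons) {
  is_base <- cons != "-" & cons != "."
  idx <- which(is_base)
  degapped <- cons[idx]
  flag <- rep(FALSE, length(cons))
  if (length(degapped) >= 2) {
    cg <- which(degapped[-length(degapped)] == "C" & degapped[-1] == "G")
    flag[idx[cg]] <- TRUE       # the C
    flag[idx[cg + 1]] <- TRUE   # the G
  }
  flag
}

#' Kimura divergence for a table of copy-vs-consensus alignments
#'
#' Applies [kimura_distance()] to every row of an alignment table. Copies
#' whose alignment is saturated (the two-parameter estimator is undefined)
#' are returned with `k = NA` and `saturated = TRUE` instead of failing the
#' whole table; a warning reports how many were skipped.
#'
#' @param alignments A data frame with columns `te_id`, `consensus_aln`,
#'   `copy_aln` and (carried through if present) `family`, `superfamily`,
#'   `chrom`, `start`, `end`.
#' @param cpg_adjust Passed to [kimura_distance()].
#'
#' @return A tibble with one row per copy: the carried-through annotation
#'   columns plus `p`, `q`, `k`, `k_pct`, `n_sites`, `copy_length`
#'   (ungapped copy length) and `saturated`.
#' @export
kimura_divergence <- function(alignments, cpg_adjust = TRUE) {
  check_columns(alignments, c("te_id", "consensus_aln", "copy_aln"))
  est <- purrr::map2(
    alignments$consensus_aln, alignments$copy_aln,
    function(cons, cop) {
      tryCatch(
        kimura_distance(cons, cop, cpg_adjust = cpg_adjust),
        mycote_saturation_error = function(e) {
          tibble::tibble(
            p = NA_real_, q = NA_real_, k = NA_real_, k_pct = NA_real_,
            n_sites = NA_integer_, cpg_adjusted = cpg_adjust
          )
        }
      )
    }
  )
  est <- dplyr::bind_rows(est)
  carried <- intersect(
    c("te_id", "family", "superfamily", "chrom", "start", "end"),
    names(alignments)
  )
  out <- dplyr::bind_cols(alignments[carried], est)
  out$copy_length <- nchar(gsub("[-.]", "", alignments$copy_aln))
  out$saturated <- is.na(out$k)
  n_sat <- sum(out$saturated)
  if (n_sat > 0) {
    rlang::warn(sprintf("%d saturated alignment(s) returned k = NA", n_sat))
  }
  tibble::as_tibble(out)
}

#' Build a repeat divergence landscape
#'
#' Bins TE copies by Kimura distance (1 Kimura-percent bins, 0–`max_bin`)
#' and accumulates genome coverage per superfamily per bin — the classic
#' "repeat landscape" in which recent TE expansions pile up at low
#' divergence and ancient ones trail off to the right.
#'
#' @param estimates A data frame with columns `k`, `copy_length` and
#'   `superfamily` (e.g. the output of [kimura_divergence()]). Rows with
#'   `k = NA` are dropped with a warning.
#' @param genome_length Total assembly length in bp (> 0).
#' @param max_bin Largest divergence bin; copies with `100 * k > max_bin`
#'   are clamped into it (default 50, matching the usual 0–50 axis).
#'
#' @return A long-format tibble `(superfamily, bin, coverage_pct)` with a
#'   complete 0..`max_bin` bin grid per superfamily present in the input.
#'   The attribute `n_clamped` counts copies clamped into the last bin.
#'   Coverage satisfies `sum(coverage_pct) * genome_length / 100 ==
#'   sum(copy_length)`.
#' @export
build_landscape <- function(estimates, genome_length, max_bin = 50L) {
  if (!is.numeric(genome_length) || genome_length <= 0) {
    rlang::abort("`genome_length` must be a positive number")
  }
  check_columns(estimates, c("k", "copy_length", "superfamily"))
  est <- tibble::as_tibble(estimates)
  if (anyNA(est$k)) {
    rlang::warn(sprintf("dropping %d copies with undefined k", sum(is.na(est$k))))
    est <- dplyr::filter(est, !is.na(.data$k))
  }
  if (any(est$copy_length <= 0)) {
    rlang::abort("all copy lengths must be > 0")
  }
  if (nrow(est) == 0) {
    out <- tibble::tibble(
      superfamily = character(), bin = integer(), coverage_pct = numeric()
    )
    attr(out, "n_clamped") <- 0L
    attr(out, "genome_length") <- genome_length
    return(out)
  }
  raw_bin <- floor(100 * est$k)
  n_clamped <- sum(raw_bin > max_bin)
  est$bin <- as.integer(pmin(pmax(raw_bin, 0L), max_bin))

  out <- est |>
    dplyr::group_by(.data$superfamily, .data$bin) |>
    dplyr::summarise(
      coverage_pct = sum(.data$copy_length) / genome_length * 100,
      .groups = "drop"
    ) |>
    tidyr::complete(
      superfamily = unique(est$superfamily),
      bin = 0:max_bin,
      fill = list(coverage_pct = 0)
    ) |>
    dplyr::arrange(.data$superfamily, .data$bin)
  attr(out, "n_clamped") <- n_clamped
  attr(out, "genome_length") <- genome_length
  out
}
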