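#' Default transposon-related protein-domain blocklist
#'
#' Domain tokens marking a predicted gene as transposon-derived (reverse
#' transcriptases, transposases, gag-pol, helitron helicases, ...). A gene
#' is flagged when any of its domain labels contains one of these tokens,
#' case-insensitively, as a substring.
#'
#' @return A character vector of tokens.
#' @export
transposon_domain_blocklist <- function() {
  c(
    "transposon", "zinc_finger_bed_domain", "ricesleeper",
    "helicase-primase", "helicase/primase", "gag-pol", "far1-related",
    "ribonuclease_hi", "ribonuclease_h", "jockey",
    "rve_super_family_integrase", "transposase", "transposable",
    "helitron", "pif1", "zinc_finger_mym-type_protein_2",
    "reverse_transcriptase"
  )
}

# internal: ordered domain patterns for the expanded (Class C) families and
# crinkler effectors; matching is case-insensitive substring, first hit wins
class_c_patterns <- function() {
  list(
    crinkler = c("crinkler"),
    C_CaM_kinase = c("calmodulin", "camk"),
    C_STY_kinase = c("kinase"),
    C_BTB_POZ = c("btb", "poz"),
    C_Sel1 = c("sel1"),
    C_Kelch = c("kelch")
  )
}

# internal: split a domains field into tokens; accepts list-columns or
# comma-separated strings; NA/"" -> no domains
domain_tokens <- function(domains) {
  if (is.list(domains)) {
    lapply(domains, function(d) d[!is.na(d) & nzchar(d)])
  } else {
    lapply(strsplit(ifelse(is.na(domains), "", domains), ","), function(d) {
      d <- trimws(d)
      d[nzchar(d)]
    })
  }
}

# internal: does any token contain any pattern (case-insensitive substring)?
matches_any <- function(tokens, patterns) {
  if (length(tokens) == 0) return(FALSE)
  any(vapply(
    patterns,
    function(p) any(grepl(p, tokens, ignore.case = TRUE, fixed = FALSE)),
    logical(1)
  ))
}

#' Flag genes with transposon-related protein domains
#'
#' Genes whose predicted protein domains match the transposon blocklist are
#' TE-derived gene models, not host genes; they are flagged here and
#' labelled `transposon_related` by [classify_genes()].
#'
#' @param genes A data frame with `gene_id` and `domains` (comma-separated
#'   string or list-column of domain labels; empty means no known domain).
#' @param blocklist Tokens matched case-insensitively as substrings
#'   (default [transposon_domain_blocklist()]).
#'
#' @return The input tibble with a logical `transposon_related` column.
#' @export
remove_transposon_genes <- function(genes, blocklist = transposon_domain_blocklist()) {
  check_columns(genes, c("gene_id", "domains"))
  toks <- domain_tokens(genes$domains)
  dplyr::mutate(
    tibble::as_tibble(genes),
    transposon_related = vapply(toks, matches_any, logical(1), patterns = blocklist)
  )
}

#' Classify genes into core / orphan / expanded-family classes
#'
#' Deterministic rule-based classification of predicted genes:
#' \describe{
#'   \item{transposon_related}{any domain matches the transposon blocklist.}
#'   \item{crinkler}{a crinkler effector domain is present (takes
#'     precedence over Class C tokens when both occur).}
#'   \item{C_*}{one of the five expanded high-copy-number signalling
#'     families: serine/threonine/tyrosine kinase, calmodulin-dependent
#'     kinase, BTB/POZ, Sel1-like, Kelch-like.}
#'   \item{B_HCN / B_LCN}{orphans (no known domain), split into high copy
#'     number (overlapping a de novo repeat, `repeat_overlap = TRUE`) and
#'     low copy number.}
#'   \item{A}{everything else: core genes with an identifiable,
#'     non-expanded protein domain.}
#' }
#'
#' @param genes A data frame with `gene_id`, `domains` and `repeat_overlap`
#'   (logical).
#' @param blocklist Transposon-domain tokens
#'   (default [transposon_domain_blocklist()]).
#' @param crinkler_precedence If a gene carries both a crinkler and a
#'   Class C token, crinkler wins (default `TRUE`); set `FALSE` to prefer
#'   the Class C label. Conflicts are counted in the `n_conflicts`
#'   attribute.
#'
#' @return The input tibble with a `class` factor column; every gene gets
#'   exactly one class.
#' @export
classify_genes <- function(genes, blocklist = transposon_domain_blocklist(),
                           crinkler_precedence = TRUE) {
  check_columns(genes, c("gene_id", "domains", "repeat_overlap"))
  if (anyDuplicated(genes$gene_id)) {
    rlang::abort("duplicated `gene_id` in `genes`")
  }
  toks <- domain_tokens(genes$domains)
  pats <- class_c_patterns()

  is_te <- vapply(toks, matches_any, logical(1), patterns = blocklist)
  is_crink <- vapply(toks, matches_any, logical(1), patterns = pats$crinkler)
  c_classes <- setdiff(names(pats), "crinkler")
  c_hit <- vapply(toks, function(tk) {
    for (cl in c_classes) {
      if (matches_any(tk, pats[[cl]])) return(cl)
    }
    NA_character_
  }, character(1))

  n_conflicts <- sum(!is_te & is_crink & !is.na(c_hit))

  cls <- character(nrow(genes))
  has_domain <- lengths(toks) > 0
  for (i in seq_len(nrow(genes))) {
    cls[i] <- if (is_te[i]) {
      "transposon_related"
    } else if (is_crink[i] && (crinkler_precedence || is.na(c_hit[i]))) {
      "crinkler"
    } else if (!is.na(c_hit[i])) {
      c_hit[i]
    } else if (!has_domain[i]) {
      if (isTRUE(genes$repeat_overlap[i])) "B_HCN" else "B_LCN"
    } else {
      "A"
    }
  }

  out <- dplyr::mutate(
    tibble::as_tibble(genes),
    class = factor(cls, levels = gene_class_levels())
  )
  attr(out, "n_conflicts") <- n_conflicts
  out
}

#' All gene class labels in display order
#' @return A character vector of class levels.
#' @export
gene_class_levels <- function() {
  c("A", "B_LCN", "B_HCN",
    "C_STY_kinase", "C_CaM_kinase", "C_BTB_POZ", "C_Sel1", "C_Kelch",
    "crinkler", "transposon_related")
}

#' Intergenic distances per gene
#'
#' Distance from each gene to its nearest neighbouring gene on either side
#' along the chromosome, reported relative to the gene's own orientation
#' (`dist_5prime`, `dist_3prime`). Overlapping neighbours give distance 0;
#' chromosome-terminal genes get `NA` on the open side. Input is auto-sorted
#' per chromosome.
#'
#' @param genes A data frame with `gene_id`, `chrom`, `start`, `end` and
#'   optionally `strand` (unstranded treated as `+`).
#' @return A tibble `(gene_id, chrom, start, end, strand, dist_5prime,
#'   dist_3prime)`.
#' @export
intergenic_distances <- function(genes) {
  check_columns(genes, c("gene_id", "chrom", "start", "end"))
  check_intervals(genes)
  if (anyDuplicated(genes$gene_id)) {
    rlang::abort("duplicated `gene_id` in `genes`")
  }
  g <- tibble::as_tibble(genes)
  if (!"strand" %in% names(g)) g$strand <- "+"
  g |>
    dplyr::arrange(.data$chrom, .data$start, .data$end) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(
      dist_left = pmax(.data$start - dplyr::lag(.data$end), 0L),
      dist_right = pmax(dplyr::lead(.data$start) - .data$end, 0L),
      dist_5prime = dplyr::if_else(.data$strand == "-", .data$dist_right, .data$dist_left),
      dist_3prime = dplyr::if_else(.data$strand == "-", .data$dist_left, .data$dist_right)
    ) |>
    dplyr::ungroup() |>
    dplyr::select(
      "gene_id", "chrom", "start", "end", "strand",
      "dist_5prime", "dist_3prime"
    )
}

#' Gene density over tiling windows
#'
#' Counts genes per fixed non-overlapping window; each gene is assigned to
#' the window containing its midpoint, so every gene is counted exactly
#' once.
#'
#' @param genes A data frame with `chrom`, `start`, `end`.
#' @param window Window width in bp (default 10 kb).
#' @param chrom_lengths Optional tibble `(chrom, length)`; windows then tile
#'   whole chromosomes, otherwise up to the last gene.
#' @return A tibble `(chrom, window_start, window_end, n_genes)`.
#' @export
gene_density <- function(genes, window = 10000L, chrom_lengths = NULL) {
  check_intervals(genes)
  if (window <= 0) rlang::abort("`window` must be positive")
  mid <- (genes$start + genes$end) %/% 2
  counts <- tibble::tibble(chrom = genes$chrom, win = mid %/% window) |>
    dplyr::count(.data$chrom, .data$win, name = "n_genes")
  ends <- if (!is.null(chrom_lengths)) {
    check_columns(chrom_lengths, c("chrom", "length"))
    tibble::tibble(
      chrom = chrom_lengths$chrom,
      max_win = pmax((chrom_lengths$length - 1L) %/% window, 0)
    )
  } else {
    counts |>
      dplyr::group_by(.data$chrom) |>
      dplyr::summarise(max_win = max(.data$win), .groups = "drop")
  }
  grid <- ends |>
    dplyr::group_by(.data$chrom) |>
    dplyr::reframe(win = 0:.data$max_win)
  grid |>
    dplyr::left_join(counts, by = c("chrom", "win")) |>
    dplyr::mutate(
      n_genes = dplyr::if_else(is.na(.data$n_genes), 0L, as.integer(.data$n_genes)),
      window_start = .data$win * as.integer(window),
      window_end = .data$window_start + as.integer(window)
    ) |>
    dplyr::select("chrom", "window_start", "window_end", "n_genes")
}
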