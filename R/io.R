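# File-format boundary. Every coordinate inside the package is 0-based
# half-open; GFF3 (1-based inclusive) and RepeatMasker .out (1-based
# inclusive) are converted exactly here.

#' Read / write a genome FASTA
#'
#' Thin wrappers over Biostrings with the package's conventions (multi-
#' record, wrapped at 70 columns).
#'
#' @param path File path.
#' @return `read_genome_fasta()` returns a [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' @param genome A [Biostrings::DNAStringSet].
#' @rdname read_genome_fasta
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Read a RepeatMasker .out annotation table
#'
#' Parses the whitespace-delimited RepeatMasker `.out` format (tolerating
#' the standard 3-line header and the trailing `*` overlap marker) into a
#' 0-based half-open TE tibble. `C` strand is reported as `-`.
#'
#' @param path File path.
#' @return A tibble `(te_id, chrom, start, end, strand, family,
#'   superfamily, score, div_pct)`.
#' @export
read_rm_out <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  is_header <- grepl("^(SW|score|$)", lines)
  body <- lines[!is_header & nzchar(lines)]
  if (length(body) == 0) {
    return(tibble::tibble(
      te_id = character(), chrom = character(), start = integer(),
      end = integer(), strand = character(), family = character(),
      superfamily = character(), score = numeric(), div_pct = numeric()
    ))
  }
  fields <- strsplit(body, "\\s+")
  bad <- which(lengths(fields) < 14)
  if (length(bad) > 0) {
    rlang::abort(sprintf("malformed .out record at line %d",
                         which(!is_header & nzchar(lines))[bad[1]]))
  }
  f <- function(i) vapply(fields, `[[`, character(1), i)
  start1 <- as.integer(f(6)); end1 <- as.integer(f(7))
  if (any(end1 < start1)) rlang::abort("coordinate violation: end < start in .out")
  tibble::tibble(
    te_id = f(15),
    chrom = f(5),
    start = start1 - 1L,
    end = end1,
    strand = ifelse(f(9) == "C", "-", "+"),
    family = f(10),
    superfamily = f(11),
    score = as.numeric(f(1)),
    div_pct = as.numeric(f(2))
  )
}

#' Write a RepeatMasker-style .out table
#'
#' @param tes TE tibble with `te_id`, `chrom`, `start`, `end`, `strand`,
#'   `family`, `superfamily` and optionally `score`, `div_pct`.
#' @param path File path.
#' @rdname read_rm_out
#' @export
write_rm_out <- function(tes, path) {
  check_intervals(tes)
  header <- c(
    "   SW   perc perc perc  query     position in query     matching  repeat          position in repeat",
    "score   div. del. ins.  sequence  begin  end   (left)   repeat    class/family  begin  end    (left)  ID",
    ""
  )
  score <- if ("score" %in% names(tes)) tes$score else rep(0, nrow(tes))
  div <- if ("div_pct" %in% names(tes)) tes$div_pct else rep(0, nrow(tes))
  rows <- sprintf(
    "%5.0f %6.1f  0.0  0.0  %s %d %d (0) %s %s %s 1 %d (0) %s",
    score, div, tes$chrom, tes$start + 1L, tes$end,
    ifelse(tes$strand == "-", "C", "+"),
    tes$family, tes$superfamily, tes$end - tes$start, tes$te_id
  )
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read / write BED6 intervals
#'
#' BED is natively 0-based half-open, matching the package's internal
#' convention, so coordinates pass through unchanged.
#'
#' @param path File path.
#' @return A tibble `(chrom, start, end, name, score, strand)`.
#' @export
read_bed6 <- function(path) {
  x <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "name", "score", "strand"),
    col_types = "ciicdc", comment = "#", progress = FALSE
  )
  check_intervals(x)
  x
}

#' @param x An interval tibble with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @rdname read_bed6
#' @export
write_bed6 <- function(x, path) {
  check_intervals(x)
  out <- tibble::tibble(
    chrom = x$chrom, start = x$start, end = x$end,
    name = x$name %||% x$te_id %||% x$gene_id %||% x$locus_id %||% ".",
    score = x$score %||% 0,
    strand = x$strand %||% "."
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read / write a gene annotation GFF3 with domain labels
#'
#' Genes are stored as GFF3 `gene` features (1-based inclusive on disk,
#' converted to 0-based half-open on read) with `ID`, comma-separated
#' `domains` and `repeat_overlap` attributes.
#'
#' @param path File path.
#' @return A tibble `(gene_id, chrom, start, end, strand, domains,
#'   repeat_overlap)`.
#' @export
read_gene_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  domains <- if ("domains" %in% names(S4Vectors::mcols(gr))) {
    d <- S4Vectors::mcols(gr)$domains
    if (is.list(d) || methods::is(d, "CharacterList")) {
      vapply(d, function(v) paste(v, collapse = ","), character(1))
    } else {
      ifelse(is.na(d), "", d)
    }
  } else rep("", length(gr))
  ro <- if ("repeat_overlap" %in% names(S4Vectors::mcols(gr))) {
    as.logical(S4Vectors::mcols(gr)$repeat_overlap)
  } else rep(FALSE, length(gr))
  tibble::tibble(
    gene_id = gr$ID,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = ifelse(as.character(BiocGenerics::strand(gr)) == "-", "-", "+"),
    domains = domains,
    repeat_overlap = ro
  )
}

#' @param genes A gene tibble as returned by [read_gene_gff3()].
#' @rdname read_gene_gff3
#' @export
write_gene_gff3 <- function(genes, path) {
  check_intervals(genes)
  check_columns(genes, c("gene_id", "strand"))
  domains <- genes$domains %||% rep("", nrow(genes))
  ro <- genes$repeat_overlap %||% rep(FALSE, nrow(genes))
  attrs <- sprintf(
    "ID=%s;repeat_overlap=%s%s",
    genes$gene_id, tolower(as.character(ro)),
    ifelse(nzchar(domains), paste0(";domains=", domains), "")
  )
  rows <- sprintf(
    "%s\tmycoTE\tgene\t%d\t%d\t.\t%s\t.\t%s",
    genes$chrom, genes$start + 1L, genes$end, genes$strand, attrs
  )
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}

#' Read / write per-cytosine methylation calls
#'
#' TSV with columns `chrom`, `pos` (0-based), `strand`, `meth_freq`,
#' `coverage`.
#'
#' @param path File path.
#' @return A tibble of methylation records.
#' @export
read_methylation_tsv <- function(path) {
  readr::read_tsv(path, col_types = "cicdi", progress = FALSE)
}

#' @param records A methylation record tibble.
#' @rdname read_methylation_tsv
#' @export
write_methylation_tsv <- function(records, path) {
  check_columns(records, c("chrom", "pos", "strand", "meth_freq", "coverage"))
  readr::write_tsv(records, path, progress = FALSE)
  invisible(path)
}

#' Read / write small RNA read tables
#'
#' TSV with columns `chrom`, `start`, `end` (0-based half-open), `strand`,
#' `length`, `first_nt`, `sequence`, `library`, `replicate`, `count`.
#'
#' @param path File path.
#' @return A tibble of reads.
#' @export
read_srna_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_intervals(x)
  x
}

#' @param reads An sRNA read tibble.
#' @rdname read_srna_tsv
#' @export
write_srna_tsv <- function(reads, path) {
  check_intervals(reads)
  readr::write_tsv(reads, path, progress = FALSE)
  invisible(path)
}

#' Read / write count matrices
#'
#' TSV with a `feature_id` column followed by one column per sample.
#'
#' @param path File path.
#' @return A counts tibble.
#' @export
read_counts_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(x, "feature_id")
  x
}

#' @param counts A counts tibble.
#' @rdname read_counts_tsv
#' @export
write_counts_tsv <- function(counts, path) {
  check_columns(counts, "feature_id")
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}
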