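# Counts enter as a tibble with a `feature_id` column followed by one
# numeric column per sample; helpers below convert to/from a plain matrix.

# internal: counts tibble -> numeric matrix with feature_id rownames
counts_matrix <- function(counts) {
  check_columns(counts, "feature_id")
  m <- as.matrix(counts[, setdiff(names(counts), "feature_id"), drop = FALSE])
  if (!is.numeric(m)) rlang::abort("count columns must be numeric")
  if (any(m < 0)) rlang::abort("counts must be non-negative")
  rownames(m) <- counts$feature_id
  m
}

# internal: matrix -> counts tibble
counts_tibble <- function(m) {
  dplyr::bind_cols(
    tibble::tibble(feature_id = rownames(m)),
    tibble::as_tibble(m)
  )
}

#' Median-of-ratios size factors
#'
#' Per-sample normalisation factors computed as the median, over features
#' with strictly positive counts in every sample, of the ratio of the
#' sample's count to the feature's geometric mean across samples — the
#' standard robust library-size estimate for count matrices.
#'
#' @param counts A counts tibble (`feature_id` + one column per sample).
#' @return A tibble `(sample, size_factor)` with all factors > 0.
#' @export
size_factors <- function(counts) {
  m <- counts_matrix(counts)
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) {
    rlang::abort(paste(
      "no feature has positive counts in every sample;",
      "median-of-ratios undefined (consider a pseudo-reference fallback)"
    ))
  }
  lg <- log(m[pos, , drop = FALSE])
  geo <- exp(rowMeans(lg))
  sf <- apply(m[pos, , drop = FALSE], 2, function(col) stats::median(col / geo))
  tibble::tibble(sample = colnames(m), size_factor = unname(sf))
}

#' Normalise a count matrix by size factors
#'
#' @param counts A counts tibble.
#' @param factors Output of [size_factors()] (computed from `counts` when
#'   omitted).
#' @return A counts tibble of normalised counts (`count / size_factor`).
#' @export
normalize_counts <- function(counts, factors = size_factors(counts)) {
  m <- counts_matrix(counts)
  check_columns(factors, c("sample", "size_factor"))
  sf <- factors$size_factor[match(colnames(m), factors$sample)]
  if (anyNA(sf)) rlang::abort("size factors missing for some samples")
  if (any(sf <= 0)) rlang::abort("size factors must be > 0")
  counts_tibble(sweep(m, 2, sf, "/"))
}

#' Reads per kilobase per million mapped reads (RPKM)
#'
#' `RPKM = count / (length/1e3) / (total/1e6)`.
#'
#' @param counts A counts tibble.
#' @param lengths A tibble `(feature_id, length)` in bp (> 0).
#' @param totals Per-sample total mapped reads; defaults to column sums.
#' @return A counts-shaped tibble of RPKM values.
#' @export
rpkm <- function(counts, lengths, totals = NULL) {
  m <- counts_matrix(counts)
  check_columns(lengths, c("feature_id", "length"))
  len <- lengths$length[match(rownames(m), lengths$feature_id)]
  if (anyNA(len)) rlang::abort("lengths missing for some features")
  if (any(len <= 0)) rlang::abort("feature lengths must be > 0")
  tot <- totals %||% colSums(m)
  if (any(tot <= 0)) rlang::abort("totals must be > 0")
  out <- sweep(m / (len / 1e3), 2, tot / 1e6, "/")
  counts_tibble(out)
}

#' Apply the expressed-feature filters
#'
#' The three filters used to call a feature expressed, by feature kind:
#' \describe{
#'   \item{`te_subfamily`}{at least 100 normalised counts — by default in
#'     at least one sample; `subfamily_mode = "sum"` instead requires the
#'     sum across samples to reach 100.}
#'   \item{`te_locus`}{length strictly greater than 100 bp AND RPKM >= 1 in
#'     at least `min_samples` (default 6) samples.}
#'   \item{`gene`}{normalised count >= 2 in at least 2 samples.}
#' }
#'
#' @param normalized A normalised counts tibble (see [normalize_counts()]);
#'   for `te_locus` supply raw `counts` too (RPKM uses raw totals).
#' @param kind One of `"te_subfamily"`, `"te_locus"`, `"gene"`.
#' @param lengths Required for `te_locus`: tibble `(feature_id, length)`.
#' @param counts Raw counts tibble, required for `te_locus`.
#' @param min_samples RPKM support threshold for `te_locus` (default 6).
#' @param subfamily_mode `"per_sample"` (default) or `"sum"`.
#' @return A tibble `(feature_id, expressed)`.
#' @export
filter_expressed <- function(normalized, kind = c("te_subfamily", "te_locus", "gene"),
                             lengths = NULL, counts = NULL, min_samples = 6L,
                             subfamily_mode = c("per_sample", "sum")) {
  kind <- match.arg(kind)
  subfamily_mode <- match.arg(subfamily_mode)
  nm <- counts_matrix(normalized)
  expressed <- switch(kind,
    te_subfamily = if (subfamily_mode == "per_sample") {
      apply(nm >= 100, 1, any)
    } else {
      rowSums(nm) >= 100
    },
    te_locus = {
      if (is.null(lengths)) rlang::abort("`lengths` required for kind = 'te_locus'")
      if (is.null(counts)) rlang::abort("`counts` (raw) required for kind = 'te_locus'")
      rk <- counts_matrix(rpkm(counts, lengths))
      len <- lengths$length[match(rownames(nm), lengths$feature_id)]
      long <- len > 100
      supported <- rowSums(rk[match(rownames(nm), rownames(rk)), , drop = FALSE] >= 1) >= min_samples
      long & supported
    },
    gene = rowSums(nm >= 2) >= 2
  )
  tibble::tibble(feature_id = rownames(nm), expressed = unname(expressed))
}

#' Partition TE loci into genic and non-genic sets
#'
#' TE copies that overlap an expressed gene by at least 1 bp are set aside
#' as "genic": their apparent expression may simply be read-through from
#' the host gene, so downstream TE-expression analyses use the non-genic
#' set only.
#'
#' @param te_loci TE intervals (`te_id`, `chrom`, `start`, `end`).
#' @param genes Gene intervals (`gene_id`, `chrom`, `start`, `end`).
#' @param expressed_gene_ids Character vector of expressed gene ids.
#' @return The TE tibble with a logical `genic` column.
#' @export
exclude_genic_tes <- function(te_loci, genes, expressed_gene_ids) {
  check_intervals(te_loci); check_columns(te_loci, "te_id")
  check_intervals(genes); check_columns(genes, "gene_id")
  eg <- dplyr::filter(tibble::as_tibble(genes), .data$gene_id %in% expressed_gene_ids)
  genic <- rep(FALSE, nrow(te_loci))
  if (nrow(eg) > 0) {
    hits <- GenomicRanges::findOverlaps(as_granges0(te_loci), as_granges0(eg))
    genic[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  dplyr::mutate(tibble::as_tibble(te_loci), genic = genic)
}

#' Simplified two-group differential expression test
#'
#' A deliberately simple differential test for normalised counts: the fold
#' change is `log2((mean_B + c) / (mean_A + c))` with pseudocount `c`, and
#' the p-value comes from a pooled-variance two-sample t test on
#' `log2(count + c)` (on the log scale the group variances are comparable
#' for count data of similar magnitude, and pooling preserves degrees of
#' freedom in small designs).
#' This is a documented approximation — no dispersion shrinkage or
#' count-model fit — adequate for the clear planted effects of synthetic
#' data; externally computed results can be supplied wherever a
#' `DifferentialResult`-shaped table is consumed.
#'
#' @param normalized A normalised counts tibble.
#' @param group_a,group_b Disjoint character vectors of sample (column)
#'   names; `group_a` is the reference, so positive `log2fc` means higher
#'   in `group_b`. Each needs >= 2 samples.
#' @param lfc_threshold,fdr_threshold Significance calls require
#'   `|log2fc| > lfc_threshold` and `fdr < fdr_threshold` (defaults 0.5 and
#'   0.05).
#' @param pseudocount Added before logging (default 1).
#'
#' @return A tibble of class `mycote_de` with columns `(feature_id,
#'   mean_a, mean_b, log2fc, p, fdr, significant)`; see [tidy()],
#'   [glance()] and [autoplot.mycote_de()].
#' @export
simple_de <- function(normalized, group_a, group_b, lfc_threshold = 0.5,
                      fdr_threshold = 0.05, pseudocount = 1) {
  m <- counts_matrix(normalized)
  if (length(intersect(group_a, group_b)) > 0) {
    rlang::abort("`group_a` and `group_b` must be disjoint")
  }
  if (!all(c(group_a, group_b) %in% colnames(m))) {
    rlang::abort("some group samples are not columns of `normalized`")
  }
  if (length(group_a) < 2 || length(group_b) < 2) {
    rlang::abort("each group needs at least 2 samples")
  }
  a <- m[, group_a, drop = FALSE]
  b <- m[, group_b, drop = FALSE]
  mean_a <- unname(rowMeans(a))
  mean_b <- unname(rowMeans(b))
  log2fc <- log2((mean_b + pseudocount) / (mean_a + pseudocount))
  la <- log2(a + pseudocount)
  lb <- log2(b + pseudocount)
  p <- vapply(seq_len(nrow(m)), function(i) {
    xa <- la[i, ]; xb <- lb[i, ]
    if (stats::var(xa) + stats::var(xb) == 0) {
      return(if (mean(xa) == mean(xb)) 1 else .Machine$double.eps)
    }
    stats::t.test(xb, xa, var.equal = TRUE)$p.value
  }, numeric(1))
  fdr <- stats::p.adjust(p, method = "BH")
  out <- tibble::tibble(
    feature_id = rownames(m), mean_a = mean_a, mean_b = mean_b,
    log2fc = log2fc, p = p, fdr = fdr,
    significant = abs(log2fc) > lfc_threshold & fdr < fdr_threshold
  )
  class(out) <- c("mycote_de", class(out))
  attr(out, "lfc_threshold") <- lfc_threshold
  attr(out, "fdr_threshold") <- fdr_threshold
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p A numeric vector of p-values in `[0, 1]` (validated).
#' @return Adjusted p-values (monotone in the ranks, `>=` raw, capped at 1)
#'   in the original order.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    rlang::abort("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}
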