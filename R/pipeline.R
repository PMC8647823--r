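#' Run the full integrative analysis on a synthetic dataset
#'
#' End-to-end orchestration of every stage on data from
#' [simulate_dataset()]: TE divergence landscape; methylome merging,
#' site bimodality, per-locus mCG and per-class comparisons; gene
#' classification and intergenic distances; nearest-TE proximity tests;
#' expression normalisation, filters and differential subfamilies; sRNA
#' locus calling, enrichment classification, origin assignment, the
#' shuffled-locus distance null and per-superfamily sRNA production.
#' Stages can be toggled off; every stochastic step is seeded from the
#' config.
#'
#' @param config A [sim_config()]; its `seed` drives both the simulation
#'   and the shuffle null.
#' @param sim Optionally, a pre-generated [simulate_dataset()] result (the
#'   config is then only used for stage parameters and the shuffle seed).
#' @param stages Character vector of stages to run, any of `"divergence"`,
#'   `"methylome"`, `"gene_classes"`, `"expression"`, `"proximity"`,
#'   `"srna"` (dependencies are handled: `srna` and `proximity` need
#'   `expression` and `gene_classes`).
#' @param n_shuffles Shuffle sets for the sRNA distance null (default 1).
#'
#' @return An object of class `mycote_pipeline`: a list of per-stage
#'   result tables (see Details) plus the `sim` input and echoed
#'   parameters.
#'
#' @details Result elements: `landscape`, `divergence`; `site_fractions`,
#'   `te_methylation`, `gene_methylation`, `te_expression_methylation_test`,
#'   `gene_class_methylation` (Dunn comparisons); `gene_classes`,
#'   `intergenic`; `size_factors`, `expressed_genes`, `expressed_te_loci`,
#'   `expressed_subfamilies`, `de_subfamilies`; `nearest_te`,
#'   `proximity_tests`, `family_enrichment`; `srna_loci`,
#'   `srna_enrichment`, `srna_origin`, `origin_counts`, `shuffle_null`,
#'   `srna_production`.
#' @export
run_pipeline <- function(config = sim_config(), sim = NULL,
                         stages = c("divergence", "methylome", "gene_classes",
                                    "expression", "proximity", "srna"),
                         n_shuffles = 1L) {
  stopifnot(inherits(config, "mycote_sim_config"))
  sim <- sim %||% simulate_dataset(config)
  res <- list(config = config)

  if ("divergence" %in% stages) {
    res$divergence <- kimura_divergence(sim$alignments, cpg_adjust = TRUE)
    res$landscape <- build_landscape(
      res$divergence,
      genome_length = sum(sim$chrom_lengths$length)
    )
  }

  merged <- NULL
  if ("methylome" %in% stages) {
    merged <- merge_symmetric_cg(sim$methylation)
    res$site_fractions <- classify_sites(merged)
    te_loci <- dplyr::rename(sim$tes, locus_id = "te_id")
    res$te_methylation <- score_loci(merged, te_loci) |>
      dplyr::left_join(
        dplyr::select(sim$tes, locus_id = "te_id", "family", "superfamily",
                      "planted_k", "expressed"),
        by = "locus_id"
      )
    res$gene_methylation <- score_loci(
      merged, dplyr::rename(sim$genes, locus_id = "gene_id")
    )
    res$te_metagene <- metagene_profile(
      dplyr::rename(sim$tes, locus_id = "te_id"), merged
    )
  }

  classified <- NULL
  if ("gene_classes" %in% stages || "proximity" %in% stages ||
      "srna" %in% stages) {
    classified <- classify_genes(sim$genes)
    res$gene_classes <- classified
    res$class_counts <- dplyr::count(classified, .data$class, name = "n_genes")
    res$intergenic <- intergenic_distances(sim$genes) |>
      dplyr::left_join(dplyr::select(classified, "gene_id", "class"),
                       by = "gene_id")
  }

  expressed_genes <- character(0)
  expressed_tes <- character(0)
  if ("expression" %in% stages || "srna" %in% stages) {
    gc <- sim$counts$gene_counts
    res$size_factors <- size_factors(gc)
    gnorm <- normalize_counts(gc, res$size_factors)
    res$expressed_genes <- filter_expressed(gnorm, kind = "gene")
    expressed_genes <- res$expressed_genes$feature_id[res$expressed_genes$expressed]

    te_lengths <- tibble::tibble(
      feature_id = sim$tes$te_id, length = sim$tes$end - sim$tes$start
    )
    tnorm <- normalize_counts(sim$counts$te_locus_counts)
    res$expressed_te_loci <- filter_expressed(
      tnorm, kind = "te_locus", lengths = te_lengths,
      counts = sim$counts$te_locus_counts
    )
    res$te_partition <- exclude_genic_tes(sim$tes, sim$genes, expressed_genes)
    expressed_tes <- res$expressed_te_loci$feature_id[res$expressed_te_loci$expressed]

    snorm <- normalize_counts(sim$counts$subfamily_counts)
    res$expressed_subfamilies <- filter_expressed(snorm, kind = "te_subfamily")
    samples <- sim$counts$samples
    res$de_subfamilies <- simple_de(
      snorm,
      group_a = samples$sample[samples$condition == "t0"],
      group_b = samples$sample[samples$condition == "t24_exudate"]
    )
  }

  if ("methylome" %in% stages && !is.null(merged)) {
    # expressed vs non-expressed TE mCG (planted expression flags)
    tm <- dplyr::filter(res$te_methylation, .data$defined)
    kwx <- kw_h_test(list(
      tm$mcg_score[tm$expressed], tm$mcg_score[!tm$expressed]
    ))
    res$te_expression_methylation_test <- tibble::tibble(
      statistic = kwx$statistic, p = kwx$p,
      median_expressed = stats::median(tm$mcg_score[tm$expressed]),
      median_nonexpressed = stats::median(tm$mcg_score[!tm$expressed]),
      n_expressed = sum(tm$expressed), n_nonexpressed = sum(!tm$expressed)
    )
    if (!is.null(classified)) {
      gm <- res$gene_methylation |>
        dplyr::filter(.data$defined) |>
        dplyr::left_join(
          dplyr::select(classified, locus_id = "gene_id", "class"),
          by = "locus_id"
        )
      res$gene_class_methylation <- kw_dunn(
        gm, mcg_score, class, reference = "A"
      )
    }
  }

  if ("proximity" %in% stages) {
    keep <- classified$gene_id[classified$class != "transposon_related"]
    res$nearest_te <- nearest_te(
      dplyr::filter(sim$genes, .data$gene_id %in% keep), sim$tes
    )
    cls_tbl <- dplyr::select(classified, "gene_id", "class") |>
      dplyr::mutate(class = collapse_c_classes(.data$class))
    res$proximity_tests <- distance_class_test(res$nearest_te, cls_tbl)
    res$family_enrichment <- closest_family_enrichment(res$nearest_te, cls_tbl)
  }

  if ("srna" %in% stages) {
    loci <- call_srna_loci(sim$srna_reads)
    # per-(library, replicate) locus counts for the enrichment DE
    locus_counts <- srna_locus_counts(sim$srna_reads, loci)
    samples_by <- function(lib) {
      grep(paste0("^", lib, "_"), setdiff(names(locus_counts), "feature_id"),
           value = TRUE)
    }
    lnorm <- normalize_counts(locus_counts)
    de_ox <- simple_de(lnorm, samples_by("untreated"), samples_by("oxidized"),
                       lfc_threshold = 0)
    de_tr <- simple_de(lnorm, samples_by("untreated"), samples_by("trapr"),
                       lfc_threshold = 0)
    res$srna_enrichment <- classify_srna_enrichment(de_ox, de_tr)
    retained <- dplyr::inner_join(
      loci,
      dplyr::rename(res$srna_enrichment, locus_id = "feature_id"),
      by = "locus_id"
    ) |> dplyr::filter(.data$retained)

    res$srna_origin <- assign_origin(
      retained, sim$tes, expressed_tes, sim$genes, expressed_genes
    )
    res$origin_counts <- dplyr::count(res$srna_origin, .data$origin,
                                      name = "n_loci", .drop = FALSE)
    nuclear <- dplyr::filter(res$srna_origin, .data$chrom != "chrM")
    res$shuffle_null <- shuffle_null_distance(
      dplyr::filter(nuclear, .data$origin %in% c("genic", "unannotated")),
      sim$tes,
      dplyr::filter(sim$chrom_lengths, .data$chrom != "chrM"),
      n_sets = n_shuffles,
      seed = config$seed + 4L
    )
    te_k <- if (!is.null(res$divergence)) {
      dplyr::select(res$divergence, "te_id", "k")
    } else {
      dplyr::select(dplyr::rename(sim$truth$te, k = "planted_k"), "te_id", "k")
    }
    res$srna_production <- te_srna_production(
      nuclear, dplyr::left_join(sim$tes, te_k, by = "te_id")
    )
    res$srna_profiles <- purrr::map(
      stats::setNames(nm = unique(sim$srna_reads$library)),
      function(lib) profile_reads(sim$srna_reads, library = lib)
    )
  }

  res$sim <- sim
  structure(res, class = "mycote_pipeline")
}

# internal: Class C subclasses pooled into one "C" label for the
# proximity panels (subclasses are too small to test individually)
collapse_c_classes <- function(class) {
  cl <- as.character(class)
  dplyr::case_when(
    startsWith(cl, "C_") ~ "C",
    TRUE ~ cl
  )
}

# internal: per-(library, replicate) counts of reads per called locus
srna_locus_counts <- function(reads, loci) {
  hits <- GenomicRanges::findOverlaps(as_granges0(reads), as_granges0(loci))
  ri <- S4Vectors::queryHits(hits)
  li <- S4Vectors::subjectHits(hits)
  rep_col <- if ("replicate" %in% names(reads)) reads$replicate[ri] else 1L
  tab <- tibble::tibble(
    locus_id = loci$locus_id[li],
    sample = sprintf("%s_r%d", reads$library[ri], rep_col),
    count = reads$count[ri]
  ) |>
    dplyr::group_by(.data$locus_id, .data$sample) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "count",
                       values_fill = 0) |>
    dplyr::rename(feature_id = "locus_id")
  # keep locus order
  tab[match(loci$locus_id, tab$feature_id), ]
}

#' @export
print.mycote_pipeline <- function(x, ...) {
  cat("mycoTE pipeline run\n")
  cat(sprintf("  seed: %d\n", x$config$seed))
  if (!is.null(x$landscape)) {
    cat(sprintf("  divergence: %d copies, %d superfamilies\n",
                nrow(x$divergence), length(unique(x$landscape$superfamily))))
  }
  if (!is.null(x$site_fractions)) {
    cat(sprintf("  methylome: %d merged CpG sites (%.1f%% high, %.1f%% low)\n",
                x$site_fractions$n_sites, 100 * x$site_fractions$frac_high,
                100 * x$site_fractions$frac_low))
  }
  if (!is.null(x$class_counts)) {
    cat(sprintf("  genes: %d classified into %d classes\n",
                sum(x$class_counts$n_genes), nrow(x$class_counts)))
  }
  if (!is.null(x$origin_counts)) {
    oc <- stats::setNames(x$origin_counts$n_loci,
                          as.character(x$origin_counts$origin))
    cat(sprintf("  sRNA: %d retained loci (%s)\n", sum(oc),
                paste(sprintf("%s: %d", names(oc), oc), collapse = ", ")))
  }
  invisible(x)
}

#' Write the main pipeline tables to a directory
#'
#' Serialises the tabular results of [run_pipeline()] as TSV files
#' (landscape, site fractions, per-locus methylation, gene classes,
#' proximity tests, sRNA loci with origins, origin counts, shuffle-null
#' test) plus the echoed configuration as a key-value text file.
#'
#' @param result A `mycote_pipeline` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_results <- function(result, dir) {
  stopifnot(inherits(result, "mycote_pipeline"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) {
    if (!is.null(x)) {
      readr::write_tsv(x, file.path(dir, paste0(name, ".tsv")), progress = FALSE)
    }
  }
  wr(result$landscape, "landscape")
  wr(result$site_fractions, "site_fractions")
  wr(result$te_methylation, "te_methylation")
  wr(result$gene_methylation, "gene_methylation")
  wr(dplyr::select(result$gene_classes, "gene_id", "class"), "gene_classes")
  wr(result$nearest_te, "nearest_te")
  wr(result$proximity_tests, "proximity_tests")
  wr(result$family_enrichment, "family_enrichment")
  wr(result$srna_origin, "srna_loci")
  wr(result$origin_counts, "origin_counts")
  if (!is.null(result$shuffle_null)) wr(result$shuffle_null$test, "shuffle_null")
  cfg <- result$config
  scalars <- Filter(function(v) is.atomic(v) && length(v) == 1, cfg)
  writeLines(
    sprintf("%s: %s", names(scalars), vapply(scalars, as.character, character(1))),
    file.path(dir, "config.txt")
  )
  invisible(dir)
}
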