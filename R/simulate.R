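#' Configuration for the synthetic genome generator
#'
#' Builds the full parameter set for simulating a small fungal genome with
#' planted truth: TE copies at known Kimura divergences, genes of known
#' classes (a fraction of the expanded Class C genes placed next to MULE
#' copies), a bimodal CpG methylome conditioned on feature class, 24-nt
#' 5'U/A-biased small RNA reads from young TEs across
#' untreated / oxidized / TraPR libraries (with a mitochondrial contaminant
#' depleted in the treated libraries), and negative-binomial count matrices
#' over a 5-condition x 4-replicate expression design with planted fold
#' changes.
#'
#' Defaults define the reference study conditions used throughout the
#' package's tests: a 2-Mb nuclear genome (2 chromosomes) plus a small
#' mitochondrial contig, ~500 TE copies in 8 families over two divergence
#' waves, ~800 genes, and ~50k sRNA reads.
#'
#' @param seed Integer seed; every generator derives its randomness from it.
#' @param n_chromosomes,chrom_length Nuclear chromosome count and length (bp).
#' @param mito_length Length of the designated mitochondrial contig.
#' @param gc Background GC content.
#' @param te_library Tibble `(family, superfamily, consensus_length)`.
#' @param copy_plan Tibble `(family, n_copies)`; per-copy planted K is drawn
#'   from the two-wave mixture below and copy length as a fraction of the
#'   consensus.
#' @param young_k_range,old_k_range,p_young Divergence waves: planted K is
#'   uniform in `young_k_range` with probability `p_young`, else uniform in
#'   `old_k_range`.
#' @param length_fraction_range Copy length as a fraction of consensus.
#' @param ts_tv_ratio Transition:transversion ratio used to split the
#'   planted K into expected (P, Q) (default 2, i.e. P = 2Q).
#' @param gene_plan Named integer vector of gene counts per class.
#' @param gene_length_range Gene lengths (bp).
#' @param c_near_mule_fraction,c_near_mule_dist Fraction of Class C genes
#'   planted within `c_near_mule_dist` bp downstream of a MULE copy.
#' @param beta_high,beta_low `c(shape1, shape2)` of the high / low
#'   methylation components.
#' @param p_high_by_class Named probabilities of drawing the high component
#'   per feature class (must cover every class the annotation produces).
#' @param meth_coverage_mean Mean per-strand read coverage of methylation
#'   calls.
#' @param p_te_expressed_young,p_te_expressed_old Probability that a TE
#'   copy is expressed, by age (young = K below `srna_young_k`).
#' @param p_gene_expressed Named per-class probabilities of gene expression.
#' @param srna_young_k TEs with planted K below this produce sRNA loci.
#' @param p_srna_per_young_te Probability a young TE hosts an sRNA locus.
#' @param srna_locus_length_range,srna_mean_reads sRNA locus size and mean
#'   untreated read count per locus.
#' @param n_genic_srna,n_unannotated_srna,n_mito_srna Planted loci counts
#'   for the non-TE origins.
#' @param srna_unannot_te_gap Range (bp) of the gap between a planted
#'   unannotated sRNA locus and the TE copy it flanks — non-TE sRNA loci
#'   are planted in the vicinity of TEs, the association the analysis is
#'   designed to detect.
#' @param srna_genic_max_te_gap Genic sRNA loci are planted in expressed
#'   genes whose nearest TE lies within this many bp (closest genes are
#'   used when too few qualify), at the TE-facing end of the gene.
#' @param srna_length_probs Named probabilities over read lengths
#'   (default peaked at 24 nt).
#' @param first_nt_probs Named 5' nucleotide probabilities (U/A biased).
#' @param p_srna_enriched Probability a (non-mito) locus is truly enriched
#'   in each treated assay (independently).
#' @param srna_enrich_factor Count multiplier for truly enriched loci in
#'   the corresponding treated libraries.
#' @param mito_depletion Count multiplier for mitochondrial loci in both
#'   treated libraries (< 1).
#' @param srna_reps Library replicates per treatment.
#' @param conditions,n_reps Expression design (5 conditions x 4 replicates).
#' @param nb_dispersion Negative-binomial dispersion (1/size).
#' @param n_subfamilies_per_family TE subfamily resolution of the count
#'   matrix: each family contributes this many subfamily features, so the
#'   planted differential subfamilies are a small fraction of the matrix
#'   (as in real TE subfamily quantification).
#' @param gene_expr_mean,te_locus_expr_mean,subfamily_expr_mean Baseline
#'   negative-binomial means for expressed features.
#' @param n_de_subfamilies,de_log2fc Subfamilies planted as differential in
#'   the exudate conditions, and their log2 fold change.
#'
#' @return A list of class `mycote_sim_config`.
#' @export
sim_config <- function(
  seed = 1L,
  n_chromosomes = 2L,
  chrom_length = 1e6,
  mito_length = 20000L,
  gc = 0.3,
  te_library = default_te_library(),
  copy_plan = default_copy_plan(),
  young_k_range = c(0.005, 0.06),
  old_k_range = c(0.15, 0.35),
  p_young = 0.5,
  length_fraction_range = c(0.15, 0.5),
  ts_tv_ratio = 2,
  gene_plan = c(
    A = 400L, B_LCN = 150L, B_HCN = 100L,
    C_STY_kinase = 40L, C_CaM_kinase = 20L, C_BTB_POZ = 20L,
    C_Sel1 = 20L, C_Kelch = 20L,
    crinkler = 20L, transposon_related = 10L
  ),
  gene_length_range = c(500L, 1200L),
  c_near_mule_fraction = 0.6,
  c_near_mule_dist = 1000L,
  beta_high = c(50, 2),
  beta_low = c(2, 50),
  p_high_by_class = c(
    te_expressed = 0.1, te_nonexpressed = 0.95,
    gene_A = 0.05, gene_B_LCN = 0.5, gene_B_HCN = 0.5,
    gene_C_STY_kinase = 0.1, gene_C_CaM_kinase = 0.1,
    gene_C_BTB_POZ = 0.1, gene_C_Sel1 = 0.1, gene_C_Kelch = 0.1,
    gene_crinkler = 0.3, gene_transposon_related = 0.8,
    background = 0.3, mito = 0.02
  ),
  meth_coverage_mean = 25,
  p_te_expressed_young = 0.4,
  p_te_expressed_old = 0.1,
  p_gene_expressed = c(
    A = 0.9, B_LCN = 0.5, B_HCN = 0.5,
    C_STY_kinase = 0.7, C_CaM_kinase = 0.7, C_BTB_POZ = 0.7,
    C_Sel1 = 0.7, C_Kelch = 0.7,
    crinkler = 0.5, transposon_related = 0.2
  ),
  srna_young_k = 0.1,
  p_srna_per_young_te = 0.7,
  srna_locus_length_range = c(100L, 300L),
  srna_mean_reads = 60,
  n_genic_srna = 60L,
  n_unannotated_srna = 80L,
  n_mito_srna = 10L,
  srna_unannot_te_gap = c(5L, 150L),
  srna_genic_max_te_gap = 300L,
  srna_length_probs = c(
    "18" = 0.02, "19" = 0.02, "20" = 0.05, "21" = 0.08, "22" = 0.10,
    "23" = 0.15, "24" = 0.35, "25" = 0.12, "26" = 0.06, "27" = 0.03,
    "28" = 0.01, "29" = 0.005, "30" = 0.005
  ),
  first_nt_probs = c(U = 0.5, A = 0.3, C = 0.1, G = 0.1),
  p_srna_enriched = 0.25,
  srna_enrich_factor = 4,
  mito_depletion = 0.05,
  srna_reps = 3L,
  conditions = c("t0", "t24_mock", "t24_exudate", "t48_mock", "t48_exudate"),
  n_reps = 4L,
  nb_dispersion = 0.05,
  n_subfamilies_per_family = 5L,
  gene_expr_mean = 200,
  te_locus_expr_mean = 150,
  subfamily_expr_mean = 500,
  n_de_subfamilies = 3L,
  de_log2fc = 2
) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  structure(cfg, class = "mycote_sim_config")
}

#' Default TE family library for the simulator
#' @return A tibble `(family, superfamily, consensus_length)`.
#' @export
default_te_library <- function() {
  tibble::tibble(
    family = c("Gypsy-1", "Copia-1", "MULE-1", "CMC-1",
               "hAT-1", "LINE-1", "Helitron-1", "TcMar-1"),
    superfamily = c("LTR/Gypsy", "LTR/Copia", "DNA/MULE-MuDR", "DNA/CMC-EnSpm",
                    "DNA/hAT", "LINE", "RC/Helitron", "DNA/TcMar"),
    consensus_length = c(2500L, 2300L, 1800L, 2000L,
                         1500L, 2200L, 1600L, 1200L)
  )
}

#' Default per-family copy numbers (~500 copies)
#' @return A tibble `(family, n_copies)`.
#' @export
default_copy_plan <- function() {
  tibble::tibble(
    family = c("Gypsy-1", "Copia-1", "MULE-1", "CMC-1",
               "hAT-1", "LINE-1", "Helitron-1", "TcMar-1"),
    n_copies = c(70L, 60L, 80L, 60L, 60L, 60L, 55L, 55L)
  )
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_chromosomes >= 1, cfg$chrom_length > 0, cfg$mito_length > 0,
    cfg$gc > 0, cfg$gc < 1, cfg$ts_tv_ratio > 0,
    all(cfg$gene_plan >= 0), all(cfg$copy_plan$n_copies >= 0),
    cfg$c_near_mule_fraction >= 0, cfg$c_near_mule_fraction <= 1,
    all(cfg$beta_high > 0), all(cfg$beta_low > 0),
    all(cfg$p_high_by_class >= 0), all(cfg$p_high_by_class <= 1),
    cfg$mito_depletion >= 0, cfg$mito_depletion <= 1,
    cfg$nb_dispersion > 0,
    length(cfg$conditions) == 5, cfg$n_reps >= 2
  )
  if (abs(sum(cfg$srna_length_probs) - 1) > 1e-8) {
    rlang::abort("`srna_length_probs` must sum to 1")
  }
  if (abs(sum(cfg$first_nt_probs) - 1) > 1e-8) {
    rlang::abort("`first_nt_probs` must sum to 1")
  }
  missing <- setdiff(names(cfg$gene_plan), names(cfg$p_gene_expressed))
  if (length(missing) > 0) {
    rlang::abort(sprintf("`p_gene_expressed` missing class(es): %s",
                         paste(missing, collapse = ", ")))
  }
  invisible(cfg)
}

# internal: random DNA string of given length and GC content
random_dna <- function(n, gc) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

#' Solve the expected (P, Q) substitution proportions for a planted K
#'
#' Given a target Kimura two-parameter distance and a
#' transition:transversion ratio `r` (`P = r Q`), finds the (P, Q) pair
#' whose plug-in K2P distance equals the target. Rejects targets beyond
#' the saturation limit of the model (argument of the log non-positive).
#'
#' @param k Target distance (substitutions/site, >= 0).
#' @param ts_tv_ratio `P/Q` (default 2).
#' @return A list `(p, q)`.
#' @export
kimura_pq_for_k <- function(k, ts_tv_ratio = 2) {
  if (k < 0) rlang::abort("planted K must be >= 0")
  if (k == 0) return(list(p = 0, q = 0))
  r <- ts_tv_ratio
  # admissibility margin: the expected proportions must keep the log
  # arguments clearly positive (1 - 2P - Q >= 0.05), otherwise sampling
  # noise around (P, Q) makes re-estimation blow up — treated as saturated
  q_max <- min(0.95 / (2 * r + 1), 0.5 - 1e-6)
  k_of_q <- function(q) -0.5 * log((1 - (2 * r + 1) * q) * sqrt(1 - 2 * q))
  if (k >= k_of_q(q_max)) {
    rlang::abort(
      sprintf("planted K = %.3f is beyond the K2P saturation limit for ts/tv = %.2f", k, r),
      class = "mycote_saturation_error"
    )
  }
  q <- stats::uniroot(function(q) k_of_q(q) - k, c(1e-12, q_max),
                      tol = 1e-12)$root
  list(p = r * q, q = q)
}

# internal: mutate a consensus fragment to the planted K; returns the copy
# string (same length; substitutions only, no indels)
mutate_to_k <- function(fragment, k, ts_tv_ratio) {
  if (k == 0) return(fragment)
  pq <- kimura_pq_for_k(k, ts_tv_ratio)
  chars <- strsplit(fragment, "", fixed = TRUE)[[1]]
  L <- length(chars)
  n_ts <- stats::rbinom(1, L, pq$p)
  n_tv <- stats::rbinom(1, L, pq$q)
  if (n_ts + n_tv > L) n_tv <- L - n_ts
  pos <- sample.int(L, n_ts + n_tv)
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv_map <- list(A = c("C", "T"), G = c("C", "T"), C = c("A", "G"), T = c("A", "G"))
  if (n_ts > 0) {
    i <- pos[seq_len(n_ts)]
    chars[i] <- ts_map[chars[i]]
  }
  if (n_tv > 0) {
    i <- pos[n_ts + seq_len(n_tv)]
    chars[i] <- vapply(chars[i], function(b) sample(tv_map[[b]], 1), character(1))
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic genome with planted TE copies and genes
#'
#' Builds nuclear chromosomes as random background sequence interleaved
#' with TE copies (each a fragment of its family consensus mutated to a
#' planted Kimura divergence) and gene intervals, plus a designated
#' mitochondrial contig. A configured fraction of Class C genes is placed
#' immediately downstream of a MULE copy to plant the gene-class/TE
#' proximity signal. Coordinates are 0-based half-open and byte-consistent
#' with the emitted sequences; the same config and seed reproduce
#' identical output.
#'
#' @param config A [sim_config()].
#' @return A list with `genome` (a [Biostrings::DNAStringSet]), `tes`,
#'   `alignments`, `genes` (annotation tibbles; `genes` carries `domains`
#'   and `repeat_overlap` but not the planted class), `chrom_lengths`, and
#'   `truth` (list of `te` and `gene` truth tibbles).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "mycote_sim_config"))
  withr::with_seed(config$seed, generate_genome_impl(config))
}

generate_genome_impl <- function(config) {
  lib <- config$te_library
  plan <- dplyr::inner_join(config$copy_plan, lib, by = "family")

  # family consensus sequences
  consensus <- stats::setNames(
    purrr::map_chr(lib$consensus_length, random_dna, gc = config$gc),
    lib$family
  )

  # plan TE copies: planted K from the two-wave mixture, fragment length
  copies <- plan |>
    dplyr::group_by(.data$family) |>
    dplyr::reframe(
      superfamily = .data$superfamily[1],
      consensus_length = .data$consensus_length[1],
      idx = seq_len(.data$n_copies[1])
    ) |>
    dplyr::mutate(
      te_id = sprintf("%s_copy%03d", .data$family, .data$idx),
      planted_k = ifelse(
        stats::runif(dplyr::n()) < config$p_young,
        stats::runif(dplyr::n(), config$young_k_range[1], config$young_k_range[2]),
        stats::runif(dplyr::n(), config$old_k_range[1], config$old_k_range[2])
      ),
      frac = stats::runif(dplyr::n(), config$length_fraction_range[1],
                          config$length_fraction_range[2]),
      length = pmax(50L, as.integer(round(.data$frac * .data$consensus_length)))
    )

  # fragment + mutated copy sequence per TE
  frag_start <- integer(nrow(copies))
  copy_seq <- character(nrow(copies))
  frag_seq <- character(nrow(copies))
  for (i in seq_len(nrow(copies))) {
    cons <- consensus[[copies$family[i]]]
    max_start <- nchar(cons) - copies$length[i]
    fs <- if (max_start > 0) sample.int(max_start + 1L, 1) - 1L else 0L
    frag <- substr(cons, fs + 1L, fs + copies$length[i])
    frag_start[i] <- fs
    frag_seq[i] <- frag
    copy_seq[i] <- mutate_to_k(frag, copies$planted_k[i], config$ts_tv_ratio)
  }
  copies$frag_start <- frag_start

  # TE expression flags by age
  young <- copies$planted_k < config$srna_young_k
  copies$expressed <- stats::runif(nrow(copies)) <
    ifelse(young, config$p_te_expressed_young, config$p_te_expressed_old)

  # plan genes
  gp <- config$gene_plan
  gene_class <- rep(names(gp), gp)
  n_genes <- length(gene_class)
  genes <- tibble::tibble(
    gene_id = sprintf("gene%04d", seq_len(n_genes)),
    class = gene_class,
    length = as.integer(round(stats::runif(
      n_genes, config$gene_length_range[1], config$gene_length_range[2]
    ))),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    domains = purrr::map_chr(gene_class, sample_domains),
    repeat_overlap = gene_class == "B_HCN",
    expressed = stats::runif(n_genes) < config$p_gene_expressed[gene_class]
  )

  # pair a fraction of Class C genes with MULE copies (planted proximity)
  is_c <- startsWith(genes$class, "C_")
  mule_rows <- which(copies$superfamily == "DNA/MULE-MuDR")
  n_pair <- min(length(mule_rows),
                round(config$c_near_mule_fraction * sum(is_c)))
  paired_genes <- sample(which(is_c), n_pair)
  paired_mules <- sample(mule_rows, n_pair)
  genes$near_mule <- FALSE
  genes$near_mule[paired_genes] <- TRUE

  # assemble placement blocks: singleton TEs, singleton genes, and
  # (MULE + gap + Class C gene) compound blocks
  blocks <- list()
  used_te <- rep(FALSE, nrow(copies))
  used_gene <- rep(FALSE, n_genes)
  for (j in seq_len(n_pair)) {
    ti <- paired_mules[j]; gi <- paired_genes[j]
    gap <- as.integer(round(stats::runif(1, 50, config$c_near_mule_dist)))
    blocks[[length(blocks) + 1]] <- list(
      type = "pair", te = ti, gene = gi, gap = gap,
      length = copies$length[ti] + gap + genes$length[gi]
    )
    used_te[ti] <- TRUE; used_gene[gi] <- TRUE
  }
  for (ti in which(!used_te)) {
    blocks[[length(blocks) + 1]] <- list(type = "te", te = ti,
                                         length = copies$length[ti])
  }
  for (gi in which(!used_gene)) {
    blocks[[length(blocks) + 1]] <- list(type = "gene", gene = gi,
                                         length = genes$length[gi])
  }
  blocks <- blocks[sample.int(length(blocks))]

  # distribute blocks over chromosomes proportionally to length budget
  chrom_names <- sprintf("chr%d", seq_len(config$n_chromosomes))
  block_len <- vapply(blocks, function(b) b$length, numeric(1))
  total_feat <- sum(block_len)
  budget <- config$n_chromosomes * config$chrom_length
  if (total_feat >= 0.9 * budget) {
    rlang::abort("planted features exceed 90% of the nuclear genome; enlarge chromosomes")
  }
  chrom_of_block <- sample(rep(seq_len(config$n_chromosomes),
                               length.out = length(blocks)))

  te_rows <- list(); gene_rows <- list(); seqs <- character(0)
  for (ci in seq_len(config$n_chromosomes)) {
    bl <- blocks[chrom_of_block == ci]
    feat_len <- sum(vapply(bl, function(b) b$length, numeric(1)))
    gap_total <- config$chrom_length - feat_len
    if (gap_total < length(bl) + 1) {
      rlang::abort("chromosome overfull; reduce copy/gene plan or lengthen chromosomes")
    }
    cuts <- sort(stats::runif(length(bl), 0, gap_total))
    gaps <- diff(c(0, cuts, gap_total))
    pieces <- character(2 * length(bl) + 1)
    pos <- 0L
    for (k in seq_along(bl)) {
      g <- as.integer(round(gaps[k]))
      pieces[2 * k - 1] <- random_dna(g, config$gc)
      pos <- pos + g
      b <- bl[[k]]
      if (b$type == "te" || b$type == "pair") {
        ti <- b$te
        te_rows[[length(te_rows) + 1]] <- tibble::tibble(
          row = ti, chrom = chrom_names[ci], start = pos,
          end = pos + copies$length[ti]
        )
      }
      if (b$type == "pair") {
        ti <- b$te; gi <- b$gene
        seq_block <- paste0(copy_seq[ti], random_dna(b$gap, config$gc))
        gstart <- pos + copies$length[ti] + b$gap
        gene_rows[[length(gene_rows) + 1]] <- tibble::tibble(
          row = gi, chrom = chrom_names[ci], start = gstart,
          end = gstart + genes$length[gi]
        )
        seq_block <- paste0(seq_block, random_dna(genes$length[gi], config$gc))
        pieces[2 * k] <- seq_block
        pos <- pos + b$length
      } else if (b$type == "te") {
        pieces[2 * k] <- copy_seq[b$te]
        pos <- pos + b$length
      } else {
        gi <- b$gene
        gene_rows[[length(gene_rows) + 1]] <- tibble::tibble(
          row = gi, chrom = chrom_names[ci], start = pos,
          end = pos + genes$length[gi]
        )
        pieces[2 * k] <- random_dna(genes$length[gi], config$gc)
        pos <- pos + b$length
      }
    }
    last_gap <- config$chrom_length - pos
    pieces[2 * length(bl) + 1] <- random_dna(as.integer(last_gap), config$gc)
    seqs <- c(seqs, paste(pieces, collapse = ""))
  }

  mito_seq <- random_dna(config$mito_length, config$gc)
  genome <- Biostrings::DNAStringSet(c(seqs, mito_seq))
  names(genome) <- c(chrom_names, "chrM")

  te_pos <- dplyr::bind_rows(te_rows) |> dplyr::arrange(.data$row)
  gene_pos <- dplyr::bind_rows(gene_rows) |> dplyr::arrange(.data$row)

  tes <- copies[te_pos$row, ] |>
    dplyr::mutate(chrom = te_pos$chrom, start = te_pos$start, end = te_pos$end) |>
    dplyr::select("te_id", "family", "superfamily", "chrom", "start", "end",
                  "length", "planted_k", "expressed")
  alignments <- tibble::tibble(
    te_id = tes$te_id, family = tes$family, superfamily = tes$superfamily,
    chrom = tes$chrom, start = tes$start, end = tes$end,
    consensus_aln = frag_seq[te_pos$row], copy_aln = copy_seq[te_pos$row]
  )
  genes_out <- genes[gene_pos$row, ] |>
    dplyr::mutate(chrom = gene_pos$chrom, start = gene_pos$start,
                  end = gene_pos$end) |>
    dplyr::arrange(.data$chrom, .data$start)
  gene_truth <- genes_out |>
    dplyr::select("gene_id", "class", "near_mule", "expressed")
  genes_ann <- genes_out |>
    dplyr::select("gene_id", "chrom", "start", "end", "strand",
                  "domains", "repeat_overlap")

  chrom_lengths <- tibble::tibble(
    chrom = names(genome), length = Biostrings::width(genome)
  )
  list(
    genome = genome,
    tes = tes |> dplyr::arrange(.data$chrom, .data$start),
    alignments = alignments |> dplyr::arrange(.data$chrom, .data$start),
    genes = genes_ann,
    chrom_lengths = chrom_lengths,
    truth = list(
      te = tes |> dplyr::select("te_id", "family", "superfamily",
                                "planted_k", "length", "expressed"),
      gene = gene_truth
    )
  )
}

# internal: domain labels emitted per planted gene class
sample_domains <- function(class) {
  core <- c("ABC_transporter", "Cytochrome_P450", "Ribosomal_L1",
            "WD40_repeat", "MFS_transporter", "Glycosyl_hydrolase",
            "HSP70_chaperone", "Zn_clus_fungal_TF")
  te_like <- c("Reverse_transcriptase_1", "Transposase_21",
               "Helitron_like_N", "gag-pol_polyprotein", "MULE_transposase")
  switch(class,
    A = sample(core, 1),
    B_LCN = "",
    B_HCN = "",
    C_STY_kinase = "Pkinase_STY",
    C_CaM_kinase = "Calmodulin_dep_kinase",
    C_BTB_POZ = "BTB_POZ_domain",
    C_Sel1 = "Sel1_repeat",
    C_Kelch = "Kelch_motif",
    crinkler = "Crinkler_effector",
    transposon_related = sample(te_like, 1),
    rlang::abort(sprintf("unknown gene class '%s' in gene_plan", class))
  )
}

#' Generate a synthetic CpG methylome
#'
#' Scans the simulated genome for CpG dinucleotides and emits two stranded
#' methylation records per CpG. The site's underlying methylation level is
#' drawn from a two-component beta mixture; the mixing probability depends
#' on the feature class at that position (expressed/non-expressed TE, gene
#' class, background, mito), which is how the TE-silencing signal is
#' planted. Per-strand observed frequencies add binomial sampling noise at
#' the drawn coverage.
#'
#' @param sim Output of [generate_genome()].
#' @param config The same [sim_config()].
#' @return A list with `records` (tibble `chrom, pos, strand, meth_freq,
#'   coverage`) and `site_truth` (tibble `chrom, pos, feature_class,
#'   component, true_level`).
#' @export
generate_methylome <- function(sim, config) {
  stopifnot(inherits(config, "mycote_sim_config"))
  withr::with_seed(config$seed + 1L, generate_methylome_impl(sim, config))
}

generate_methylome_impl <- function(sim, config) {
  cpg <- Biostrings::vmatchPattern("CG", sim$genome)
  sites <- purrr::map2(names(sim$genome), as.list(cpg), function(chrom, ir) {
    tibble::tibble(chrom = chrom, pos = BiocGenerics::start(ir) - 1L)
  }) |> dplyr::bind_rows()
  if (nrow(sites) == 0) return(list(records = tibble::tibble(), site_truth = tibble::tibble()))

  # feature class per site: TE (by expression) > gene (by class) > background
  cls <- rep("background", nrow(sites))
  cls[sites$chrom == "chrM"] <- "mito"
  site_gr <- GenomicRanges::GRanges(sites$chrom,
                                    IRanges::IRanges(sites$pos + 1L, width = 1L))
  gene_cls <- sim$truth$gene$class[match(sim$genes$gene_id, sim$truth$gene$gene_id)]
  gh <- GenomicRanges::findOverlaps(site_gr, as_granges0(sim$genes))
  cls[S4Vectors::queryHits(gh)] <-
    paste0("gene_", gene_cls[S4Vectors::subjectHits(gh)])
  th <- GenomicRanges::findOverlaps(site_gr, as_granges0(sim$tes))
  cls[S4Vectors::queryHits(th)] <- ifelse(
    sim$tes$expressed[S4Vectors::subjectHits(th)], "te_expressed", "te_nonexpressed"
  )

  missing <- setdiff(unique(cls), names(config$p_high_by_class))
  if (length(missing) > 0) {
    rlang::abort(sprintf("`p_high_by_class` missing feature class(es): %s",
                         paste(missing, collapse = ", ")))
  }
  p_high <- config$p_high_by_class[cls]
  high <- stats::runif(nrow(sites)) < p_high
  level <- ifelse(
    high,
    stats::rbeta(nrow(sites), config$beta_high[1], config$beta_high[2]),
    stats::rbeta(nrow(sites), config$beta_low[1], config$beta_low[2])
  )

  strand_rec <- function(strand, pos_shift) {
    cov <- stats::rpois(nrow(sites), config$meth_coverage_mean - 1) + 1L
    tibble::tibble(
      chrom = sites$chrom,
      pos = sites$pos + pos_shift,
      strand = strand,
      meth_freq = stats::rbinom(nrow(sites), cov, level) / cov,
      coverage = cov
    )
  }
  records <- dplyr::bind_rows(strand_rec("+", 0L), strand_rec("-", 1L)) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$strand)
  list(
    records = records,
    site_truth = tibble::tibble(
      chrom = sites$chrom, pos = sites$pos, feature_class = cls,
      component = ifelse(high, "high", "low"), true_level = level
    )
  )
}

#' Generate synthetic small RNA reads in three treatment libraries
#'
#' Plants sRNA-producing loci preferentially in young TE copies (planted K
#' below `srna_young_k`), plus genic loci on expressed genes, loci in
#' unannotated background, and mitochondrial contaminant loci. Reads have a
#' 24-nt-peaked length distribution and a 5' U/A-biased first nucleotide.
#' Truly enriched loci have their expected counts multiplied by
#' `srna_enrich_factor` in the corresponding treated libraries
#' (oxidized / TraPR); mitochondrial loci are scaled by `mito_depletion`
#' in both treated libraries.
#'
#' @param sim Output of [generate_genome()].
#' @param config The same [sim_config()].
#' @return A list with `reads` (tibble `chrom, start, end, strand, length,
#'   first_nt, sequence, library, replicate, count`) and `locus_truth`
#'   (tibble with planted interval, origin, enrichment flags, `is_mito`).
#' @export
generate_srna_reads <- function(sim, config) {
  stopifnot(inherits(config, "mycote_sim_config"))
  if (nrow(sim$tes) == 0 && config$p_srna_per_young_te > 0) {
    rlang::abort("empty TE annotation but srna model requests TE-derived loci")
  }
  withr::with_seed(config$seed + 2L, generate_srna_impl(sim, config))
}

generate_srna_impl <- function(sim, config) {
  lr <- config$srna_locus_length_range
  rand_len <- function(n) as.integer(round(stats::runif(n, lr[1], lr[2])))

  # TE-derived loci from young copies
  young <- dplyr::filter(sim$tes, .data$planted_k < config$srna_young_k)
  host <- young[stats::runif(nrow(young)) < config$p_srna_per_young_te, ]
  te_loci <- if (nrow(host) > 0) {
    len <- pmin(rand_len(nrow(host)), host$end - host$start)
    off <- floor(stats::runif(nrow(host)) * (host$end - host$start - len + 1))
    tibble::tibble(
      chrom = host$chrom, start = as.integer(host$start + off),
      end = as.integer(host$start + off + len),
      origin = ifelse(host$expressed, "TE_expressed", "TE_nonexpressed"),
      host_id = host$te_id
    )
  } else tibble::tibble()

  # genic loci: expressed genes not overlapping a TE, preferring genes whose
  # nearest TE is close; the locus sits at the TE-facing end of the gene
  # (sRNA-producing genes lie in the vicinity of TEs)
  eg <- sim$genes[sim$genes$gene_id %in%
                    sim$truth$gene$gene_id[sim$truth$gene$expressed], ]
  if (nrow(eg) > 0) {
    ov <- GenomicRanges::findOverlaps(as_granges0(eg), as_granges0(sim$tes))
    if (length(ov) > 0) eg <- eg[-unique(S4Vectors::queryHits(ov)), ]
  }
  genic_loci <- if (nrow(eg) > 0 && config$n_genic_srna > 0) {
    nt <- nearest_te(eg, sim$tes)
    eg$te_dist <- nt$distance
    eg$te_start <- sim$tes$start[match(nt$te_id, sim$tes$te_id)]
    eg <- eg[!is.na(eg$te_dist), ]
    near <- which(eg$te_dist <= config$srna_genic_max_te_gap)
    if (length(near) < config$n_genic_srna) {
      near <- order(eg$te_dist)[seq_len(min(config$n_genic_srna, nrow(eg)))]
    }
    pick <- sample(near, min(config$n_genic_srna, length(near)))
    gg <- eg[pick, ]
    len <- pmin(rand_len(nrow(gg)), gg$end - gg$start)
    te_left <- gg$te_start < gg$start
    start <- ifelse(te_left, gg$start, gg$end - len)
    tibble::tibble(
      chrom = gg$chrom, start = as.integer(start),
      end = as.integer(start + len),
      origin = "genic", host_id = gg$gene_id
    )
  } else tibble::tibble()

  # unannotated loci: planted flanking a random TE copy at a small gap,
  # rejected if they touch any annotation
  unann_loci <- {
    ann <- dplyr::bind_rows(
      dplyr::select(sim$tes, "chrom", "start", "end"),
      dplyr::select(sim$genes, "chrom", "start", "end")
    )
    nuc <- dplyr::filter(sim$chrom_lengths, .data$chrom != "chrM")
    gapr <- config$srna_unannot_te_gap
    got <- tibble::tibble()
    tries <- 0
    while (nrow(got) < config$n_unannotated_srna && tries < 200) {
      tries <- tries + 1
      n_draw <- 2 * (config$n_unannotated_srna - nrow(got)) + 5
      ti <- sample.int(nrow(sim$tes), n_draw, replace = TRUE)
      len <- rand_len(n_draw)
      gap <- as.integer(round(stats::runif(n_draw, gapr[1], gapr[2])))
      left_side <- stats::runif(n_draw) < 0.5
      start <- ifelse(left_side,
                      sim$tes$start[ti] - gap - len,
                      sim$tes$end[ti] + gap)
      cand <- tibble::tibble(chrom = sim$tes$chrom[ti],
                             start = as.integer(start),
                             end = as.integer(start + len)) |>
        dplyr::left_join(nuc, by = "chrom") |>
        dplyr::filter(.data$start >= 0, !is.na(.data$length),
                      .data$end <= .data$length) |>
        dplyr::select("chrom", "start", "end")
      if (nrow(cand) > 0) {
        hit <- GenomicRanges::findOverlaps(as_granges0(cand), as_granges0(ann))
        cand <- cand[setdiff(seq_len(nrow(cand)),
                             unique(S4Vectors::queryHits(hit))), ]
        got <- dplyr::bind_rows(got, cand)
      }
    }
    got <- utils::head(got, config$n_unannotated_srna)
    dplyr::mutate(got, origin = "unannotated", host_id = NA_character_)
  }

  mito_len <- sim$chrom_lengths$length[sim$chrom_lengths$chrom == "chrM"]
  mito_loci <- if (config$n_mito_srna > 0) {
    len <- rand_len(config$n_mito_srna)
    start <- floor(stats::runif(config$n_mito_srna) * (mito_len - len))
    tibble::tibble(
      chrom = "chrM", start = as.integer(start), end = as.integer(start + len),
      origin = "unannotated", host_id = NA_character_
    )
  } else tibble::tibble()

  loci <- dplyr::bind_rows(te_loci, genic_loci, unann_loci, mito_loci) |>
    dplyr::mutate(
      locus_id = sprintf("planted_srna%04d", dplyr::row_number()),
      is_mito = .data$chrom == "chrM",
      enriched_oxidized = !.data$is_mito &
        stats::runif(dplyr::n()) < config$p_srna_enriched,
      enriched_trapr = !.data$is_mito &
        stats::runif(dplyr::n()) < config$p_srna_enriched,
      base_mean = stats::rlnorm(dplyr::n(), log(config$srna_mean_reads), 0.4) *
        dplyr::if_else(.data$is_mito, 6, 1),  # mito contaminant is abundant
      strand = sample(c("+", "-"), dplyr::n(), replace = TRUE)
    )

  lens <- as.integer(names(config$srna_length_probs))
  nts <- names(config$first_nt_probs)
  libraries <- c("untreated", "oxidized", "trapr")
  read_rows <- purrr::map(seq_len(nrow(loci)), function(i) {
    lc <- loci[i, ]
    purrr::map(libraries, function(lib) {
      factor <- 1
      if (lib == "oxidized" && lc$enriched_oxidized) factor <- config$srna_enrich_factor
      if (lib == "trapr" && lc$enriched_trapr) factor <- config$srna_enrich_factor
      if (lib != "untreated" && lc$is_mito) factor <- config$mito_depletion
      purrr::map(seq_len(config$srna_reps), function(rep) {
        n <- stats::rpois(1, lc$base_mean * factor / config$srna_reps)
        if (n == 0) return(NULL)
        rl <- sample(lens, n, replace = TRUE, prob = config$srna_length_probs)
        start <- lc$start +
          floor(stats::runif(n) * pmax(lc$end - lc$start - rl, 1))
        first <- sample(nts, n, replace = TRUE, prob = config$first_nt_probs)
        tibble::tibble(
          chrom = lc$chrom, start = as.integer(start),
          end = as.integer(start + rl),
          strand = lc$strand, length = rl, first_nt = first,
          library = lib, replicate = rep, count = 1L
        )
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  # read sequence: first nt fixed (U written as T), remainder random
  seq_tail <- vapply(read_rows$length - 1L, random_dna, character(1),
                     gc = config$gc)
  read_rows$sequence <- paste0(
    ifelse(read_rows$first_nt == "U", "T", read_rows$first_nt), seq_tail
  )

  list(
    reads = read_rows |> dplyr::arrange(.data$chrom, .data$start),
    locus_truth = dplyr::select(
      loci, "locus_id", "chrom", "start", "end", "origin", "host_id",
      "is_mito", "enriched_oxidized", "enriched_trapr", "base_mean"
    )
  )
}

#' Generate negative-binomial count matrices for the expression design
#'
#' Emits counts for genes, TE subfamilies and TE loci over the five
#' developmental conditions (0 h control; 24 h and 48 h, mock and
#' exudate) with `n_reps` replicates each. Expressed features get the
#' configured baseline mean, non-expressed features a near-zero mean, and
#' `n_de_subfamilies` randomly chosen TE subfamilies are shifted by
#' `de_log2fc` in the exudate conditions.
#'
#' @param sim Output of [generate_genome()].
#' @param config The same [sim_config()].
#' @return A list with `samples` (sample sheet), `gene_counts`,
#'   `subfamily_counts`, `te_locus_counts` (counts tibbles) and
#'   `de_truth` (tibble `feature_id, planted_log2fc`).
#' @export
generate_expression_counts <- function(sim, config) {
  stopifnot(inherits(config, "mycote_sim_config"))
  withr::with_seed(config$seed + 3L, generate_counts_impl(sim, config))
}

generate_counts_impl <- function(sim, config) {
  samples <- tidyr::expand_grid(
    condition = config$conditions,
    replicate = seq_len(config$n_reps)
  ) |>
    dplyr::mutate(sample = sprintf("%s_r%d", .data$condition, .data$replicate))
  size <- 1 / config$nb_dispersion
  nb_matrix <- function(mu_matrix) {
    m <- matrix(
      stats::rnbinom(length(mu_matrix), mu = as.vector(mu_matrix), size = size),
      nrow = nrow(mu_matrix), dimnames = dimnames(mu_matrix)
    )
    m
  }

  # genes
  g_expr <- sim$truth$gene$expressed
  g_mu <- ifelse(g_expr,
                 stats::rlnorm(length(g_expr), log(config$gene_expr_mean), 0.6),
                 0)
  gene_mu <- matrix(rep(g_mu, nrow(samples)), ncol = nrow(samples),
                    dimnames = list(sim$truth$gene$gene_id, samples$sample))
  gene_counts <- counts_tibble(nb_matrix(gene_mu))

  # TE subfamilies: several per family, a few planted as differential in
  # the exudate conditions (a small fraction of the matrix, so the
  # median-of-ratios reference stays anchored on null subfamilies)
  fams <- unique(sim$tes$family)
  subfams <- as.vector(vapply(fams, function(f) {
    sprintf("%s_sub%d", f, seq_len(config$n_subfamilies_per_family))
  }, character(config$n_subfamilies_per_family)))
  n_de <- min(config$n_de_subfamilies, length(subfams))
  de_fams <- sample(subfams, n_de)
  sub_mu_base <- stats::rlnorm(length(subfams), log(config$subfamily_expr_mean), 0.5)
  exu <- grepl("exudate", samples$condition)
  sub_mu <- matrix(rep(sub_mu_base, nrow(samples)), ncol = nrow(samples),
                   dimnames = list(subfams, samples$sample))
  sub_mu[de_fams, exu] <- sub_mu[de_fams, exu] * 2^config$de_log2fc
  subfamily_counts <- counts_tibble(nb_matrix(sub_mu))

  # TE loci: expressed copies get the baseline mean
  te_mu <- ifelse(sim$tes$expressed,
                  stats::rlnorm(nrow(sim$tes), log(config$te_locus_expr_mean), 0.5),
                  0)
  te_mu_m <- matrix(rep(te_mu, nrow(samples)), ncol = nrow(samples),
                    dimnames = list(sim$tes$te_id, samples$sample))
  te_locus_counts <- counts_tibble(nb_matrix(te_mu_m))

  list(
    samples = samples,
    gene_counts = gene_counts,
    subfamily_counts = subfamily_counts,
    te_locus_counts = te_locus_counts,
    de_truth = tibble::tibble(
      feature_id = subfams,
      planted_log2fc = ifelse(subfams %in% de_fams, config$de_log2fc, 0)
    )
  )
}

#' Generate the complete synthetic dataset
#'
#' Runs all four generators in order under the config's seed and collects
#' their outputs plus the combined truth tables.
#'
#' @param config A [sim_config()].
#' @return A list with `genome`, `tes`, `alignments`, `genes`,
#'   `chrom_lengths`, `methylation` (records), `srna_reads`, `counts`
#'   (list from [generate_expression_counts()]) and `truth` (list with
#'   `te`, `gene`, `methylation_sites`, `srna_loci`, `de`).
#' @export
simulate_dataset <- function(config = sim_config()) {
  g <- generate_genome(config)
  meth <- generate_methylome(g, config)
  srna <- generate_srna_reads(g, config)
  counts <- generate_expression_counts(g, config)
  list(
    genome = g$genome, tes = g$tes, alignments = g$alignments,
    genes = g$genes, chrom_lengths = g$chrom_lengths,
    methylation = meth$records, srna_reads = srna$reads, counts = counts,
    config = config,
    truth = list(
      te = g$truth$te, gene = g$truth$gene,
      methylation_sites = meth$site_truth,
      srna_loci = srna$locus_truth,
      de = counts$de_truth
    )
  )
}
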