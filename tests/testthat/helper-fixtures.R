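# Shared fixtures and independent oracles for the test suite.

# a scaled-down simulation config for fast end-to-end tests; explicit
# arguments in ... override the scaled defaults
small_config <- function(seed = 7L, ...) {
  defaults <- list(
    seed = seed,
    n_chromosomes = 2L,
    chrom_length = 2e5,
    mito_length = 8000L,
    copy_plan = dplyr::mutate(default_copy_plan(), n_copies = 10L),
    gene_plan = c(
      A = 60L, B_LCN = 25L, B_HCN = 20L,
      C_STY_kinase = 8L, C_CaM_kinase = 5L, C_BTB_POZ = 5L,
      C_Sel1 = 5L, C_Kelch = 5L,
      crinkler = 5L, transposon_related = 4L
    ),
    srna_mean_reads = 40,
    n_genic_srna = 20L,
    n_unannotated_srna = 25L,
    n_mito_srna = 5L
  )
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# brute-force sort-based median (oracle for score_loci)
oracle_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n == 0) return(NA_real_)
  if (n %% 2 == 1) s[(n + 1) / 2] else mean(s[c(n / 2, n / 2 + 1)])
}

# brute-force BH step-up (oracle for bh_adjust)
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# full-enumeration two-sided Fisher p (oracle for fisher_exact_2x2)
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  prob_of <- function(x) {
    choose(r1, x) * choose(r2, c1 - x) / choose(n, c1)
  }
  p_obs <- prob_of(a)
  sum(vapply(lo:hi, function(x) {
    p <- prob_of(x)
    if (p <= p_obs * (1 + 1e-7)) p else 0
  }, numeric(1)))
}

# Kruskal-Wallis H from first principles on pooled ranks with tie
# correction (oracle for kw_h_test / kruskal.test)
oracle_kw_h <- function(groups) {
  x <- unlist(groups)
  n <- length(x)
  r <- rank(x)
  idx <- rep(seq_along(groups), lengths(groups))
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, idx, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
  ties <- table(x)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h / correction
}

# brute-force nearest-TE scan (oracle for nearest_te)
oracle_nearest <- function(genes, tes) {
  purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    ts <- tes[tes$chrom == genes$chrom[i], ]
    if (nrow(ts) == 0) {
      return(tibble::tibble(gene_id = genes$gene_id[i],
                            te_id = NA_character_, distance = NA_integer_))
    }
    d <- vapply(seq_len(nrow(ts)), function(j) {
      max(0, ts$start[j] - genes$end[i], genes$start[i] - ts$end[j])
    }, numeric(1))
    ord <- order(d, ts$start, ts$te_id)
    tibble::tibble(gene_id = genes$gene_id[i], te_id = ts$te_id[ord[1]],
                   distance = as.integer(d[ord[1]]))
  })
}

# random interval set on a toy assembly
random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000,
                            max_len = 500, prefix = "iv") {
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  tibble::tibble(
    id = sprintf("%s%03d", prefix, seq_len(n)),
    chrom = sample(chroms, n, replace = TRUE),
    start = start, end = start + len
  )
}
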