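#' Nearest classified TE per gene
#'
#' For every gene, finds the classified TE copy on the same chromosome with
#' the smallest edge-to-edge distance (0 when the intervals overlap;
#' strand-agnostic). Ties are broken by leftmost TE start, then smallest
#' `te_id`. Genes on chromosomes without any TE get an `NA` record and are
#' counted in the `n_undefined` attribute.
#'
#' @param genes A data frame with `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param tes A data frame of classified TE copies with `te_id`, `chrom`,
#'   `start`, `end` and optionally `family`, `superfamily` (carried
#'   through).
#'
#' @return A tibble `(gene_id, te_id, family, superfamily, distance)`, one
#'   row per gene in input order.
#' @export
nearest_te <- function(genes, tes) {
  check_columns(genes, "gene_id")
  check_intervals(genes)
  check_columns(tes, "te_id")
  check_intervals(tes)

  te_cols <- intersect(c("family", "superfamily"), names(tes))
  # TEs pre-sorted by (start, te_id) per chromosome so that the first
  # minimum-distance column realises the tie rule (leftmost start, then
  # smallest id)
  te_tbl <- tibble::as_tibble(tes) |>
    dplyr::arrange(.data$chrom, .data$start, .data$te_id)

  out <- tibble::tibble(
    gene_id = genes$gene_id, te_id = NA_character_, distance = NA_integer_
  )
  for (cc in te_cols) out[[cc]] <- NA_character_
  for (chr in unique(genes$chrom)) {
    gi <- which(genes$chrom == chr)
    ts <- te_tbl[te_tbl$chrom == chr, , drop = FALSE]
    if (nrow(ts) == 0) next
    d <- outer(genes$start[gi], ts$end, function(gs, te) gs - te)
    d2 <- outer(genes$end[gi], ts$start, function(ge, tstart) tstart - ge)
    d <- pmax(d, d2, 0L)
    j <- max.col(-d, ties.method = "first")
    out$te_id[gi] <- ts$te_id[j]
    out$distance[gi] <- as.integer(d[cbind(seq_along(gi), j)])
    for (cc in te_cols) out[[cc]][gi] <- ts[[cc]][j]
  }
  out <- out[, c("gene_id", "te_id", te_cols, "distance")]
  attr(out, "n_undefined") <- sum(is.na(out$distance))
  out
}

#' Kruskal-Wallis comparison of nearest-TE distances per gene class
#'
#' For each TE family and each gene class, compares the nearest-TE distance
#' distribution of that class against the reference class (default Class A
#' core genes), restricted to genes whose closest TE belongs to the given
#' family. The rank-based Kruskal-Wallis H statistic (with tie correction,
#' chi-square approximation) is used; p-values are Benjamini-Hochberg
#' adjusted across all comparisons made in the call.
#'
#' @param nearest Output of [nearest_te()] (needs `gene_id`, `family`,
#'   `distance`).
#' @param classes A data frame `(gene_id, class)`.
#' @param reference Reference class (default `"A"`).
#' @param min_n Comparisons where either group has fewer observations are
#'   skipped (`skipped = TRUE`, `p = NA`); default 2.
#'
#' @return A tibble `(family, class, statistic, p, p_adj, n_ref, n_class,
#'   skipped)`. Genes classified `transposon_related` are excluded (they
#'   are themselves TE-derived).
#' @export
distance_class_test <- function(nearest, classes, reference = "A", min_n = 2L) {
  check_columns(nearest, c("gene_id", "family", "distance"))
  check_columns(classes, c("gene_id", "class"))
  dat <- nearest |>
    dplyr::inner_join(
      dplyr::mutate(tibble::as_tibble(classes), class = as.character(.data$class)),
      by = "gene_id"
    ) |>
    dplyr::filter(!is.na(.data$distance), .data$class != "transposon_related")
  other <- setdiff(unique(dat$class), reference)
  fams <- unique(dat$family)

  rows <- purrr::map(fams, function(fam) {
    ref_d <- dat$distance[dat$family == fam & dat$class == reference]
    purrr::map(other, function(cl) {
      cl_d <- dat$distance[dat$family == fam & dat$class == cl]
      if (length(ref_d) < min_n || length(cl_d) < min_n) {
        return(tibble::tibble(
          family = fam, class = cl, statistic = NA_real_, p = NA_real_,
          n_ref = length(ref_d), n_class = length(cl_d), skipped = TRUE
        ))
      }
      kw <- kw_h_test(list(cl_d, ref_d))
      tibble::tibble(
        family = fam, class = cl, statistic = kw$statistic, p = kw$p,
        n_ref = length(ref_d), n_class = length(cl_d), skipped = FALSE
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  rows$p_adj <- NA_real_
  rows$p_adj[!rows$skipped] <- stats::p.adjust(rows$p[!rows$skipped], method = "BH")
  dplyr::select(
    rows, "family", "class", "statistic", "p", "p_adj",
    "n_ref", "n_class", "skipped"
  )
}

# internal: Kruskal-Wallis H with tie correction via stats::kruskal.test,
# with the all-identical degenerate case defined as H = 0, p = 1
kw_h_test <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1) {
    return(list(statistic = 0, p = 1, df = length(groups) - 1))
  }
  kt <- stats::kruskal.test(x, g)
  list(statistic = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter))
}

#' Fisher exact test on a 2x2 contingency table
#'
#' Two-sided exact p-value computed by summing hypergeometric probabilities
#' of all tables (with the observed margins) whose probability does not
#' exceed that of the observed table. The odds ratio is the sample odds
#' ratio `(a d)/(b c)`, with a Haldane correction (+0.5 to every cell) when
#' any cell is zero.
#'
#' @param a,b,c,d Non-negative integer cell counts, rows = groups, columns
#'   = outcome: `matrix(c(a, b, c, d), 2, 2, byrow = TRUE)`.
#' @return A one-row tibble `(odds_ratio, p)`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    rlang::abort("cell counts must be non-negative integers")
  }
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 + r2 == 0) rlang::abort("empty table")
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  support <- lo:hi
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  p <- min(p, 1)
  or <- if (any(cells == 0)) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    (a * d) / (b * c)
  }
  tibble::tibble(odds_ratio = or, p = p)
}

#' Enrichment of a TE family as the closest element to a gene class
#'
#' For each gene class (vs the reference class) and each TE family, builds
#' the 2x2 table "closest TE is family F / is not" x "class X / reference"
#' and applies the two-sided Fisher exact test — is family F
#' over-represented next to class X genes relative to core genes?
#'
#' @inheritParams distance_class_test
#' @param family Optional character vector restricting the TE families
#'   tested (default: all families present).
#' @return A tibble `(family, class, a, b, c, d, odds_ratio, p, p_adj,
#'   skipped)` where `a` counts class-X genes with family F closest, `b`
#'   the other class-X genes, and `c`, `d` the same for the reference
#'   class; BH adjustment spans all comparisons in the call.
#' @export
closest_family_enrichment <- function(nearest, classes, family = NULL,
                                      reference = "A") {
  check_columns(nearest, c("gene_id", "family", "distance"))
  check_columns(classes, c("gene_id", "class"))
  dat <- nearest |>
    dplyr::inner_join(
      dplyr::mutate(tibble::as_tibble(classes), class = as.character(.data$class)),
      by = "gene_id"
    ) |>
    dplyr::filter(!is.na(.data$distance), .data$class != "transposon_related")
  fams <- family %||% unique(dat$family)
  other <- setdiff(unique(dat$class), reference)

  rows <- purrr::map(fams, function(fam) {
    purrr::map(other, function(cl) {
      in_cl <- dat$class == cl
      in_ref <- dat$class == reference
      a <- sum(in_cl & dat$family == fam)
      b <- sum(in_cl & dat$family != fam)
      c_ <- sum(in_ref & dat$family == fam)
      d <- sum(in_ref & dat$family != fam)
      if (a + b == 0 || c_ + d == 0) {
        return(tibble::tibble(
          family = fam, class = cl, a = a, b = b, c = c_, d = d,
          odds_ratio = NA_real_, p = NA_real_, skipped = TRUE
        ))
      }
      ft <- fisher_exact_2x2(a, b, c_, d)
      tibble::tibble(
        family = fam, class = cl, a = a, b = b, c = c_, d = d,
        odds_ratio = ft$odds_ratio, p = ft$p, skipped = FALSE
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  rows$p_adj <- NA_real_
  rows$p_adj[!rows$skipped] <- stats::p.adjust(rows$p[!rows$skipped], method = "BH")
  rows
}

#' Kruskal-Wallis test with Dunn post hoc comparisons to a reference group
#'
#' Overall Kruskal-Wallis H across all groups, followed by Dunn's
#' rank-based z comparisons of every group against the reference group, on
#' pooled ranks with tie correction, Benjamini-Hochberg adjusted across the
#' reported family of comparisons. This is the standard non-parametric
#' many-groups-vs-control analysis for, e.g., per-class mCG score
#' distributions.
#'
#' @param data A data frame.
#' @param value,group Column names (tidy-eval) holding the measurement and
#'   the group label.
#' @param reference The control group every other group is compared to.
#'
#' @return An object of class `mycote_kw_dunn`: use [tidy()] for the
#'   pairwise table `(group, reference, z, p, p_adj, n)` and [glance()] for
#'   the overall test `(statistic, df, p_value, n_groups, n_obs)`.
#' @export
kw_dunn <- function(data, value, group, reference = "A") {
  value <- rlang::enquo(value)
  group <- rlang::enquo(group)
  x <- rlang::eval_tidy(value, data)
  g <- as.character(rlang::eval_tidy(group, data))
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- g[keep]
  if (length(unique(g)) < 2) rlang::abort("need at least 2 groups")
  if (min(table(g)) < 2) rlang::abort("every group needs n >= 2")
  if (!reference %in% g) rlang::abort(sprintf("reference group '%s' not present", reference))

  groups <- split(x, g)
  overall <- kw_h_test(groups)

  n <- length(x)
  r <- rank(x)
  # tie correction for the pooled-rank variance
  tie_sizes <- table(x)
  tie_term <- sum(tie_sizes^3 - tie_sizes) / (12 * (n - 1))
  mean_ranks <- tapply(r, g, mean)
  ns <- tapply(r, g, length)

  others <- setdiff(names(groups), reference)
  if (length(unique(x)) == 1) {
    z <- rep(0, length(others))
  } else {
    z <- vapply(others, function(cl) {
      se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / ns[[cl]] + 1 / ns[[reference]]))
      (mean_ranks[[cl]] - mean_ranks[[reference]]) / se
    }, numeric(1))
  }
  p <- 2 * stats::pnorm(-abs(z))
  pairwise <- tibble::tibble(
    group = others, reference = reference, z = unname(z), p = unname(p),
    p_adj = stats::p.adjust(p, method = "BH"),
    n = unname(as.integer(ns[others]))
  )
  structure(
    list(statistic = overall$statistic, df = overall$df, p_value = overall$p,
         pairwise = pairwise, n_groups = length(groups), n_obs = n),
    class = "mycote_kw_dunn"
  )
}

#' @export
print.mycote_kw_dunn <- function(x, ...) {
  cat(sprintf(
    "Kruskal-Wallis: H = %.3f, df = %d, p = %.3g (%d groups, n = %d)\n",
    x$statistic, x$df, x$p_value, x$n_groups, x$n_obs
  ))
  cat(sprintf("Dunn comparisons vs '%s':\n", x$pairwise$reference[1]))
  print(x$pairwise, ...)
  invisible(x)
}
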