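#' @import ggplot2
NULL

#' Plot a repeat divergence landscape
#'
#' Stacked genome-coverage bars per Kimura-percent bin, coloured by TE
#' superfamily: young expansions pile up on the left, old decayed copies
#' trail right.
#'
#' @param landscape Output of [build_landscape()].
#' @return A ggplot object.
#' @export
plot_landscape <- function(landscape) {
  check_columns(landscape, c("superfamily", "bin", "coverage_pct"))
  ggplot(landscape, aes(x = .data$bin, y = .data$coverage_pct,
                        fill = .data$superfamily)) +
    geom_col(width = 1) +
    labs(x = "Kimura distance (CpG adjusted, %)",
         y = "Genome coverage (%)", fill = "Superfamily") +
    theme_minimal()
}

#' Plot a metagene methylation profile
#'
#' @param profile Output of [metagene_profile()].
#' @return A ggplot object with upstream / body / downstream panels.
#' @export
plot_metagene <- function(profile) {
  check_columns(profile, c("segment", "bin", "mean_mcg"))
  ggplot(profile, aes(x = .data$bin, y = .data$mean_mcg)) +
    geom_line(na.rm = TRUE) +
    facet_grid(~.data$segment, scales = "free_x", space = "free_x") +
    labs(x = "Bin (5' to 3')", y = "Mean mCG") +
    ylim(0, 1) +
    theme_minimal()
}

#' Plot an sRNA length x first-nucleotide profile
#'
#' Stacked read counts per read length, coloured by 5' nucleotide — the
#' standard Dicer/Argonaute diagnostic plot.
#'
#' @param profile Output of [profile_reads()].
#' @return A ggplot object.
#' @export
plot_srna_profile <- function(profile) {
  check_columns(profile, c("length", "A", "C", "G", "U"))
  long <- tidyr::pivot_longer(profile, c("A", "C", "G", "U"),
                              names_to = "first_nt", values_to = "n")
  ggplot(long, aes(x = .data$length, y = .data$n, fill = .data$first_nt)) +
    geom_col() +
    labs(x = "Read length (nt)", y = "Reads", fill = "5' nt") +
    theme_minimal()
}

#' Plot sRNA locus origin counts
#'
#' @param origin_counts A tibble `(origin, n_loci)` as produced by
#'   [run_pipeline()].
#' @return A ggplot bar chart.
#' @export
plot_origin_counts <- function(origin_counts) {
  check_columns(origin_counts, c("origin", "n_loci"))
  ggplot(origin_counts, aes(x = .data$origin, y = .data$n_loci,
                            fill = .data$origin)) +
    geom_col(show.legend = FALSE) +
    labs(x = "Genomic origin", y = "sRNA loci") +
    theme_minimal()
}

#' MA-style plot for a simplified differential result
#'
#' @param object A `mycote_de` object from [simple_de()].
#' @param ... Unused.
#' @return A ggplot object: mean normalised count (log10) vs log2 fold
#'   change, significant features highlighted.
#' @export
autoplot.mycote_de <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  ggplot(dat, aes(x = log10((.data$mean_a + .data$mean_b) / 2 + 1),
                  y = .data$log2fc, colour = .data$significant)) +
    geom_point(alpha = 0.7) +
    scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "red")) +
    labs(x = "log10 mean normalised count", y = "log2 fold change",
         colour = "Significant") +
    theme_minimal()
}

#' Plot observed vs shuffled nearest-TE distance distributions
#'
#' @param object A `mycote_shuffle_null` object.
#' @param ... Unused.
#' @return A ggplot boxplot on log10(distance + 1).
#' @export
autoplot.mycote_shuffle_null <- function(object, ...) {
  dat <- dplyr::bind_rows(
    dplyr::mutate(object$observed, set = "observed"),
    dplyr::mutate(object$shuffled, set = "shuffled")
  )
  ggplot(dat, aes(x = .data$set, y = log10(.data$distance + 1))) +
    geom_boxplot() +
    labs(x = NULL, y = "log10(distance to nearest TE + 1)") +
    theme_minimal()
}
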