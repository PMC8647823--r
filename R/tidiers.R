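#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a Kruskal-Wallis / Dunn result
#'
#' @param x A `mycote_kw_dunn` object from [kw_dunn()].
#' @param ... Unused.
#' @return The pairwise comparison tibble `(group, reference, z, p, p_adj,
#'   n)`.
#' @export
tidy.mycote_kw_dunn <- function(x, ...) {
  x$pairwise
}

#' @rdname tidy.mycote_kw_dunn
#' @return `glance()`: a one-row tibble `(statistic, df, p_value, n_groups,
#'   n_obs)`.
#' @export
glance.mycote_kw_dunn <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, df = x$df, p_value = x$p_value,
    n_groups = x$n_groups, n_obs = x$n_obs
  )
}

#' Tidy a shuffled-locus null result
#'
#' @param x A `mycote_shuffle_null` object from [shuffle_null_distance()].
#' @param ... Unused.
#' @return The pooled per-locus distance tibble with a `set` column
#'   (`"observed"` / `"shuffled"`).
#' @export
tidy.mycote_shuffle_null <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$observed, set = "observed"),
    dplyr::mutate(dplyr::select(x$shuffled, -"set"), set = "shuffled")
  )
}

#' @rdname tidy.mycote_shuffle_null
#' @return `glance()`: the one-row test summary.
#' @export
glance.mycote_shuffle_null <- function(x, ...) {
  x$test
}

#' Tidy a simplified differential result
#'
#' @param x A `mycote_de` object from [simple_de()].
#' @param ... Unused.
#' @return `tidy()`: the per-feature result tibble; `glance()`: one row
#'   with the thresholds and significant-feature count.
#' @export
tidy.mycote_de <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "mycote_de")
  out
}

#' @rdname tidy.mycote_de
#' @export
glance.mycote_de <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x),
    n_significant = sum(x$significant),
    lfc_threshold = attr(x, "lfc_threshold"),
    fdr_threshold = attr(x, "fdr_threshold")
  )
}
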