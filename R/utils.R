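#' @importFrom rlang %||% abort warn .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join bind_rows n row_number across all_of if_else rename
#'   distinct pull count slice everything
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median p.adjust rbinom rnbinom rpois runif rbeta setNames
#'   kruskal.test pnorm dhyper t.test uniroot quantile sd var
#' @importFrom utils head tail
NULL

# internal: check a tibble has the named columns
check_columns <- function(x, cols, arg = deparse(substitute(x))) {
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    rlang::abort(sprintf(
      "`%s` is missing required column(s): %s",
      arg, paste(missing, collapse = ", ")
    ))
  }
  invisible(x)
}

# internal: validate 0-based half-open intervals
check_intervals <- function(x, arg = deparse(substitute(x))) {
  check_columns(x, c("chrom", "start", "end"), arg)
  bad <- which(x$end <= x$start)
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "`%s` has %d malformed interval(s) (end <= start), first at row %d",
      arg, length(bad), bad[1]
    ))
  }
  invisible(x)
}

# internal: 0-based half-open tibble -> GRanges (1-based closed inside GRanges)
as_granges0 <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

# internal: edge-to-edge distance between two half-open intervals (vectorised)
interval_gap <- function(start1, end1, start2, end2) {
  pmax(0L, pmax(start2 - end1, start1 - end2))
}

# internal: weighted modal value; ties broken by smallest value
weighted_mode <- function(x, w) {
  tab <- tapply(w, factor(x, levels = sort(unique(x))), sum)
  as.numeric(names(tab)[which.max(tab)])
}
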