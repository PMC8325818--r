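## Per-sample quantification: total and relative counts.

#' Per-sample total and relative gene counts
#'
#' Tallies reads per gene within each sample (or within each ROI of a named
#' list), and derives the companion frequency matrix in which each row is
#' normalized by its sample's total. The gene panel of the output is the
#' union of genes across samples, sorted lexicographically, so column order
#' is reproducible.
#'
#' @param spots a [spot_table].
#' @param rois optional named list of `c(xmin, xmax, ymin, ymax)` boxes; when
#'   given, grouping is by ROI (a read may fall in several overlapping ROIs)
#'   instead of by the sample column.
#' @return A list of class `count_matrix` with elements `counts`
#'   (samples x genes, integer) and `frequencies` (rows summing to 1; a
#'   zero-read sample yields an all-zero row with a warning).
#' @examples
#' ct <- total_counts(spot_table(c("A", "A", "B"), c(0, 1, 2), c(0, 0, 0)))
#' ct$frequencies
#' @export
total_counts <- function(spots, rois = NULL) {
  stopifnot(inherits(spots, "spot_table"))
  if (nrow(spots) == 0L) stop("no reads to count")
  if (is.null(rois)) {
    groups <- unique(spots$sample)
    per_group <- lapply(groups, function(s) spots[spots$sample == s, ])
  } else {
    if (is.null(names(rois)) || any(!nzchar(names(rois))))
      stop("rois must be a named list of boxes")
    groups <- names(rois)
    per_group <- lapply(rois, function(r) select_roi(spots, r))
  }
  genes <- sort(unique(spots$gene))
  counts <- matrix(0L, length(groups), length(genes),
                   dimnames = list(groups, genes))
  for (i in seq_along(groups)) {
    tab <- table(factor(per_group[[i]]$gene, levels = genes))
    counts[i, ] <- as.integer(tab)
  }
  totals <- rowSums(counts)
  freq <- counts / ifelse(totals == 0, 1, totals)
  if (any(totals == 0))
    warning("sample(s) with zero reads get an all-zero frequency row: ",
            paste(groups[totals == 0], collapse = ", "))
  structure(list(counts = counts, frequencies = freq),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d sample(s) x %d genes, %d reads\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Bar plot of total (or relative) counts per gene
#'
#' @param x a `count_matrix` from [total_counts()].
#' @param relative plot frequencies instead of raw counts.
#' @param ... passed to [graphics::barplot()].
#' @return The bar midpoints, invisibly.
#' @export
plot_total_counts <- function(x, relative = FALSE, ...) {
  stopifnot(inherits(x, "count_matrix"))
  m <- if (relative) x$frequencies else x$counts
  graphics::barplot(m, beside = TRUE, las = 2,
                    legend.text = nrow(m) > 1,
                    ylab = if (relative) "frequency" else "reads", ...)
}
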