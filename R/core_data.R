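## Core data model: spot tables, nuclear images, segmented maps, class
## references, and their delimited-text I/O.

#' Construct a spot table
#'
#' A spot table holds one row per decoded read: a gene label and continuous
#' 2D pixel coordinates, plus a sample/ROI identifier. It is the entry point
#' of every read-level analysis in spotmap.
#'
#' @param gene character vector of gene labels, one per read. Matching is
#'   case-sensitive exact string match throughout the package.
#' @param x,y numeric pixel coordinates (origin top-left, y downward).
#' @param sample optional sample/ROI id per read; when absent all reads get
#'   `"sample_1"`.
#' @return A `data.frame` of class `spot_table` with columns
#'   `gene`, `x`, `y`, `sample`. Row order carries no meaning.
#' @examples
#' spot_table(c("Gad1", "Rorb"), x = c(1, 2), y = c(3, 4))
#' @export
spot_table <- function(gene, x, y, sample = NULL) {
  gene <- as.character(gene)
  x <- as.numeric(x)
  y <- as.numeric(y)
  n <- length(gene)
  if (length(x) != n || length(y) != n)
    stop("gene, x and y must have equal length")
  if (n == 0L) stop("a spot table must contain at least one read")
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y)))
    stop("spot coordinates must be finite and non-missing")
  if (anyNA(gene) || any(!nzchar(gene)))
    stop("every gene label must be a nonempty string")
  if (is.null(sample)) sample <- rep("sample_1", n)
  sample <- as.character(sample)
  if (length(sample) != n) stop("sample must have one entry per read")
  out <- data.frame(gene = gene, x = x, y = y, sample = sample,
                    stringsAsFactors = FALSE)
  class(out) <- c("spot_table", "data.frame")
  out
}

#' @export
print.spot_table <- function(x, ...) {
  cat(sprintf("spot_table: %d reads, %d genes, %d sample(s)\n",
              nrow(x), length(unique(x$gene)), length(unique(x$sample))))
  cat(sprintf("  x range [%.1f, %.1f], y range [%.1f, %.1f]\n",
              min(x$x), max(x$x), min(x$y), max(x$y)))
  print.data.frame(head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more reads\n", nrow(x) - 6L))
  invisible(x)
}

#' Read a spot table from delimited text
#'
#' Rows whose coordinates cannot be parsed as finite numbers are dropped;
#' the number dropped is attached as attribute `n_dropped` and reported.
#'
#' @param path path to a delimited text file with a header row.
#' @param gene_col,x_col,y_col,sample_col column names holding the gene
#'   label, coordinates and (optionally) the sample id. `sample_col = NULL`
#'   assigns `"sample_1"` to every read.
#' @param delimiter field delimiter, default comma.
#' @param flip_y if `TRUE`, y is negated and shifted so data recorded with y
#'   increasing upward land in the package's image convention.
#' @return A [spot_table] with attribute `n_dropped`.
#' @export
read_spot_table <- function(path, gene_col = "gene", x_col = "x", y_col = "y",
                            sample_col = "sample", delimiter = ",",
                            flip_y = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (nrow(raw) == 0L) stop("empty spot table: ", path)
  for (col in c(gene_col, x_col, y_col)) {
    if (!col %in% names(raw))
      stop("mapped column '", col, "' not present in ", path)
  }
  x <- suppressWarnings(as.numeric(raw[[x_col]]))
  y <- suppressWarnings(as.numeric(raw[[y_col]]))
  ok <- is.finite(x) & is.finite(y)
  n_dropped <- sum(!ok)
  if (n_dropped > 0L)
    message(n_dropped, " row(s) with unparseable coordinates dropped")
  if (!any(ok)) stop("no rows with parseable coordinates in ", path)
  smp <- if (!is.null(sample_col) && sample_col %in% names(raw))
    raw[[sample_col]][ok] else NULL
  yy <- y[ok]
  if (flip_y) yy <- max(yy) - yy
  out <- spot_table(raw[[gene_col]][ok], x[ok], yy, smp)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write a spot table to delimited text
#'
#' @param spots a [spot_table].
#' @param path output file path.
#' @param delimiter field delimiter.
#' @return `path`, invisibly.
#' @export
write_spot_table <- function(spots, path, delimiter = ",") {
  stopifnot(inherits(spots, "spot_table"))
  utils::write.table(as.data.frame(spots), path, sep = delimiter,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Select reads inside a rectangular region of interest
#'
#' The box is half-open, `[xmin, xmax) x [ymin, ymax)`, so a set of tiled
#' ROIs partitions the reads exactly: a read on a shared edge belongs to one
#' tile only.
#'
#' @param spots a [spot_table].
#' @param rect numeric vector `c(xmin, xmax, ymin, ymax)`.
#' @return The subset [spot_table]; may have zero rows.
#' @export
select_roi <- function(spots, rect) {
  stopifnot(inherits(spots, "spot_table"), length(rect) == 4)
  rect <- as.numeric(rect)
  if (rect[1] >= rect[2] || rect[3] >= rect[4])
    stop("rect must satisfy xmin < xmax and ymin < ymax")
  keep <- spots$x >= rect[1] & spots$x < rect[2] &
          spots$y >= rect[3] & spots$y < rect[4]
  out <- spots[keep, , drop = FALSE]
  class(out) <- c("spot_table", "data.frame")
  rownames(out) <- NULL
  out
}

#' Construct a scRNA-seq class reference
#'
#' Mean expression of each cell-type class for the genes in the panel,
#' as estimated from scRNA-seq. Used by [pciseq_assign()].
#'
#' @param means numeric classes x genes matrix, nonnegative, with class
#'   labels as rownames and gene labels as colnames.
#' @return An object of class `class_reference`.
#' @export
class_reference <- function(means) {
  means <- as.matrix(means)
  if (is.null(rownames(means)) || is.null(colnames(means)))
    stop("reference means need class rownames and gene colnames")
  if (anyNA(means) || any(!is.finite(means)))
    stop("reference means must be finite")
  if (any(means < 0)) stop("reference means must be nonnegative")
  structure(list(means = means), class = "class_reference")
}

#' @export
print.class_reference <- function(x, ...) {
  cat(sprintf("class_reference: %d classes x %d genes\n",
              nrow(x$means), ncol(x$means)))
  invisible(x)
}

#' Read a class reference from delimited text
#'
#' @param path delimited text file: numeric matrix with row and column labels.
#' @param delimiter field delimiter.
#' @param orientation `"classes_x_genes"` (rows are classes) or
#'   `"genes_x_classes"` (file is transposed).
#' @param panel optional character vector of panel genes; when given, the
#'   reference is aligned to the intersection in panel order, and genes
#'   absent from the panel are dropped with a warning.
#' @return A [class_reference].
#' @export
read_class_reference <- function(path, delimiter = ",",
                                 orientation = c("classes_x_genes",
                                                 "genes_x_classes"),
                                 panel = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = delimiter,
                                   row.names = 1, check.names = FALSE))
  storage.mode(m) <- "double"
  if (orientation == "genes_x_classes") m <- t(m)
  if (any(m < 0)) stop("reference contains negative mean expression")
  ref <- class_reference(m)
  if (!is.null(panel)) ref <- align_reference(ref, panel)
  ref
}

#' Align a class reference to a gene panel
#'
#' @param ref a [class_reference].
#' @param panel character vector of panel gene labels.
#' @return A [class_reference] restricted to the shared genes, in panel order.
#' @export
align_reference <- function(ref, panel) {
  stopifnot(inherits(ref, "class_reference"))
  shared <- intersect(panel, colnames(ref$means))
  if (length(shared) == 0L)
    stop("reference shares no genes with the panel")
  extra <- setdiff(colnames(ref$means), panel)
  if (length(extra) > 0L)
    warning(length(extra), " reference gene(s) not in panel dropped: ",
            paste(head(extra, 5), collapse = ", "))
  class_reference(ref$means[, shared, drop = FALSE])
}

#' Construct a nuclear-stain image
#'
#' @param pixels numeric matrix of nonnegative intensities, indexed
#'   `[ix, iy]`: the first dimension is x (image width), the second y
#'   (height), matching the package coordinate convention.
#' @return An object of class `nuclear_image`.
#' @export
nuclear_image <- function(pixels) {
  pixels <- as.matrix(pixels)
  if (length(dim(pixels)) != 2L) stop("pixels must be a 2D matrix")
  if (anyNA(pixels) || any(pixels < 0))
    stop("pixel intensities must be nonnegative and non-missing")
  structure(list(pixels = pixels), class = "nuclear_image")
}

#' @export
print.nuclear_image <- function(x, ...) {
  cat(sprintf("nuclear_image: %d x %d pixels, intensity [%.3g, %.3g]\n",
              nrow(x$pixels), ncol(x$pixels), min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Read a single-channel nuclear-stain image (TIFF or PNG)
#'
#' @param path image file. Multi-channel images are a hard error: extract the
#'   nuclear channel upstream (e.g. `EBImage::readImage(path)[, , 1]`).
#' @return A [nuclear_image].
#' @export
read_nuclear_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (length(d) > 2L && any(d[-(1:2)] > 1L))
    stop("multi-channel image: select the nuclear channel before loading, ",
         "e.g. EBImage::readImage(path)[, , 1]")
  nuclear_image(matrix(as.numeric(img), d[1], d[2]))
}

#' Construct a segmented map
#'
#' Units (cells, bins or spot environments) x genes count matrix with unit
#' centroids, produced by the segmentation strategies and consumed by the
#' clustering, embedding and cell-typing tools.
#'
#' @param counts nonnegative integer units x genes matrix; unique gene
#'   colnames required.
#' @param unit_kind `"cell"`, `"bin"` or `"spot_env"`.
#' @param centroids units x 2 matrix of unit centroid `(x, y)`.
#' @param geometry optional per-unit footprint record (mask label id, or bin
#'   center and radius).
#' @param sample per-unit sample id; recycled if length 1.
#' @return An object of class `segmented_map`.
#' @export
segmented_map <- function(counts, unit_kind = c("cell", "bin", "spot_env"),
                          centroids, geometry = NULL, sample = "sample_1") {
  unit_kind <- match.arg(unit_kind)
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  storage.mode(counts) <- "integer"
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts)))
    stop("counts needs unique gene colnames")
  centroids <- as.matrix(centroids)
  if (nrow(centroids) != nrow(counts) || ncol(centroids) != 2L)
    stop("centroids must be a units x 2 matrix matching counts rows")
  colnames(centroids) <- c("x", "y")
  if (length(sample) == 1L) sample <- rep(sample, nrow(counts))
  if (length(sample) != nrow(counts))
    stop("sample must have one entry per unit")
  structure(list(counts = counts, unit_kind = unit_kind,
                 centroids = centroids, geometry = geometry,
                 sample = as.character(sample)),
            class = "segmented_map")
}

#' @export
print.segmented_map <- function(x, ...) {
  cat(sprintf("segmented_map (%s): %d units x %d genes, %d reads total\n",
              x$unit_kind, nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Export a segmented map as delimited text
#'
#' Writes `<prefix>_counts.csv` (units as rows, genes as columns) and
#' `<prefix>_centroids.csv`; with `sparse = TRUE` the counts go to
#' MatrixMarket `<prefix>_counts.mtx` plus `<prefix>_genes.txt`.
#'
#' @param seg a [segmented_map].
#' @param prefix output path prefix.
#' @param sparse write counts in MatrixMarket format instead of dense CSV.
#' @return Character vector of the files written, invisibly.
#' @export
write_segmented_map <- function(seg, prefix, sparse = FALSE) {
  stopifnot(inherits(seg, "segmented_map"))
  cent <- data.frame(unit = rownames(seg$counts) %||% seq_len(nrow(seg$counts)),
                     seg$centroids, kind = seg$unit_kind, sample = seg$sample)
  fc <- paste0(prefix, "_centroids.csv")
  utils::write.table(cent, fc, sep = ",", row.names = FALSE, quote = FALSE)
  if (sparse) {
    fm <- paste0(prefix, "_counts.mtx")
    Matrix::writeMM(Matrix::Matrix(seg$counts, sparse = TRUE), fm)
    fg <- paste0(prefix, "_genes.txt")
    writeLines(colnames(seg$counts), fg)
    files <- c(fm, fg, fc)
  } else {
    fm <- paste0(prefix, "_counts.csv")
    utils::write.table(data.frame(unit = cent$unit, seg$counts,
                                  check.names = FALSE),
                       fm, sep = ",", row.names = FALSE, quote = FALSE)
    files <- c(fm, fc)
  }
  invisible(files)
}

#' Read a segmented map written by [write_segmented_map()]
#'
#' @param prefix the prefix used at export (dense CSV layout).
#' @return A [segmented_map].
#' @export
read_segmented_map <- function(prefix) {
  cm <- utils::read.table(paste0(prefix, "_counts.csv"), header = TRUE,
                          sep = ",", check.names = FALSE)
  ct <- utils::read.table(paste0(prefix, "_centroids.csv"), header = TRUE,
                          sep = ",", check.names = FALSE)
  counts <- as.matrix(cm[, -1, drop = FALSE])
  rownames(counts) <- cm[[1]]
  segmented_map(counts, unit_kind = ct$kind[1],
                centroids = as.matrix(ct[, c("x", "y")]),
                sample = ct$sample)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
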