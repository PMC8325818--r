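## Segmentation strategies: watershed cells from a nuclear stain,
## overlapping square bins, per-read spot environments; QC filtering.

#' Watershed segmentation of a nuclear-stain image
#'
#' Standard DAPI pipeline: white top-hat (disc structuring element) to
#' remove uneven background and enhance nuclei, global intensity threshold
#' (Otsu when not given), hole filling and speck removal, watershed on the
#' distance transform to split touching nuclei, then bounded outward
#' expansion of each nucleus by `expansion` pixels, meeting expansions split
#' by the nearest-nucleus rule. Pixels beyond the expansion stay 0:
#' inter-cell space is unassigned and reads landing there are not assigned
#' to any cell.
#'
#' @param image a [nuclear_image] (single channel).
#' @param tophat_radius disc radius in pixels; choose it larger than the
#'   expected nucleus radius.
#' @param threshold intensity threshold applied to the (smoothed) top-hat
#'   image, on the image's own intensity scale; default Otsu.
#' @param smooth_sigma sd (pixels) of a Gaussian blur applied to the top-hat
#'   image before thresholding, stabilizing the threshold and the distance
#'   transform against pixel noise; 0 disables (default 2).
#' @param expansion outward expansion distance from the nuclear boundary in
#'   pixels (default 10).
#' @param min_area specks below this area (px^2) are removed (default 30).
#' @param watershed_tolerance minimum object-height separation in the
#'   distance transform for the watershed split (default 1).
#' @return An object of class `label_mask`: integer matrix `mask`
#'   (`[ix, iy]`, 0 = unassigned background, 1..M = cell ids) and `n_cells`.
#' @export
segment_dapi <- function(image, tophat_radius, threshold = NULL,
                         expansion = 10, min_area = 30,
                         watershed_tolerance = 1, smooth_sigma = 2) {
  stopifnot(inherits(image, "nuclear_image"), tophat_radius >= 1)
  px <- image$pixels
  if (max(px) == 0) stop("image is all zero")
  if (mean(px >= max(px) * (1 - 1e-9)) > 0.05)
    warning("image looks saturated (> 5% of pixels at maximum intensity)")
  img <- EBImage::as.Image(px)
  brush <- EBImage::makeBrush(2 * round(tophat_radius) + 1, shape = "disc")
  th <- EBImage::whiteTopHat(img, brush)
  if (smooth_sigma > 0) th <- EBImage::gblur(th, sigma = smooth_sigma)
  if (is.null(threshold)) threshold <- EBImage::otsu(th, range = range(th))
  binary <- th > threshold
  if (!any(binary))
    stop("no pixels above threshold ", signif(threshold, 3),
         "; lower the threshold or check the image")
  binary <- EBImage::fillHull(binary)
  lab0 <- EBImage::bwlabel(binary)
  areas <- tabulate(as.integer(lab0))
  small <- which(areas < min_area)
  if (length(small) > 0L) binary[as.integer(lab0) %in% small] <- FALSE
  if (!any(binary))
    stop("all candidate nuclei below min_area = ", min_area,
         "; lower the threshold or min_area")
  dm <- EBImage::distmap(binary)
  nuc <- EBImage::watershed(dm, tolerance = watershed_tolerance, ext = 1)
  nuc <- matrix(as.integer(nuc), nrow(px), ncol(px))
  # relabel consecutively
  ids <- sort(unique(nuc[nuc > 0]))
  relab <- integer(max(ids)); relab[ids] <- seq_along(ids)
  nuc[nuc > 0] <- relab[nuc[nuc > 0]]
  mask <- expand_labels(nuc, expansion)
  structure(list(mask = mask, n_cells = length(ids),
                 threshold = threshold, tophat_radius = tophat_radius,
                 expansion = expansion, min_area = min_area),
            class = "label_mask")
}

# Bounded nearest-nucleus expansion: every background pixel within
# `expansion` of a nucleus pixel takes that pixel's label.
expand_labels <- function(nuc, expansion) {
  if (expansion <= 0) return(nuc)
  fg <- which(nuc > 0, arr.ind = TRUE)
  bg <- which(nuc == 0, arr.ind = TRUE)
  if (nrow(bg) == 0L) return(nuc)
  nn <- FNN::get.knnx(fg, bg, k = 1)
  take <- nn$nn.dist[, 1] <= expansion
  out <- nuc
  out[bg[take, , drop = FALSE]] <- nuc[fg[nn$nn.index[take, 1], , drop = FALSE]]
  out
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("label_mask: %d cells over %d x %d pixels (%.1f%% assigned)\n",
              x$n_cells, nrow(x$mask), ncol(x$mask),
              100 * mean(x$mask > 0)))
  invisible(x)
}

#' Assign reads to segmented cells
#'
#' Each read maps to the mask label at its pixel (`floor` of the continuous
#' coordinates). Reads on background (label 0) are discarded but tallied, as
#' are reads outside the image extent; assigned + background + out-of-extent
#' always equals the input read count.
#'
#' @param spots a [spot_table].
#' @param mask a `label_mask` from [segment_dapi()], or a plain integer
#'   label matrix.
#' @return A [segmented_map] with `unit_kind = "cell"`, one unit per mask
#'   label (including read-less cells), centroids at the label pixel
#'   centroids, and attributes `n_background` and `n_out_of_extent`.
#' @export
assign_spots <- function(spots, mask) {
  stopifnot(inherits(spots, "spot_table"))
  m <- if (inherits(mask, "label_mask")) mask$mask else mask
  ix <- floor(spots$x) + 1L
  iy <- floor(spots$y) + 1L
  inside <- ix >= 1L & ix <= nrow(m) & iy >= 1L & iy <= ncol(m)
  n_out <- sum(!inside)
  lab <- rep(0L, nrow(spots))
  lab[inside] <- m[cbind(ix[inside], iy[inside])]
  n_bg <- sum(inside & lab == 0L)
  M <- max(m)
  if (M < 1L) stop("mask contains no cells")
  genes <- sort(unique(spots$gene))
  keep <- lab > 0L
  counts <- table(factor(lab[keep], levels = seq_len(M)),
                  factor(spots$gene[keep], levels = genes))
  counts <- matrix(as.integer(counts), M, length(genes),
                   dimnames = list(seq_len(M), genes))
  fg <- which(m > 0, arr.ind = TRUE)
  cent <- cbind(x = tapply(fg[, 1] - 0.5, m[fg], mean),
                y = tapply(fg[, 2] - 0.5, m[fg], mean))[seq_len(M), ,
                                                        drop = FALSE]
  smp <- if (any(keep)) spots$sample[keep][1] else "sample_1"
  out <- segmented_map(counts, "cell", cent,
                       geometry = data.frame(label = seq_len(M)),
                       sample = smp)
  attr(out, "n_background") <- n_bg
  attr(out, "n_out_of_extent") <- n_out
  out
}

#' Segment reads into overlapping square bins
#'
#' Bin centers sit on a regular lattice with the given spacing, spanning the
#' data bounding box; each bin is an axis-aligned square of half-width
#' `radius` (a disc with `circular = TRUE`). A read contributes to every bin
#' containing it, so bins overlap when `spacing < 2 * radius`; with
#' `spacing = 2 * radius` the squares tile the plane and every interior read
#' is counted exactly once. Bins that receive no reads are dropped.
#'
#' @param spots a [spot_table].
#' @param radius bin half-width in pixels.
#' @param spacing distance between adjacent bin centers in pixels.
#' @param circular use discs of the given radius instead of squares.
#' @return A [segmented_map] with `unit_kind = "bin"`; geometry records each
#'   bin's center, radius and shape.
#' @export
overlapping_bins <- function(spots, radius, spacing, circular = FALSE) {
  stopifnot(inherits(spots, "spot_table"), radius > 0, spacing > 0)
  x0 <- min(spots$x); y0 <- min(spots$y)
  ncx <- ceiling((max(spots$x) - x0) / spacing)
  ncy <- ceiling((max(spots$y) - y0) / spacing)
  xr <- spots$x - x0
  yr <- spots$y - y0
  ilo <- pmax(0, ceiling((xr - radius) / spacing))
  ihi <- pmin(ncx, floor((xr + radius) / spacing))
  jlo <- pmax(0, ceiling((yr - radius) / spacing))
  jhi <- pmin(ncy, floor((yr + radius) / spacing))
  nxc <- ihi - ilo + 1L
  nyc <- jhi - jlo + 1L
  ok <- nxc > 0L & nyc > 0L
  r1 <- which(ok)
  # expand read x covering-index pairs, then cross with y covering indices
  pr <- rep(r1, nxc[r1])
  pxi <- sequence(nxc[r1], from = ilo[r1])
  qn <- nyc[pr]
  qr <- rep(pr, qn)
  qxi <- rep(pxi, qn)
  qyi <- sequence(qn, from = jlo[pr])
  if (circular) {
    keep <- (spots$x[qr] - (x0 + qxi * spacing))^2 +
            (spots$y[qr] - (y0 + qyi * spacing))^2 <= radius^2
    qr <- qr[keep]; qxi <- qxi[keep]; qyi <- qyi[keep]
  }
  if (length(qr) == 0L) stop("no read falls inside any bin")
  code <- qxi + qyi * (ncx + 1L)
  bins <- sort(unique(code))
  bfac <- match(code, bins)
  genes <- sort(unique(spots$gene))
  gfac <- match(spots$gene[qr], genes)
  counts <- matrix(0L, length(bins), length(genes),
                   dimnames = list(bins, genes))
  tab <- table(factor(bfac, levels = seq_along(bins)),
               factor(gfac, levels = seq_along(genes)))
  counts[] <- as.integer(tab)
  cx <- x0 + (bins %% (ncx + 1L)) * spacing
  cy <- y0 + (bins %/% (ncx + 1L)) * spacing
  segmented_map(counts, "bin", cbind(x = cx, y = cy),
                geometry = data.frame(cx = cx, cy = cy, radius = radius,
                                      shape = if (circular) "disc"
                                              else "square"),
                sample = spots$sample[1])
}

#' Summarize the local environment of every read
#'
#' One unit per read: its row counts the genes of all reads (itself
#' included) within Euclidean distance `radius` of the focal read. An
#' isolated read yields a one-hot row of its own gene.
#'
#' @param spots a [spot_table].
#' @param radius environment radius in pixels.
#' @return A [segmented_map] with `unit_kind = "spot_env"`, centroids at the
#'   focal read positions, rows in read order.
#' @export
spot_environment_bins <- function(spots, radius) {
  stopifnot(inherits(spots, "spot_table"), radius > 0)
  n <- nrow(spots)
  genes <- sort(unique(spots$gene))
  gi <- match(spots$gene, genes)
  ind <- matrix(0L, n, length(genes))
  ind[cbind(seq_len(n), gi)] <- 1L
  counts <- matrix(0L, n, length(genes), dimnames = list(NULL, genes))
  r2 <- radius^2
  chunk <- max(1L, floor(2e6 / n))
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    d2 <- outer(spots$x[idx], spots$x, "-")^2 +
          outer(spots$y[idx], spots$y, "-")^2
    counts[idx, ] <- (d2 <= r2) %*% ind
  }
  segmented_map(counts, "spot_env", cbind(x = spots$x, y = spots$y),
                geometry = data.frame(radius = radius),
                sample = spots$sample)
}

#' Quality-control filter on a segmented map
#'
#' Drops units whose total reads fall outside `[min_reads, max_reads]`, then
#' genes whose remaining total is below `min_gene_reads`. Applying the same
#' thresholds twice is a no-op (idempotent).
#'
#' @param seg a [segmented_map].
#' @param min_reads minimum reads per unit (default 0).
#' @param max_reads maximum reads per unit (default `Inf`).
#' @param min_gene_reads minimum total reads for a gene to be kept
#'   (default 0).
#' @return The filtered [segmented_map], with attributes `n_units_dropped`
#'   and `n_genes_dropped`.
#' @export
qc_filter <- function(seg, min_reads = 0, max_reads = Inf,
                      min_gene_reads = 0) {
  stopifnot(inherits(seg, "segmented_map"),
            min_reads >= 0, max_reads >= min_reads, min_gene_reads >= 0)
  tot <- rowSums(seg$counts)
  keep_u <- tot >= min_reads & tot <= max_reads
  if (!any(keep_u)) {
    q <- stats::quantile(tot)
    stop("all units filtered out; reads/unit quantiles: ",
         paste(names(q), signif(q, 3), sep = "=", collapse = ", "))
  }
  counts <- seg$counts[keep_u, , drop = FALSE]
  gtot <- colSums(counts)
  keep_g <- gtot >= min_gene_reads
  if (!any(keep_g)) {
    q <- stats::quantile(gtot)
    stop("all genes filtered out; reads/gene quantiles: ",
         paste(names(q), signif(q, 3), sep = "=", collapse = ", "))
  }
  geom <- seg$geometry
  if (is.data.frame(geom) && nrow(geom) == length(keep_u))
    geom <- geom[keep_u, , drop = FALSE]
  out <- segmented_map(counts[, keep_g, drop = FALSE], seg$unit_kind,
                       seg$centroids[keep_u, , drop = FALSE],
                       geometry = geom, sample = seg$sample[keep_u])
  attr(out, "n_units_dropped") <- sum(!keep_u)
  attr(out, "n_genes_dropped") <- sum(!keep_g)
  out
}
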