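## Gaussian KDE expression-density maps and two-gene overlays.
##
## Densities are evaluated by exact summation over the read kernels, so a map
## can be queried at any point in the plane (the gradient finder needs
## off-grid evaluations) and the result is a true probability density:
## integrating a map over the plane gives 1 before any display scaling.

# Exact isotropic-Gaussian KDE evaluation at arbitrary query points.
# Chunked so memory stays ~ O(chunk * n_reads).
kde2d_eval <- function(px, py, qx, qy, bw) {
  n <- length(px)
  stopifnot(n >= 1L, bw > 0, length(qx) == length(qy))
  nq <- length(qx)
  out <- numeric(nq)
  norm <- 1 / (n * 2 * pi * bw^2)
  chunk <- max(1L, floor(2e6 / n))
  for (s in seq(1L, nq, by = chunk)) {
    idx <- s:min(s + chunk - 1L, nq)
    d2 <- outer(qx[idx], px, "-")^2 + outer(qy[idx], py, "-")^2
    out[idx] <- norm * rowSums(exp(-d2 / (2 * bw^2)))
  }
  out
}

# Silverman's rule of thumb for an isotropic 2D Gaussian kernel:
# sigma_hat * n^(-1/6), with sigma_hat the mean of the marginal sds.
silverman_bw2d <- function(x, y) {
  n <- length(x)
  s <- mean(c(stats::sd(x), stats::sd(y)))
  if (!is.finite(s) || s == 0) s <- 1
  s * n^(-1 / 6)
}

#' Kernel density estimate of a gene's expression over the tissue
#'
#' Smooths the read positions of one gene into a continuous expression
#' density with an isotropic Gaussian kernel, evaluated on a regular grid
#' that covers the reads' bounding box plus three bandwidths of margin.
#' The map is a probability density (integrates to 1 over the plane);
#' display scaling happens only at plot time so maps remain comparable.
#'
#' @param spots a [spot_table].
#' @param gene gene label to map (exact match).
#' @param bandwidth Gaussian kernel sd in pixels; default Silverman's rule on
#'   the gene's reads. Always recorded in the output.
#' @param grid_step grid spacing in pixels; default `bandwidth / 2`.
#' @return An object of class `density_map`: grid vectors `x`, `y`, matrix
#'   `values` (`values[ix, iy]`, per-pixel^2 units), the contributing
#'   `reads`, `gene`, `bandwidth` and `grid_step`.
#' @export
gene_density <- function(spots, gene, bandwidth = NULL, grid_step = NULL) {
  stopifnot(inherits(spots, "spot_table"))
  sel <- spots$gene == gene
  if (!any(sel))
    stop("gene '", gene, "' absent; available: ",
         paste(sort(unique(spots$gene)), collapse = ", "))
  px <- spots$x[sel]; py <- spots$y[sel]
  if (length(px) == 1L)
    warning("gene '", gene, "' has a single read; map is one Gaussian bump")
  if (is.null(bandwidth)) bandwidth <- silverman_bw2d(px, py)
  stopifnot(bandwidth > 0)
  if (is.null(grid_step)) grid_step <- bandwidth / 2
  gx <- seq(min(px) - 3 * bandwidth, max(px) + 3 * bandwidth, by = grid_step)
  gy <- seq(min(py) - 3 * bandwidth, max(py) + 3 * bandwidth, by = grid_step)
  q <- expand.grid(x = gx, y = gy)
  vals <- matrix(kde2d_eval(px, py, q$x, q$y, bandwidth),
                 nrow = length(gx), ncol = length(gy))
  structure(list(x = gx, y = gy, values = vals,
                 reads = cbind(x = px, y = py),
                 gene = gene, bandwidth = bandwidth, grid_step = grid_step),
            class = "density_map")
}

#' Integrate a density map over its grid
#'
#' Riemann sum of the gridded values times the grid cell area; close to 1
#' for any map whose grid covers the reads (the default margin does).
#'
#' @param map a `density_map`.
#' @return Scalar integrated mass.
#' @export
density_mass <- function(map) {
  stopifnot(inherits(map, "density_map"))
  sum(map$values) * map$grid_step^2
}

#' Evaluate a density map at arbitrary points
#'
#' Uses the exact kernel sum over the stored reads, so points outside the
#' grid are valid (the KDE is defined everywhere), never clipped.
#'
#' @param map a `density_map`.
#' @param x,y query coordinates.
#' @return Density values at the query points.
#' @export
density_at <- function(map, x, y) {
  stopifnot(inherits(map, "density_map"))
  kde2d_eval(map$reads[, "x"], map$reads[, "y"], x, y, map$bandwidth)
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf(
    "density_map '%s': %d x %d grid (step %.3g px), bandwidth %.3g px, %d reads\n",
    x$gene, length(x$x), length(x$y), x$grid_step, x$bandwidth, nrow(x$reads)))
  invisible(x)
}

#' Overlay two gene density maps as a two-channel composite
#'
#' Each channel is independently rescaled to `[0, 1]` by its own maximum, so
#' the composite shows where each gene is (relatively) dense regardless of
#' absolute abundance. If the grids differ, `b` is re-evaluated on `a`'s
#' grid; if the bounding boxes are disjoint, a union grid is used with a
#' warning.
#'
#' @param a,b `density_map` objects (channel 1 and channel 2).
#' @return An object of class `density_overlay` with grid vectors `x`, `y`,
#'   channel matrices `ch1`, `ch2` in `[0, 1]`, and the two gene labels.
#' @export
overlay_densities <- function(a, b) {
  stopifnot(inherits(a, "density_map"), inherits(b, "density_map"))
  gx <- a$x; gy <- a$y
  disjoint <- min(b$reads[, "x"]) > max(a$reads[, "x"]) ||
              max(b$reads[, "x"]) < min(a$reads[, "x"]) ||
              min(b$reads[, "y"]) > max(a$reads[, "y"]) ||
              max(b$reads[, "y"]) < min(a$reads[, "y"])
  if (disjoint) {
    warning("disjoint bounding boxes; overlaying on the union grid")
    allx <- c(a$reads[, "x"], b$reads[, "x"])
    ally <- c(a$reads[, "y"], b$reads[, "y"])
    m <- 3 * max(a$bandwidth, b$bandwidth)
    gx <- seq(min(allx) - m, max(allx) + m, by = a$grid_step)
    gy <- seq(min(ally) - m, max(ally) + m, by = a$grid_step)
  }
  q <- expand.grid(x = gx, y = gy)
  same_grid <- !disjoint && identical(a$x, b$x) && identical(a$y, b$y)
  va <- if (disjoint)
    matrix(density_at(a, q$x, q$y), length(gx), length(gy)) else a$values
  vb <- if (same_grid) b$values else
    matrix(density_at(b, q$x, q$y), length(gx), length(gy))
  rescale <- function(v) if (max(v) > 0) v / max(v) else v
  structure(list(x = gx, y = gy, ch1 = rescale(va), ch2 = rescale(vb),
                 genes = c(a$gene, b$gene)),
            class = "density_overlay")
}

#' Plot a density map as a grayscale heat map
#'
#' White marks high expression density, black absence, on the package's
#' image convention (y increases downward).
#'
#' @param x a `density_map`.
#' @param ... passed to [graphics::image()].
#' @export
plot.density_map <- function(x, ...) {
  graphics::image(x$x, rev(-x$y), x$values[, rev(seq_along(x$y))],
                  col = grDevices::gray(seq(0, 1, length.out = 256)),
                  xlab = "x (px)", ylab = "-y (px)", main = x$gene,
                  useRaster = TRUE, asp = 1, ...)
}

#' Plot a two-gene density overlay
#'
#' Channel 1 renders red, channel 2 green; co-dense areas appear yellow.
#'
#' @param x a `density_overlay`.
#' @param ... ignored.
#' @export
plot.density_overlay <- function(x, ...) {
  img <- grDevices::rgb(t(x$ch1)[seq_along(x$y), , drop = FALSE],
                        t(x$ch2)[seq_along(x$y), , drop = FALSE],
                        0)
  dim(img) <- c(length(x$y), length(x$x))
  graphics::plot(range(x$x), range(-x$y), type = "n", asp = 1,
                 xlab = "x (px)", ylab = "-y (px)",
                 main = paste(x$genes, collapse = " + "))
  graphics::rasterImage(img, min(x$x), min(-x$y), max(x$x), max(-x$y))
}
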