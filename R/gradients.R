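## Gradient discovery (KDE-difference vector field) and supervised 1D
## gradient profiling by minimum distance to an origin point set.

#' De novo gradient field over a spot map
#'
#' Lays a regular lattice of reference points over the data bounding box and,
#' at each point `p`, sums over the gene panel the absolute local density
#' variation per axis:
#' `G_x(p) = sum_genes |d(p - (b,0)) - d(p + (b,0))|` and analogously for
#' `G_y`, where `d` is each gene's normalized Gaussian KDE and `b` the
#' finite-difference offset. Large `(G_x, G_y)` marks locations where many
#' genes change expression, i.e. candidate tissue gradients or boundaries.
#'
#' Because of the absolute value the field encodes per-axis gradient
#' intensity but not sign; `signed = TRUE` drops the absolute value (summing
#' signed differences) for users who want true direction.
#'
#' @param spots a [spot_table].
#' @param genes gene panel to sum over; default all genes with >= 2 reads.
#' @param bandwidth KDE sd in pixels; default Silverman's rule on all
#'   selected reads pooled.
#' @param b finite-difference offset in pixels; default `bandwidth / 2`.
#' @param lattice_step spacing of the reference lattice; default `2 * b`.
#' @param signed sum signed instead of absolute differences.
#' @return An object of class `gradient_field`: lattice vectors `x`, `y`,
#'   matrices `Gx`, `Gy` (`[ix, iy]`), logical `interior` flagging lattice
#'   points whose offset probe points stay at least 3 bandwidths inside the
#'   data bounding box (KDE edge bias is not corrected outside), and the
#'   parameters used.
#' @export
gradient_field <- function(spots, genes = NULL, bandwidth = NULL, b = NULL,
                           lattice_step = NULL, signed = FALSE) {
  stopifnot(inherits(spots, "spot_table"))
  tab <- table(spots$gene)
  if (is.null(genes)) genes <- names(tab)[tab >= 2]
  missing <- setdiff(genes, names(tab))
  if (length(missing) > 0L)
    stop("gene(s) absent: ", paste(missing, collapse = ", "))
  genes <- genes[tab[genes] >= 2]
  if (length(genes) == 0L) stop("need at least one gene with >= 2 reads")
  sel <- spots$gene %in% genes
  if (is.null(bandwidth))
    bandwidth <- silverman_bw2d(spots$x[sel], spots$y[sel])
  stopifnot(bandwidth > 0)
  if (is.null(b)) b <- bandwidth / 2
  stopifnot(b > 0)
  if (is.null(lattice_step)) lattice_step <- 2 * b
  bbox <- c(min(spots$x[sel]), max(spots$x[sel]),
            min(spots$y[sel]), max(spots$y[sel]))
  lx <- seq(bbox[1], bbox[2], by = lattice_step)
  ly <- seq(bbox[3], bbox[4], by = lattice_step)
  q <- expand.grid(x = lx, y = ly)
  Gx <- matrix(0, length(lx), length(ly))
  Gy <- matrix(0, length(lx), length(ly))
  comb <- if (signed) function(a, bb) a - bb else function(a, bb) abs(a - bb)
  for (g in genes) {
    gs <- spots$gene == g
    px <- spots$x[gs]; py <- spots$y[gs]
    dxm <- kde2d_eval(px, py, q$x - b, q$y, bandwidth)
    dxp <- kde2d_eval(px, py, q$x + b, q$y, bandwidth)
    dym <- kde2d_eval(px, py, q$x, q$y - b, bandwidth)
    dyp <- kde2d_eval(px, py, q$x, q$y + b, bandwidth)
    Gx <- Gx + matrix(comb(dxm, dxp), length(lx), length(ly))
    Gy <- Gy + matrix(comb(dym, dyp), length(lx), length(ly))
  }
  # a lattice point is interior when its offset probe points stay three
  # bandwidths inside the data bounding box
  m <- 3 * bandwidth + b
  interior <- outer(lx >= bbox[1] + m & lx <= bbox[2] - m,
                    ly >= bbox[3] + m & ly <= bbox[4] - m, "&")
  structure(list(x = lx, y = ly, Gx = Gx, Gy = Gy, interior = interior,
                 b = b, bandwidth = bandwidth, lattice_step = lattice_step,
                 genes = genes, signed = signed),
            class = "gradient_field")
}

#' @export
print.gradient_field <- function(x, ...) {
  cat(sprintf(
    "gradient_field: %d x %d lattice (step %.3g px), %d genes, bw %.3g, b %.3g%s\n",
    length(x$x), length(x$y), x$lattice_step, length(x$genes),
    x$bandwidth, x$b, if (x$signed) " (signed)" else ""))
  invisible(x)
}

#' Quiver plot of a gradient field
#'
#' Arrows show per-axis gradient intensity at each lattice point. With the
#' default unsigned field, arrow components are magnitudes (direction up to
#' sign per axis).
#'
#' @param x a `gradient_field`.
#' @param scale arrow length per density-difference unit; default scales the
#'   largest arrow to one lattice step.
#' @param ... passed to [graphics::arrows()].
#' @export
plot.gradient_field <- function(x, scale = NULL, ...) {
  q <- expand.grid(x = x$x, y = x$y)
  gx <- as.vector(x$Gx); gy <- as.vector(x$Gy)
  m <- max(sqrt(gx^2 + gy^2))
  if (is.null(scale)) scale <- if (m > 0) x$lattice_step / m else 1
  graphics::plot(range(x$x), range(-x$y), type = "n", asp = 1,
                 xlab = "x (px)", ylab = "-y (px)", main = "gradient field")
  nz <- sqrt(gx^2 + gy^2) > 0
  graphics::arrows(q$x[nz], -q$y[nz],
                   q$x[nz] + scale * gx[nz], -q$y[nz] - scale * gy[nz],
                   length = 0.03, ...)
}

# Densify a poly-line to points spaced at most `spacing` apart.
densify_polyline <- function(vertices, spacing = 1) {
  v <- as.matrix(vertices)
  if (nrow(v) == 1L) return(v)
  pts <- list(v[1, , drop = FALSE])
  for (i in seq_len(nrow(v) - 1L)) {
    a <- v[i, ]; bb <- v[i + 1L, ]
    len <- sqrt(sum((bb - a)^2))
    nseg <- max(1L, ceiling(len / spacing))
    t <- seq_len(nseg) / nseg
    pts[[i + 1L]] <- cbind(a[1] + t * (bb[1] - a[1]),
                           a[2] + t * (bb[2] - a[2]))
  }
  out <- do.call(rbind, pts)
  colnames(out) <- c("x", "y")
  out
}

#' Project reads onto a 1D axis by distance to an origin
#'
#' For each read in the region, the axis coordinate is the minimum Euclidean
#' distance to any origin reference point:
#' `d_i = min_r sqrt((x_i - x_r)^2 + (y_i - y_r)^2)`. Poly-line origins are
#' densified to points at <= 1 px spacing before taking the minimum, so the
#' distance is effectively distance-to-curve.
#'
#' @param spots a [spot_table].
#' @param origin matrix or data frame of origin `(x, y)` coordinates: a point
#'   set, or poly-line vertices when `polyline = TRUE`.
#' @param region optional ROI box `c(xmin, xmax, ymin, ymax)` restricting the
#'   reads analyzed.
#' @param polyline treat `origin` rows as consecutive vertices of a curve.
#' @return An object of class `axis_projection`: the region's `spots`, their
#'   distances `d` (`d[i] = 0` iff read i coincides with an origin point),
#'   and the densified `origin` points.
#' @export
project_to_axis <- function(spots, origin, region = NULL, polyline = FALSE) {
  stopifnot(inherits(spots, "spot_table"))
  origin <- as.matrix(origin)
  if (nrow(origin) == 0L) stop("origin must contain at least one point")
  colnames(origin) <- c("x", "y")
  if (polyline) origin <- densify_polyline(origin, spacing = 1)
  if (!is.null(region)) spots <- select_roi(spots, region)
  if (nrow(spots) == 0L) stop("no reads in the requested region")
  d <- as.vector(FNN::get.knnx(origin, cbind(spots$x, spots$y),
                               k = 1)$nn.dist)
  structure(list(spots = spots, d = d, origin = origin),
            class = "axis_projection")
}

#' @export
print.axis_projection <- function(x, ...) {
  cat(sprintf(
    "axis_projection: %d reads, %d origin points, d in [%.2f, %.2f] px\n",
    nrow(x$spots), nrow(x$origin), min(x$d), max(x$d)))
  invisible(x)
}

#' Spatial heat map of distance to the gradient origin
#'
#' @param x an `axis_projection`.
#' @param ... passed to [graphics::points()].
#' @export
plot.axis_projection <- function(x, ...) {
  pal <- grDevices::colorRampPalette(c("navy", "turquoise", "yellow"))(256)
  col <- pal[cut(x$d, 256, labels = FALSE)]
  graphics::plot(x$spots$x, -x$spots$y, col = col, pch = 16, cex = 0.4,
                 asp = 1, xlab = "x (px)", ylab = "-y (px)",
                 main = "distance to origin", ...)
  graphics::points(x$origin[, 1], -x$origin[, 2], pch = 16, cex = 0.3,
                   col = "white")
}

#' Per-gene 1D expression profiles along a projected gradient axis
#'
#' Gaussian KDE of each requested gene's axis coordinates (distances to the
#' origin), evaluated on `[0, max(d) + 3 bw]`. Each profile is a probability
#' density in the distance coordinate; for genes away from the `d = 0`
#' boundary it integrates to 1 (boundary leakage is not corrected).
#'
#' @param projection an `axis_projection` from [project_to_axis()].
#' @param genes genes to profile; default all genes with >= 2 reads in the
#'   region. Requested genes absent from the region are skipped with a
#'   warning.
#' @param bandwidth 1D kernel sd in pixels; default Silverman's rule
#'   ([stats::bw.nrd0()]) per gene.
#' @param n_eval number of evaluation points per profile.
#' @return An object of class `axis_profiles`: named list `profiles` of
#'   data frames with columns `d` and `density`, plus the bandwidths used.
#' @export
axis_profiles <- function(projection, genes = NULL, bandwidth = NULL,
                          n_eval = 512) {
  stopifnot(inherits(projection, "axis_projection"))
  g <- projection$spots$gene
  tab <- table(g)
  if (is.null(genes)) genes <- names(tab)[tab >= 2]
  absent <- setdiff(genes, names(tab)[tab >= 2])
  if (length(absent) > 0L) {
    warning("gene(s) absent or with < 2 reads in region skipped: ",
            paste(absent, collapse = ", "))
    genes <- setdiff(genes, absent)
  }
  if (length(genes) == 0L) stop("no genes to profile")
  profiles <- list()
  bws <- numeric(0)
  for (gn in genes) {
    dg <- projection$d[g == gn]
    bw <- if (is.null(bandwidth)) stats::bw.nrd0(dg) else bandwidth
    if (bw <= 0) bw <- max(1e-6, stats::sd(dg), na.rm = TRUE)
    den <- stats::density(dg, bw = bw, from = 0,
                          to = max(projection$d) + 3 * bw, n = n_eval)
    profiles[[gn]] <- data.frame(d = den$x, density = den$y)
    bws[gn] <- bw
  }
  structure(list(profiles = profiles, bandwidth = bws),
            class = "axis_profiles")
}

#' Line plot of 1D gradient profiles
#'
#' @param x an `axis_profiles` object.
#' @param ... passed to [graphics::lines()].
#' @export
plot.axis_profiles <- function(x, ...) {
  ymax <- max(vapply(x$profiles, function(p) max(p$density), 0))
  xmax <- max(vapply(x$profiles, function(p) max(p$d), 0))
  graphics::plot(c(0, xmax), c(0, ymax), type = "n",
                 xlab = "distance to origin (px)", ylab = "density",
                 main = "gradient profiles")
  cols <- grDevices::colorRampPalette(
    c("firebrick", "orange", "forestgreen", "royalblue", "purple")
  )(length(x$profiles))
  for (i in seq_along(x$profiles))
    graphics::lines(x$profiles[[i]]$d, x$profiles[[i]]$density,
                    col = cols[i], ...)
  graphics::legend("topright", names(x$profiles), col = cols, lty = 1,
                   cex = 0.7, bty = "n")
}
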