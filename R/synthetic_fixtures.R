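## Seeded generators for every test surface: spot maps with planted
## structure, nuclei images, and class-labeled cells. Each generator is a
## pure function of its arguments plus the seed, and always returns the
## ground truth next to the data.

#' Specification for a synthetic layered tissue
#'
#' Describes a planar tissue as a mixture of planted components:
#' \describe{
#'   \item{layers}{bands along one axis, each with its own gene multinomial
#'     (emulates cortical layers with layer-restricted genes);}
#'   \item{gradients}{genes whose density varies as a Gaussian profile along
#'     one axis and uniformly along the other;}
#'   \item{pairs}{co-occurring gene pairs: each read of gene A gets a read of
#'     gene B at a fixed offset distance (random direction);}
#'   \item{background}{genes scattered uniformly over the field.}
#' }
#'
#' @param field `c(width, height)` of the field in pixels.
#' @param layers list of `list(band = c(lo, hi), axis = "x"|"y",
#'   genes = named probability vector, n = reads)`.
#' @param gradients list of `list(gene, axis, center, sd, n)`.
#' @param pairs list of `list(gene_a, gene_b, n, offset)`.
#' @param background list of `list(genes = character or named probabilities,
#'   n = reads)`.
#' @return A validated `tissue_spec` list.
#' @export
tissue_spec <- function(field = c(1000, 1000), layers = list(),
                        gradients = list(), pairs = list(),
                        background = list()) {
  stopifnot(length(field) == 2, all(field > 0))
  for (ly in layers) {
    stopifnot(length(ly$band) == 2, ly$band[1] < ly$band[2],
              ly$axis %in% c("x", "y"), all(ly$genes >= 0),
              sum(ly$genes) > 0, ly$n >= 0)
  }
  for (gr in gradients) stopifnot(gr$sd > 0, gr$n >= 0)
  for (pr in pairs) stopifnot(pr$offset >= 0, pr$n >= 0)
  structure(list(field = field, layers = layers, gradients = gradients,
                 pairs = pairs, background = background),
            class = "tissue_spec")
}

runif_field <- function(n, field) {
  cbind(x = stats::runif(n, 0, field[1]), y = stats::runif(n, 0, field[2]))
}

#' Generate a synthetic layered tissue
#'
#' Draws reads for every component of a [tissue_spec()] and returns both the
#' spot table and a truth table mapping each read to its generating
#' component.
#'
#' @param spec a [tissue_spec()].
#' @param seed RNG seed; the same spec and seed always give an identical
#'   table.
#' @return List with `spots` (a [spot_table]) and `truth` (data frame with
#'   `component` per read, aligned to `spots` rows).
#' @export
make_layered_tissue <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "tissue_spec"))
  if (!is.null(seed)) set.seed(seed)
  total <- sum(vapply(spec$layers, `[[`, 0, "n")) +
           sum(vapply(spec$gradients, `[[`, 0, "n")) +
           sum(vapply(spec$pairs, `[[`, 0, "n")) +
           sum(vapply(spec$background, `[[`, 0, "n"))
  if (total == 0) stop("spec generates zero reads")
  gene <- character(0); x <- numeric(0); y <- numeric(0); comp <- character(0)
  add <- function(g, xx, yy, cc) {
    gene <<- c(gene, g); x <<- c(x, xx); y <<- c(y, yy)
    comp <<- c(comp, rep(cc, length(g)))
  }
  f <- spec$field
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    if (ly$n == 0) next
    g <- sample(names(ly$genes), ly$n, replace = TRUE,
                prob = ly$genes / sum(ly$genes))
    along <- stats::runif(ly$n, ly$band[1], min(ly$band[2],
                          if (ly$axis == "x") f[1] else f[2]))
    other <- stats::runif(ly$n, 0, if (ly$axis == "x") f[2] else f[1])
    if (ly$axis == "x") add(g, along, other, paste0("layer_", i))
    else add(g, other, along, paste0("layer_", i))
  }
  for (i in seq_along(spec$gradients)) {
    gr <- spec$gradients[[i]]
    if (gr$n == 0) next
    along <- stats::rnorm(gr$n, gr$center, gr$sd)
    lim <- if (gr$axis == "x") f[1] else f[2]
    along <- pmin(pmax(along, 0), lim)
    other <- stats::runif(gr$n, 0, if (gr$axis == "x") f[2] else f[1])
    if (gr$axis == "x") add(rep(gr$gene, gr$n), along, other,
                            paste0("gradient_", i))
    else add(rep(gr$gene, gr$n), other, along, paste0("gradient_", i))
  }
  for (i in seq_along(spec$pairs)) {
    pr <- spec$pairs[[i]]
    if (pr$n == 0) next
    a <- runif_field(pr$n, f)
    th <- stats::runif(pr$n, 0, 2 * pi)
    bx <- pmin(pmax(a[, 1] + pr$offset * cos(th), 0), f[1])
    by <- pmin(pmax(a[, 2] + pr$offset * sin(th), 0), f[2])
    add(rep(pr$gene_a, pr$n), a[, 1], a[, 2], paste0("pair_", i))
    add(rep(pr$gene_b, pr$n), bx, by, paste0("pair_", i))
  }
  for (i in seq_along(spec$background)) {
    bg <- spec$background[[i]]
    if (bg$n == 0) next
    p <- if (is.character(bg$genes))
      setNames(rep(1, length(bg$genes)), bg$genes) else bg$genes
    g <- sample(names(p), bg$n, replace = TRUE, prob = p / sum(p))
    pos <- runif_field(bg$n, f)
    add(g, pos[, 1], pos[, 2], paste0("background_", i))
  }
  list(spots = spot_table(gene, x, y),
       truth = data.frame(component = comp, stringsAsFactors = FALSE))
}

#' Generate a synthetic nuclear-stain image
#'
#' Nuclei are isotropic Gaussian intensity bumps on a dark background, with
#' optional Gaussian pixel noise and a constant intensity offset. Pairs of
#' centers closer than `4 * nucleus_sd` are flagged as potentially
#' unresolvable in the returned metadata.
#'
#' @param n_nuclei number of nuclei (ignored when `centers` given).
#' @param size `c(width, height)` in pixels.
#' @param centers optional matrix of nucleus centers; default random with a
#'   `3 * nucleus_sd` margin from the border.
#' @param nucleus_sd Gaussian sd of each nucleus in pixels (default 10).
#' @param intensity peak intensity per nucleus (default 1).
#' @param noise_sd sd of additive Gaussian pixel noise (clamped at 0).
#' @param offset constant background intensity added everywhere.
#' @param seed RNG seed.
#' @return List with `image` (a [nuclear_image]), `centers` (n x 2 matrix),
#'   and `crowded` (logical: some pair closer than `4 * nucleus_sd`).
#' @export
make_nuclei_image <- function(n_nuclei, size = c(256, 256), centers = NULL,
                              nucleus_sd = 10, intensity = 1, noise_sd = 0,
                              offset = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(centers)) {
    m <- 3 * nucleus_sd
    stopifnot(size[1] > 2 * m, size[2] > 2 * m)
    centers <- cbind(stats::runif(n_nuclei, m, size[1] - m),
                     stats::runif(n_nuclei, m, size[2] - m))
  }
  centers <- as.matrix(centers)
  colnames(centers) <- c("x", "y")
  xs <- seq_len(size[1]) - 0.5
  ys <- seq_len(size[2]) - 0.5
  px <- matrix(0, size[1], size[2])
  for (i in seq_len(nrow(centers))) {
    px <- px + intensity *
      outer(exp(-(xs - centers[i, 1])^2 / (2 * nucleus_sd^2)),
            exp(-(ys - centers[i, 2])^2 / (2 * nucleus_sd^2)))
  }
  px <- px + offset
  if (noise_sd > 0)
    px <- pmax(px + matrix(stats::rnorm(length(px), 0, noise_sd),
                           size[1], size[2]), 0)
  crowded <- FALSE
  if (nrow(centers) > 1L)
    crowded <- min(stats::dist(centers)) < 4 * nucleus_sd
  list(image = nuclear_image(px), centers = centers, crowded = crowded)
}

#' Generate class-labeled cells with Poisson counts
#'
#' Places `n_cells` non-overlapping disc cells on a jittered grid, samples a
#' reference class for each, scales the class mean profile to the cell's
#' target depth, draws per-gene Poisson counts, and scatters the reads
#' uniformly inside the cell footprint. Returns the spot table, the ground
#' truth, and the disc label mask.
#'
#' @param ref a [class_reference] providing class mean profiles.
#' @param n_cells number of cells.
#' @param depth_range `c(lo, hi)` target total reads per cell; each cell's
#'   expected depth is uniform in this range and its scale factor is
#'   `depth / sum(class means)`.
#' @param cell_radius disc radius in pixels (default 8).
#' @param gap minimum spacing between cell footprints in pixels (default 4).
#' @param class_prob optional named sampling probabilities per class.
#' @param seed RNG seed.
#' @return List with `spots` ([spot_table]; `NULL` when no reads were
#'   drawn), `mask` (`label_mask`, disc
#'   footprints labeled in cell order), `classes` (true class per cell),
#'   `scale` (true `s_c`), `centers` (n x 2) and `depth` (realized reads per
#'   cell; cells that drew zero reads are flagged in `zero_read`).
#' @export
make_typed_cells <- function(ref, n_cells, depth_range = c(30, 60),
                             cell_radius = 8, gap = 4, class_prob = NULL,
                             seed = NULL) {
  stopifnot(inherits(ref, "class_reference"), n_cells >= 1)
  if (!is.null(seed)) set.seed(seed)
  classes <- rownames(ref$means)
  if (is.null(class_prob))
    class_prob <- setNames(rep(1, length(classes)), classes)
  pitch <- 2 * cell_radius + gap
  side <- ceiling(sqrt(n_cells))
  slots <- sample.int(side * side, n_cells)
  jit <- gap / 4
  centers <- cbind(
    x = ((slots - 1L) %% side) * pitch + cell_radius + gap / 2 +
      stats::runif(n_cells, -jit, jit),
    y = ((slots - 1L) %/% side) * pitch + cell_radius + gap / 2 +
      stats::runif(n_cells, -jit, jit))
  cls <- sample(classes, n_cells, replace = TRUE,
                prob = class_prob[classes] / sum(class_prob))
  depth <- stats::runif(n_cells, depth_range[1], depth_range[2])
  s <- depth / rowSums(ref$means)[cls]
  genes <- colnames(ref$means)
  gene <- character(0); x <- numeric(0); y <- numeric(0); cell <- integer(0)
  for (i in seq_len(n_cells)) {
    counts <- stats::rpois(length(genes), s[i] * ref$means[cls[i], ])
    ni <- sum(counts)
    if (ni == 0L) next
    g <- rep(genes, counts)
    # reads stay 1 px inside the disc edge so every read's pixel lies
    # within the rasterized footprint
    rr <- max(cell_radius - 1, cell_radius / 2) * sqrt(stats::runif(ni))
    th <- stats::runif(ni, 0, 2 * pi)
    gene <- c(gene, g)
    x <- c(x, centers[i, 1] + rr * cos(th))
    y <- c(y, centers[i, 2] + rr * sin(th))
    cell <- c(cell, rep(i, ni))
  }
  w <- side * pitch
  xs <- seq_len(w) - 0.5
  mask <- matrix(0L, w, w)
  for (i in seq_len(n_cells)) {
    inx <- which(abs(xs - centers[i, 1]) <= cell_radius)
    iny <- which(abs(xs - centers[i, 2]) <= cell_radius)
    sub <- outer(xs[inx] - centers[i, 1], xs[iny] - centers[i, 2],
                 function(a, b) a^2 + b^2) <= cell_radius^2
    mask[inx, iny][sub] <- i
  }
  realized <- tabulate(cell, n_cells)
  list(spots = if (length(gene) > 0L) spot_table(gene, x, y) else NULL,
       mask = structure(list(mask = mask, n_cells = n_cells),
                        class = "label_mask"),
       classes = cls, scale = s, centers = centers,
       cell = cell, depth = realized, zero_read = realized == 0L)
}
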