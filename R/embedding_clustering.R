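## Normalization, PCA reporting, RGB embedding maps and de novo clustering
## of segmented count matrices.

#' Normalize a segmented count matrix by per-gene totals
#'
#' Divides each gene column by its total over units, so every column sums to
#' 1. This removes the dominance of highly expressed genes before clustering
#' or embedding while preserving each gene's spatial pattern. Optionally
#' (non-default) rows can additionally be scaled to unit total, controlling
#' per-unit depth.
#'
#' @param seg a [segmented_map], or a nonnegative units x genes matrix.
#' @param per_unit additionally divide each row by its sum afterwards.
#' @return A units x genes numeric matrix with attribute `normalization`
#'   recording the method.
#' @export
normalize_by_gene_totals <- function(seg, per_unit = FALSE) {
  counts <- if (inherits(seg, "segmented_map")) seg$counts else as.matrix(seg)
  gtot <- colSums(counts)
  if (any(gtot == 0))
    stop("gene(s) with zero total counts: ",
         paste(head(colnames(counts)[gtot == 0], 5), collapse = ", "),
         "; run qc_filter() first")
  out <- sweep(counts, 2, gtot, "/")
  if (per_unit) {
    rtot <- rowSums(out)
    out <- out / ifelse(rtot == 0, 1, rtot)
  }
  attr(out, "normalization") <-
    if (per_unit) "gene_totals+unit_totals" else "gene_totals"
  out
}

#' PCA report: scores, loadings and variance explained
#'
#' Column-centered PCA of a (normalized) units x genes matrix. Loadings are
#' sign-fixed so the largest-magnitude loading of each component is
#' positive, making reported components reproducible across platforms.
#'
#' @param mat units x genes numeric matrix.
#' @param n_components number of components to report (default 20, capped at
#'   the matrix rank).
#' @return An object of class `pca_report`: `scores` (units x n), `loadings`
#'   (genes x n) and `variance_explained` over *all* components (sums to 1,
#'   nonincreasing).
#' @export
pca_report <- function(mat, n_components = 20) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) stop("need at least 2 units")
  if (all(apply(mat, 2, stats::sd) == 0))
    stop("constant matrix: no variance to decompose")
  p <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  ve <- p$sdev^2 / sum(p$sdev^2)
  nc <- min(n_components, ncol(p$rotation))
  rot <- p$rotation[, seq_len(nc), drop = FALSE]
  sc <- p$x[, seq_len(nc), drop = FALSE]
  flip <- apply(rot, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rot <- sweep(rot, 2, flip, "*")
  sc <- sweep(sc, 2, flip, "*")
  structure(list(scores = sc, loadings = rot, variance_explained = ve),
            class = "pca_report")
}

#' @export
print.pca_report <- function(x, ...) {
  cat(sprintf("pca_report: %d units, %d components reported\n",
              nrow(x$scores), ncol(x$scores)))
  cat("variance explained (top 5): ",
      paste(signif(head(x$variance_explained, 5), 3), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.pca_report <- function(x, ...) {
  graphics::barplot(head(x$variance_explained, ncol(x$scores)),
                    names.arg = seq_len(min(length(x$variance_explained),
                                            ncol(x$scores))),
                    xlab = "component", ylab = "variance explained", ...)
}

minmax_scale <- function(v) {
  r <- range(v)
  if (r[1] == r[2]) return(rep(0, length(v)))
  (v - r[1]) / (r[2] - r[1])
}

#' Three-dimensional embedding of units mapped to RGB
#'
#' Reduces the (normalized) expression matrix to three dimensions — the top
#' three principal components, or a 3D t-SNE or UMAP embedding — and
#' min-max scales each dimension independently to `[0, 1]` so every unit
#' gets an RGB triple. Rendering the units at their centroids with these
#' colors shows expression similarity as color similarity across the tissue.
#'
#' @param mat units x genes numeric matrix (normalized counts recommended).
#' @param method `"pca"`, `"tsne"` or `"umap"`.
#' @param seed RNG seed making the stochastic methods reproducible.
#' @param ... extra arguments passed to [Rtsne::Rtsne()] or [uwot::umap()].
#' @return An object of class `embedding_result`: `scores` (units x 3),
#'   `rgb` (units x 3 in `[0, 1]`, each channel spanning exactly `[0, 1]`
#'   unless degenerate), `loadings` (PCA only), `method`, `seed`.
#' @export
rgb_embedding <- function(mat, method = c("pca", "tsne", "umap"),
                          seed = NULL, ...) {
  method <- match.arg(method)
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (n < 4L) stop("need at least 4 units to embed")
  if (!is.null(seed)) set.seed(seed)
  loadings <- NULL
  if (method == "pca") {
    p <- pca_report(mat, n_components = 3)
    sc <- p$scores
    if (ncol(sc) < 3L)
      sc <- cbind(sc, matrix(0, n, 3L - ncol(sc)))
    loadings <- p$loadings
  } else if (method == "tsne") {
    perp <- min(30, floor((n - 1) / 3))
    sc <- Rtsne::Rtsne(mat, dims = 3, perplexity = max(1, perp),
                       check_duplicates = FALSE, ...)$Y
  } else {
    sc <- uwot::umap(mat, n_components = 3,
                     n_neighbors = min(15, n - 1), n_threads = 1, ...)
  }
  colnames(sc) <- c("dim1", "dim2", "dim3")
  rgbm <- apply(sc, 2, minmax_scale)
  colnames(rgbm) <- c("r", "g", "b")
  structure(list(scores = sc, rgb = rgbm, loadings = loadings,
                 method = method, seed = seed),
            class = "embedding_result")
}

#' @export
print.embedding_result <- function(x, ...) {
  cat(sprintf("embedding_result (%s): %d units -> 3 dimensions%s\n",
              x$method, nrow(x$scores),
              if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  invisible(x)
}

#' Cluster units of a segmented map
#'
#' De novo clustering of the (normalized) expression matrix by k-means,
#' hierarchical clustering (Ward linkage on Euclidean distance, cut to `k`
#' groups) or DBSCAN. DBSCAN takes `eps` / `min_samples` instead of `k` and
#' labels noise units 0.
#'
#' @param mat units x genes numeric matrix.
#' @param method `"kmeans"`, `"hierarchical"` or `"dbscan"`.
#' @param k number of clusters (k-means, hierarchical); `2 <= k <= units`.
#' @param seed RNG seed (k-means initialization).
#' @param eps DBSCAN neighborhood radius in expression space.
#' @param min_samples DBSCAN core-point threshold (neighbors within `eps`,
#'   self included; default 5).
#' @return An object of class `cluster_assignment`: integer `cluster` per
#'   unit (0 = DBSCAN noise), `method`, `k`, `seed`, `params`.
#' @export
cluster_units <- function(mat, method = c("kmeans", "hierarchical", "dbscan"),
                          k = NULL, seed = NULL, eps = NULL,
                          min_samples = 5) {
  method <- match.arg(method)
  mat <- as.matrix(mat)
  n <- nrow(mat)
  params <- list()
  if (method %in% c("kmeans", "hierarchical")) {
    if (is.null(k) || k < 2L) stop("k >= 2 required for ", method)
    if (k > n) stop("k = ", k, " exceeds number of units (", n, ")")
    if (method == "kmeans") {
      if (!is.null(seed)) set.seed(seed)
      cl <- stats::kmeans(mat, centers = k, nstart = 10,
                          iter.max = 100)$cluster
    } else {
      cl <- stats::cutree(stats::hclust(stats::dist(mat),
                                        method = "ward.D2"), k = k)
    }
  } else {
    if (is.null(eps) || eps <= 0) stop("dbscan requires eps > 0")
    cl <- dbscan_labels(mat, eps, min_samples)
    params <- list(eps = eps, min_samples = min_samples)
    k <- max(cl)
  }
  structure(list(cluster = as.integer(cl), method = method, k = k,
                 seed = seed, params = params),
            class = "cluster_assignment")
}

# Classic DBSCAN on a dense distance matrix; noise keeps label 0.
dbscan_labels <- function(mat, eps, min_samples) {
  n <- nrow(mat)
  d <- as.matrix(stats::dist(mat))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))  # self included
  core <- vapply(nb, length, 0L) >= min_samples
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nb[[i]]
    while (length(queue) > 0L) {
      j <- queue[1L]; queue <- queue[-1L]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) queue <- c(queue, nb[[j]][labels[nb[[j]]] == 0L])
      }
    }
  }
  labels
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment (%s): %d units, %d cluster(s)%s\n",
              x$method, length(x$cluster), x$k,
              if (any(x$cluster == 0L))
                sprintf(", %d noise", sum(x$cluster == 0L)) else ""))
  invisible(x)
}

#' Mean expression per cluster
#'
#' @param assign a `cluster_assignment` aligned to the rows of `seg`.
#' @param seg a [segmented_map] (or matrix) the assignment was computed on.
#' @param normalized average per-gene-normalized values (default) instead of
#'   raw counts.
#' @return A clusters x genes matrix of mean expression; empty clusters get
#'   a zero row with a warning.
#' @export
cluster_summaries <- function(assign, seg, normalized = TRUE) {
  stopifnot(inherits(assign, "cluster_assignment"))
  mat <- if (normalized) normalize_by_gene_totals(seg)
         else if (inherits(seg, "segmented_map")) seg$counts
         else as.matrix(seg)
  if (length(assign$cluster) != nrow(mat))
    stop("assignment length does not match number of units")
  ids <- seq_len(max(assign$cluster, assign$k))
  out <- matrix(0, length(ids), ncol(mat),
                dimnames = list(ids, colnames(mat)))
  for (i in ids) {
    sel <- assign$cluster == i
    if (!any(sel)) {
      warning("cluster ", i, " is empty; zero row reported")
    } else {
      out[i, ] <- colMeans(mat[sel, , drop = FALSE])
    }
  }
  out
}

#' Spatial map of units colored by cluster or RGB embedding
#'
#' @param seg a [segmented_map] providing unit centroids.
#' @param color a `cluster_assignment`, an `embedding_result`, or a vector
#'   of colors per unit.
#' @param ... passed to [graphics::points()].
#' @export
plot_unit_map <- function(seg, color, ...) {
  stopifnot(inherits(seg, "segmented_map"))
  if (inherits(color, "cluster_assignment")) {
    pal <- grDevices::colorRampPalette(
      c("firebrick", "orange", "gold", "forestgreen", "royalblue",
        "purple", "deeppink"))(max(1, color$k))
    cols <- ifelse(color$cluster == 0L, "grey70", pal[pmax(1, color$cluster)])
  } else if (inherits(color, "embedding_result")) {
    cols <- grDevices::rgb(color$rgb[, 1], color$rgb[, 2], color$rgb[, 3])
  } else cols <- color
  graphics::plot(seg$centroids[, "x"], -seg$centroids[, "y"], col = cols,
                 pch = 15, cex = 0.6, asp = 1, xlab = "x (px)",
                 ylab = "-y (px)", main = paste(seg$unit_kind, "map"), ...)
}
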