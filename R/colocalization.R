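## Gene-gene colocalization: kNN connection counts against a label-shuffled
## permutation null, reported as Z-scores.

#' Exact k-nearest-neighbor graph of the reads
#'
#' Euclidean kNN over the read positions, computed exactly. Distance ties are
#' broken by read index (lower index wins) so the graph is deterministic.
#'
#' @param spots a [spot_table].
#' @param k number of neighbors per read; must satisfy `n > k >= 1`.
#' @return An object of class `neighbor_graph`: integer matrix `nn`
#'   (`n x k`, neighbor indices in increasing-distance order) and `k`.
#' @export
build_neighbor_graph <- function(spots, k) {
  stopifnot(inherits(spots, "spot_table"))
  n <- nrow(spots)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (n <= k) stop("need more reads (", n, ") than neighbors k = ", k)
  x <- spots$x; y <- spots$y
  nn <- matrix(0L, n, k)
  chunk <- max(1L, floor(2e6 / n))
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    d2 <- outer(x[idx], x, "-")^2 + outer(y[idx], y, "-")^2
    d2[cbind(seq_along(idx), idx)] <- Inf   # no self-neighbors
    for (r in seq_along(idx)) {
      # order() is stable, so equal distances resolve to the lower index
      nn[idx[r], ] <- order(d2[r, ])[seq_len(k)]
    }
  }
  structure(list(nn = nn, k = k), class = "neighbor_graph")
}

#' Gene-gene connection counts on a neighbor graph
#'
#' Counts directed neighbor links `i -> j` by the gene pair
#' `(gene(i), gene(j))`, then symmetrizes: off-diagonal entries are the sum
#' of both directions, diagonal entries (self-colocalization) are kept as
#' counted. The total of directed links is always `n * k`.
#'
#' @param graph a `neighbor_graph`.
#' @param labels gene label per read (length `n`).
#' @return A genes x genes numeric matrix of symmetrized connection counts.
#' @export
connection_counts <- function(graph, labels) {
  stopifnot(inherits(graph, "neighbor_graph"))
  n <- nrow(graph$nn)
  if (length(labels) != n) stop("labels must have one entry per read")
  f <- factor(labels)
  ei <- rep(seq_len(n), times = graph$k)
  ej <- as.vector(graph$nn)
  symmetrize_counts(as.integer(f)[ei], as.integer(f)[ej], levels(f))
}

# Directed pair tabulation + symmetrization shared by the permutation loop.
symmetrize_counts <- function(gi, gj, genes) {
  G <- length(genes)
  d <- matrix(tabulate(gi + (gj - 1L) * G, nbins = G * G), G, G,
              dimnames = list(genes, genes))
  s <- d + t(d)
  diag(s) <- diag(d)
  s
}

#' Neighborhood-enrichment test for gene colocalization
#'
#' Builds the read kNN graph once, counts observed gene-gene connections,
#' and compares them with a permutation null in which read positions (and
#' hence the graph) stay fixed while the gene-label vector is shuffled
#' uniformly at random. For each gene pair the Z-score is
#' `(x - mu) / sigma`, with `mu` and `sigma` the mean and sd of the
#' permuted connection counts: pairs that are spatial neighbors more often
#' than under random relabeling get a positive Z, mutually exclusive pairs a
#' negative Z. The diagonal measures spatial self-clustering of each gene.
#'
#' @param spots a [spot_table] with at least 2 distinct genes.
#' @param k neighbors per read (default 5).
#' @param n_permutations number of label shuffles (default 500; minimum 10,
#'   warning below 100).
#' @param seed integer seed for the single RNG stream driving the shuffles;
#'   with a fixed seed the full result is bit-reproducible.
#' @return An object of class `coloc_result`: matrices `observed`,
#'   `null_mean`, `null_sd`, `z` (genes x genes, symmetric), plus `k`,
#'   `n_permutations` and `seed`. Pairs with `sigma = 0` get `NaN` Z with a
#'   warning.
#' @export
neighborhood_enrichment <- function(spots, k = 5, n_permutations = 500,
                                    seed = NULL) {
  stopifnot(inherits(spots, "spot_table"))
  f <- factor(spots$gene)
  if (any(tabulate(f) == 0L)) {
    warning("gene(s) with zero reads excluded")
    f <- droplevels(f)
  }
  if (nlevels(f) < 2L) stop("need at least 2 genes")
  if (n_permutations < 10L) stop("n_permutations must be >= 10")
  if (n_permutations < 100L)
    warning("fewer than 100 permutations: null mean/sd will be noisy")
  graph <- build_neighbor_graph(spots, k)
  n <- nrow(spots)
  genes <- levels(f)
  G <- length(genes)
  gidx <- as.integer(f)
  ei <- rep(seq_len(n), times = graph$k)
  ej <- as.vector(graph$nn)
  observed <- symmetrize_counts(gidx[ei], gidx[ej], genes)
  if (!is.null(seed)) set.seed(seed)
  acc <- matrix(0, G, G)
  acc2 <- matrix(0, G, G)
  for (p in seq_len(n_permutations)) {
    lab <- gidx[sample.int(n)]
    s <- symmetrize_counts(lab[ei], lab[ej], genes)
    acc <- acc + s
    acc2 <- acc2 + s * s
  }
  mu <- acc / n_permutations
  # sample sd over permutations
  sigma <- sqrt(pmax(0, (acc2 - n_permutations * mu^2) / (n_permutations - 1)))
  z <- (observed - mu) / sigma
  if (any(sigma == 0)) {
    warning("gene pair(s) with zero null sd: Z set to NaN")
    z[sigma == 0] <- NaN
  }
  structure(list(observed = observed, null_mean = mu, null_sd = sigma, z = z,
                 genes = genes, k = graph$k,
                 n_permutations = n_permutations, seed = seed),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(
    "coloc_result: %d genes, k = %d, %d permutations%s\n",
    length(x$genes), x$k, x$n_permutations,
    if (is.null(x$seed)) "" else sprintf(" (seed %d)", x$seed)))
  cat("Z-scores:\n")
  print(round(x$z, 2))
  invisible(x)
}

#' Heat map of colocalization Z-scores
#'
#' Diverging palette: red for enriched (positive Z), blue for depleted.
#'
#' @param x a `coloc_result`.
#' @param ... passed to [graphics::image()].
#' @export
plot.coloc_result <- function(x, ...) {
  G <- length(x$genes)
  zl <- max(abs(x$z[is.finite(x$z)]), 1)
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(256)
  graphics::image(seq_len(G), seq_len(G), t(x$z[G:1, , drop = FALSE]),
                  zlim = c(-zl, zl), col = pal, axes = FALSE,
                  xlab = "", ylab = "", main = "colocalization Z", ...)
  graphics::axis(1, seq_len(G), x$genes, las = 2)
  graphics::axis(2, seq_len(G), rev(x$genes), las = 2)
}
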