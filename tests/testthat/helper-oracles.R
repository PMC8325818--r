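# Independent brute-force oracles and small fixture builders shared across
# test files. Oracles are deliberately naive (per-point loops, O(n^2)) and
# never call the package code paths they check.

# exhaustive kNN by per-point distance sort, ties to the lower index
oracle_knn <- function(x, y, k) {
  n <- length(x)
  out <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    d <- sqrt((x - x[i])^2 + (y - y[i])^2)
    d[i] <- Inf
    out[i, ] <- order(d, seq_len(n))[seq_len(k)]
  }
  out
}

# exhaustive min distance from each point to an origin point set
oracle_min_dist <- function(px, py, ox, oy) {
  vapply(seq_along(px), function(i) {
    min(sqrt((ox - px[i])^2 + (oy - py[i])^2))
  }, 0)
}

# naive per-read spot-environment rows
oracle_spot_env <- function(x, y, gene, radius) {
  genes <- sort(unique(gene))
  n <- length(x)
  out <- matrix(0L, n, length(genes), dimnames = list(NULL, genes))
  for (i in seq_len(n)) {
    d <- sqrt((x - x[i])^2 + (y - y[i])^2)
    out[i, ] <- as.integer(table(factor(gene[d <= radius], levels = genes)))
  }
  out
}

# naive symmetrized gene-pair connection counts from a neighbor matrix
oracle_connection_counts <- function(nn, labels) {
  genes <- sort(unique(labels))
  G <- length(genes)
  d <- matrix(0, G, G, dimnames = list(genes, genes))
  for (i in seq_len(nrow(nn))) {
    for (j in nn[i, ]) {
      gi <- match(labels[i], genes); gj <- match(labels[j], genes)
      d[gi, gj] <- d[gi, gj] + 1
    }
  }
  s <- d + t(d)
  diag(s) <- diag(d)
  s
}

# uniform complete-spatial-randomness table
csr_spots <- function(n_per_gene, genes = c("A", "B", "C"),
                      field = c(1000, 1000), seed = NULL) {
  spec <- tissue_spec(field = field,
                      background = lapply(genes, function(g)
                        list(genes = g, n = n_per_gene)))
  make_layered_tissue(spec, seed = seed)$spots
}

# coincident A-B pairs plus uniform background C (colocalization power)
pair_spots <- function(n_pairs = 300, n_bg = 300, offset = 1,
                       field = c(10000, 10000), seed = NULL) {
  spec <- tissue_spec(field = field,
                      pairs = list(list(gene_a = "A", gene_b = "B",
                                        n = n_pairs, offset = offset)),
                      background = list(list(genes = "C", n = n_bg)))
  make_layered_tissue(spec, seed = seed)$spots
}

# small 5-class reference with distinct marker blocks, 20 genes
toy_reference <- function(n_classes = 5, markers_per_class = 4,
                          hi = 8, lo = 0.5) {
  genes <- sprintf("g%02d", seq_len(n_classes * markers_per_class))
  m <- matrix(lo, n_classes, length(genes),
              dimnames = list(paste0("class", seq_len(n_classes)), genes))
  for (k in seq_len(n_classes)) {
    m[k, (k - 1) * markers_per_class + seq_len(markers_per_class)] <- hi
  }
  class_reference(m)
}

# three spatial regions with distinct gene signatures, binned; the bands
# are separated by empty 100 px gutters so every retained bin sits cleanly
# inside one region, and sparse boundary bins are removed by read QC
three_region_bins <- function(n_per_region = 600, seed = 1) {
  spec <- tissue_spec(field = c(1100, 300), layers = list(
    list(band = c(0, 300), axis = "x",
         genes = c(R1a = 4, R1b = 4, R2a = 0.2, R2b = 0.2,
                   R3a = 0.2, R3b = 0.2), n = n_per_region),
    list(band = c(400, 700), axis = "x",
         genes = c(R1a = 0.2, R1b = 0.2, R2a = 4, R2b = 4,
                   R3a = 0.2, R3b = 0.2), n = n_per_region),
    list(band = c(800, 1100), axis = "x",
         genes = c(R1a = 0.2, R1b = 0.2, R2a = 0.2, R2b = 0.2,
                   R3a = 4, R3b = 4), n = n_per_region)))
  tt <- make_layered_tissue(spec, seed = seed)
  seg <- qc_filter(overlapping_bins(tt$spots, radius = 50, spacing = 100),
                   min_reads = 15, min_gene_reads = 1)
  region <- findInterval(seg$centroids[, "x"], c(350, 750)) + 1L
  list(seg = seg, region = region)
}

# number of bins of a bin segmented_map whose square footprint contains (x, y)
bin_cover_oracle <- function(x, y, seg) {
  g <- seg$geometry
  sum(abs(x - g$cx) <= g$radius & abs(y - g$cy) <= g$radius)
}

# concatenate two spot tables preserving the class
rbind_spots <- function(a, b) {
  out <- rbind(as.data.frame(a), as.data.frame(b))
  class(out) <- c("spot_table", "data.frame")
  rownames(out) <- NULL
  out
}
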