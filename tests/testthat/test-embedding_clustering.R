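test_that("per-gene normalization makes columns sum to one", {
  counts <- matrix(c(4L, 0L, 2L, 6L, 1L, 3L), 2, 3,
                   dimnames = list(NULL, c("a", "b", "c")))
  seg <- segmented_map(counts, "bin", cbind(1:2, 1:2))
  nm <- normalize_by_gene_totals(seg)
  expect_equal(unname(colSums(nm)), rep(1, 3))
  # a single unit turns every expressed gene into exactly 1
  one <- segmented_map(matrix(c(3L, 5L), 1, 2,
                              dimnames = list(NULL, c("a", "b"))),
                       "bin", cbind(0, 0))
  expect_equal(unname(normalize_by_gene_totals(one)[1, ]), c(1, 1))
  # proportional columns (10x expresser, same pattern) become identical
  counts2 <- cbind(lo = c(1L, 3L, 6L), hi = c(10L, 30L, 60L))
  seg2 <- segmented_map(counts2, "bin", cbind(1:3, 1:3))
  nm2 <- normalize_by_gene_totals(seg2)
  expect_equal(nm2[, "lo"], nm2[, "hi"], tolerance = 1e-12)
  # zero-total genes direct the user to QC
  counts3 <- cbind(a = c(1L, 1L), dead = c(0L, 0L))
  expect_error(normalize_by_gene_totals(
    segmented_map(counts3, "bin", cbind(1:2, 1:2))), "qc_filter")
})

test_that("PCA reports rank, variance shares and analytic directions", {
  set.seed(20)
  # rank-2 data embedded in 5 genes
  basis <- matrix(rnorm(10), 2, 5)
  mat <- matrix(rnorm(120), 60, 2) %*% basis
  p <- pca_report(mat, n_components = 5)
  expect_lt(sum(p$variance_explained[-(1:2)]), 1e-9)
  expect_equal(sum(p$variance_explained), 1)
  expect_true(all(diff(p$variance_explained) <= 1e-12))

  # 2-gene toy with known covariance: PC1 along the analytic eigenvector
  S <- matrix(c(4, 1.2, 1.2, 1), 2, 2)
  L <- chol(S)
  x2 <- matrix(rnorm(4000), 2000, 2) %*% L
  p2 <- pca_report(x2, n_components = 2)
  ev <- eigen(S)$vectors[, 1]
  ev <- ev * sign(ev[which.max(abs(ev))])
  expect_lt(max(abs(abs(sum(p2$loadings[, 1] * ev)) - 1)), 0.01)

  # column order only permutes loadings (scores invariant up to sign fix)
  p3 <- pca_report(x2[, 2:1], n_components = 2)
  expect_equal(abs(p3$scores[, 1]), abs(p2$scores[, 1]), tolerance = 1e-9)

  expect_error(pca_report(matrix(1, 5, 3)), "constant")
})

test_that("RGB channels span [0,1] and identical profiles share a color", {
  set.seed(21)
  mat <- matrix(runif(40 * 6), 40, 6)
  mat[7, ] <- mat[3, ]
  for (m in c("pca", "umap")) {
    emb <- rgb_embedding(mat, method = m, seed = 9)
    expect_equal(unname(apply(emb$rgb, 2, min)), c(0, 0, 0))
    expect_equal(unname(apply(emb$rgb, 2, max)), c(1, 1, 1))
  }
  # identical profiles share a color (exact for the linear method)
  embp <- rgb_embedding(mat, method = "pca", seed = 9)
  expect_equal(embp$rgb[7, ], embp$rgb[3, ], tolerance = 1e-8)
  expect_error(rgb_embedding(mat[1:3, ]), "at least 4")
})

test_that("distinct spatial signatures separate in RGB space", {
  fx <- three_region_bins(seed = 22)
  nm <- normalize_by_gene_totals(qc_filter(fx$seg, min_gene_reads = 1))
  reg <- fx$region
  for (m in c("pca", "tsne", "umap")) {
    emb <- rgb_embedding(nm, method = m, seed = 23)
    d <- as.matrix(dist(emb$rgb))
    same <- outer(reg, reg, "==") & upper.tri(d)
    diff_ <- outer(reg, reg, "!=") & upper.tri(d)
    expect_gt(mean(d[diff_]), mean(d[same]))
  }
})

test_that("clustering recovers planted structure deterministically", {
  set.seed(24)
  blobs <- rbind(matrix(rnorm(60, 0, 0.3), 30, 2),
                 matrix(rnorm(60, 5, 0.3), 30, 2))
  truth <- rep(1:2, each = 30)
  for (m in c("kmeans", "hierarchical")) {
    cl <- cluster_units(blobs, method = m, k = 2, seed = 25)
    expect_equal(length(unique(paste(cl$cluster, truth))), 2L)
  }
  # hierarchical with k = n isolates every unit
  cln <- cluster_units(blobs[1:8, ], "hierarchical", k = 8)
  expect_equal(sort(cln$cluster), 1:8)
  expect_error(cluster_units(blobs, "kmeans", k = 100, seed = 1), "exceeds")
  expect_error(cluster_units(blobs, "kmeans", k = 1), "k >= 2")

  # permuting unit order permutes labels consistently (same partition)
  perm <- sample(nrow(blobs))
  clp <- cluster_units(blobs[perm, ], "hierarchical", k = 2)
  clo <- cluster_units(blobs, "hierarchical", k = 2)
  expect_equal(length(unique(paste(clp$cluster, clo$cluster[perm]))), 2L)

  # seeded kmeans is bit-reproducible
  a <- cluster_units(blobs, "kmeans", k = 2, seed = 26)
  b <- cluster_units(blobs, "kmeans", k = 2, seed = 26)
  expect_identical(a, b)
})

test_that("DBSCAN finds dense groups and labels outliers as noise", {
  set.seed(27)
  blobs <- rbind(matrix(rnorm(80, 0, 0.2), 40, 2),
                 matrix(rnorm(80, 4, 0.2), 40, 2),
                 c(50, 50))
  cl <- cluster_units(blobs, "dbscan", eps = 1, min_samples = 5)
  expect_equal(cl$k, 2L)
  expect_equal(cl$cluster[81], 0L)
  expect_equal(length(unique(cl$cluster[1:40])), 1L)
  expect_equal(length(unique(cl$cluster[41:80])), 1L)
  expect_error(cluster_units(blobs, "dbscan"), "eps")
})

test_that("k-means recovers a 3-cluster mixture across seeds (ARI >= 0.9)", {
  skip_if_not_installed("mclust")
  set.seed(28)
  centers <- matrix(c(0, 0, 6, 0, 0, 6), 3, 2, byrow = TRUE)
  truth <- rep(1:3, each = 40)
  mat <- centers[truth, ] + matrix(rnorm(240, 0, 0.5), 120, 2)
  aris <- vapply(1:10, function(s) {
    cl <- cluster_units(mat, "kmeans", k = 3, seed = s)
    mclust::adjustedRandIndex(cl$cluster, truth)
  }, 0)
  expect_true(all(aris >= 0.9))
})

test_that("cluster summaries average expression per planted marker group", {
  fx <- three_region_bins(seed = 29)
  seg <- qc_filter(fx$seg, min_gene_reads = 1)
  nm <- normalize_by_gene_totals(seg)
  asg <- structure(list(cluster = fx$region, method = "kmeans", k = 3L,
                        seed = NULL, params = list()),
                   class = "cluster_assignment")
  cs <- cluster_summaries(asg, seg)
  top <- colnames(cs)[apply(cs, 1, which.max)]
  expect_true(top[1] %in% c("R1a", "R1b"))
  expect_true(top[2] %in% c("R2a", "R2b"))
  expect_true(top[3] %in% c("R3a", "R3b"))

  # one cluster holding everything reproduces the global mean
  all1 <- structure(list(cluster = rep(1L, nrow(nm)), method = "kmeans",
                         k = 1L, seed = NULL, params = list()),
                    class = "cluster_assignment")
  expect_equal(unname(cluster_summaries(all1, seg)[1, ]),
               unname(colMeans(nm)))
  # a singleton cluster reproduces that unit's profile
  solo <- structure(list(cluster = c(1L, rep(2L, nrow(nm) - 1L)),
                         method = "kmeans", k = 2L, seed = NULL,
                         params = list()),
                    class = "cluster_assignment")
  expect_equal(unname(cluster_summaries(solo, seg)[1, ]), unname(nm[1, ]))
  # an empty cluster warns and reports zeros
  gap <- structure(list(cluster = rep(1L, nrow(nm)), method = "kmeans",
                        k = 2L, seed = NULL, params = list()),
                   class = "cluster_assignment")
  expect_warning(cs2 <- cluster_summaries(gap, seg), "empty")
  expect_equal(unname(cs2[2, ]), rep(0, ncol(nm)))
})
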