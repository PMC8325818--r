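test_that("well-separated synthetic nuclei are each recovered as one label", {
  ni <- make_nuclei_image(2, size = c(200, 120),
                          centers = rbind(c(60, 60), c(120, 60)),
                          nucleus_sd = 10, noise_sd = 0.02, seed = 1)
  lm <- segment_dapi(ni$image, tophat_radius = 25, expansion = 5)
  expect_equal(lm$n_cells, 2L)
  lab_at <- function(m, p) m[floor(p[1]) + 1L, floor(p[2]) + 1L]
  l1 <- lab_at(lm$mask, ni$centers[1, ])
  l2 <- lab_at(lm$mask, ni$centers[2, ])
  expect_true(l1 > 0 && l2 > 0 && l1 != l2)
})

test_that("expansion grows each cell monotonically around one nucleus", {
  ni <- make_nuclei_image(1, size = c(120, 120), centers = cbind(60, 60),
                          nucleus_sd = 10, seed = 2)
  areas <- vapply(c(0, 5, 10, 20), function(e) {
    lm <- segment_dapi(ni$image, tophat_radius = 25, expansion = e)
    sum(lm$mask > 0)
  }, 0)
  expect_equal(length(unique(areas)), 4L)
  expect_true(all(diff(areas) > 0))
})

test_that("touching nuclei are split by the distance-transform watershed", {
  # 3 sd separation: the thresholded blobs overlap into one connected
  # component whose distance transform still carries two maxima
  ni <- make_nuclei_image(2, size = c(160, 100),
                          centers = rbind(c(65, 50), c(95, 50)),
                          nucleus_sd = 10, seed = 3)
  lm <- segment_dapi(ni$image, tophat_radius = 25, threshold = 0.3,
                     expansion = 0)
  expect_equal(lm$n_cells, 2L)
})

test_that("a constant intensity offset does not change the segmentation", {
  ni <- make_nuclei_image(3, size = c(220, 220), nucleus_sd = 9, seed = 4)
  lm0 <- segment_dapi(ni$image, tophat_radius = 22, threshold = 0.3,
                      expansion = 4)
  shifted <- nuclear_image(ni$image$pixels + 0.15)
  lm1 <- segment_dapi(shifted, tophat_radius = 22, threshold = 0.3,
                      expansion = 4)
  expect_equal(lm1$n_cells, lm0$n_cells)
  expect_equal(lm1$mask, lm0$mask)
})

test_that("spot assignment conserves reads and respects the background rule", {
  mask <- matrix(0L, 10, 10)
  mask[2:4, 2:4] <- 1L
  mask[7:9, 7:9] <- 2L
  st <- spot_table(c("A", "B", "A", "C"),
                   x = c(2.5, 7.5, 5.0, 50),
                   y = c(2.5, 7.5, 5.0, 5))
  seg <- assign_spots(st, mask)
  expect_equal(seg$counts["1", "A"], 1L)
  expect_equal(seg$counts["2", "B"], 1L)
  expect_equal(sum(seg$counts) + attr(seg, "n_background") +
                 attr(seg, "n_out_of_extent"), nrow(st))
  expect_equal(attr(seg, "n_background"), 1L)
  expect_equal(attr(seg, "n_out_of_extent"), 1L)
})

test_that("reads generated inside known cells map back to their cell", {
  ref <- toy_reference()
  tc <- make_typed_cells(ref, 60, depth_range = c(30, 50), seed = 5)
  seg <- assign_spots(tc$spots, tc$mask)
  # recount per generating cell and compare with the assignment
  truth <- t(vapply(seq_len(60), function(i) {
    tabulate(match(tc$spots$gene[tc$cell == i], colnames(seg$counts)),
             ncol(seg$counts))
  }, numeric(ncol(seg$counts))))
  agree <- sum(pmin(seg$counts, truth)) / nrow(tc$spots)
  expect_gte(agree, 0.99)
})

test_that("tiling bins partition interior reads; overlapping bins multi-count", {
  set.seed(6)
  st <- spot_table(sample(c("A", "B"), 400, TRUE),
                   runif(400, 10, 190), runif(400, 10, 190))
  tiled <- overlapping_bins(st, radius = 25, spacing = 50)
  expect_equal(sum(tiled$counts), 400L)

  # spacing = radius: a strictly interior read covered by exactly 4 bins
  one <- spot_table("A", 101.3, 77.9)
  multi <- overlapping_bins(rbind_spots(one, st), radius = 25, spacing = 25)
  # single-read covering count via the brute-force membership oracle
  covered <- bin_cover_oracle(101.3, 77.9, multi)
  expect_equal(covered, 4L)

  # total bin mass equals the sum of per-read covering-bin counts (oracle)
  bins <- overlapping_bins(st, radius = 40, spacing = 30)
  n_cover <- vapply(seq_len(nrow(st)), function(j)
    bin_cover_oracle(st$x[j], st$y[j], bins), 0L)
  expect_equal(sum(bins$counts), sum(n_cover))
})

test_that("circular bins are squares cut to the disc", {
  st <- spot_table(c("A", "A"), c(50, 50 + 24), c(50, 50 + 24))
  sq <- overlapping_bins(st, radius = 25, spacing = 50)
  ci <- overlapping_bins(st, radius = 25, spacing = 50, circular = TRUE)
  expect_gte(sum(sq$counts), sum(ci$counts))
})

test_that("spot environments match the pairwise-distance oracle", {
  set.seed(7)
  n <- 500
  st <- spot_table(sample(c("A", "B", "C"), n, TRUE),
                   runif(n, 0, 300), runif(n, 0, 300))
  env <- spot_environment_bins(st, radius = 20)
  expect_equal(unname(env$counts), unname(oracle_spot_env(st$x, st$y,
                                                          st$gene, 20)))
  # an isolated read is a one-hot of its own gene
  iso <- spot_table(c("A", "B"), c(0, 1000), c(0, 1000))
  eiso <- spot_environment_bins(iso, radius = 5)
  expect_equal(unname(eiso$counts), rbind(c(1L, 0L), c(0L, 1L)))
  # two mutually close reads both see both
  near <- spot_table(c("A", "B"), c(0, 3), c(0, 0))
  enear <- spot_environment_bins(near, radius = 5)
  expect_equal(unname(rowSums(enear$counts)), c(2, 2))
})

test_that("qc_filter drops planted units/genes, is idempotent, errors when empty", {
  counts <- matrix(10L, 8, 5,
                   dimnames = list(NULL, paste0("g", 1:5)))
  counts[1, ] <- c(1L, 1L, 0L, 0L, 0L)     # low unit
  counts[, 5] <- 0L                         # dead gene
  counts[2, 1] <- 60L                       # high unit
  seg <- segmented_map(counts, "bin", cbind(seq_len(8), seq_len(8)))
  expect_identical(qc_filter(seg, 0, Inf, 0)$counts, seg$counts)
  filt <- qc_filter(seg, min_reads = 5, max_reads = 80,
                    min_gene_reads = 1)
  # unit 1 (3 reads) and unit 2 (90 reads) both leave; gene 5 is dead
  expect_equal(nrow(filt$counts), 6L)
  expect_equal(ncol(filt$counts), 4L)
  expect_equal(attr(filt, "n_units_dropped"), 2L)
  expect_equal(attr(filt, "n_genes_dropped"), 1L)
  again <- qc_filter(filt, min_reads = 5, max_reads = 80,
                     min_gene_reads = 1)
  expect_identical(again$counts, filt$counts)
  expect_error(qc_filter(seg, min_reads = 1e6), "quantiles")
})
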