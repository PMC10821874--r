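# Joint-modality QC metrics, filtering, normalization, embeddings,
# clustering and gene activity.

test_that("percent.mt and fragment metrics match hand-built cases", {
  rna <- rbind(c(90, 10), c(50, 50))
  d <- toy_multiome(rna, matrix(1, 2, 3), gene_contig = c("chr1", "chrM"))
  ## all fragments length 100 (sub-nucleosomal): nucleosome signal 0
  fr <- data.frame(chrom = "chr1", start = c(1000L, 2000L),
                   end = c(1100L, 2100L),
                   barcode = c("c1", "c2"), count = 1L,
                   stringsAsFactors = FALSE)
  d$fragments <- fr
  qc <- compute_qc_metrics(d)
  expect_equal(qc$percent.mt, c(10, 50))
  expect_equal(qc$nCount_RNA, c(100, 100))
  expect_equal(qc$nucleosome_signal, c(0, 0))
})

test_that("fragments uniformly covering TSS +/- 1000 give enrichment near 1", {
  rna <- matrix(5, 1, 1)
  d <- toy_multiome(rna, matrix(1, 1, 2))
  tss <- d$genes$tss[1]
  ## tile the 2-kb window around the TSS with abutting 100-bp fragments
  starts <- seq(tss - 1000L, tss + 900L, by = 100L)
  d$fragments <- data.frame(chrom = "chr1", start = starts,
                            end = starts + 100L, barcode = "c1",
                            count = 1L, stringsAsFactors = FALSE)
  qc <- compute_qc_metrics(d)
  ## uniform coverage of 1x: center mean 1, flank mean 1, pseudocount 0.1
  expect_equal(qc$TSS.enrichment, 1 / 1.1, tolerance = 0.05)
})

test_that("missing fragments flag ATAC metrics unavailable, not zero", {
  d <- toy_multiome(matrix(5, 2, 2), matrix(1, 2, 2))
  expect_warning(qc <- compute_qc_metrics(d), "fragments")
  expect_true(all(is.na(qc$nucleosome_signal)))
  expect_false(attr(qc, "atac_metrics_available"))
})

test_that("filtering removes exactly the cells violating each criterion", {
  ## 6 cells, one violating each criterion, plus one clean survivor
  qc <- data.frame(
    barcode = paste0("c", 1:7),
    nCount_RNA = c(150, 5000, 5000, 5000, 5000, 5000, 5000),
    nFeature_RNA = c(100, 8000, 100, 100, 100, 100, 100),
    percent.mt = c(1, 1, 25, 1, 1, 1, 1),
    nCount_ATAC = c(5000, 5000, 5000, 150, 5000, 5000, 5000),
    nucleosome_signal = c(0.5, 0.5, 0.5, 0.5, 3, 0.5, 0.5),
    TSS.enrichment = c(5, 5, 5, 5, 5, 1, 5),
    stringsAsFactors = FALSE)
  d <- toy_multiome(matrix(5, 7, 2), matrix(1, 7, 2))
  rownames(d$rna) <- rownames(d$atac) <- d$cells$barcode <- qc$barcode
  filt <- filter_cells(d, qc)
  expect_equal(rownames(filt$rna), "c7")
  removed <- attr(filt, "qc_removed")
  expect_equal(unname(removed["nCount_RNA"]), 1)
  expect_equal(unname(removed["TSS.enrichment"]), 1)
  ## boundary cases are strict: TSS.enrichment == 1 is removed
  qc$TSS.enrichment[6] <- 1
  filt2 <- filter_cells(d, qc)
  expect_false("c6" %in% rownames(filt2$rna))
  ## idempotence
  sim <- small_sim()
  f1 <- filter_cells(sim$dataset)
  f2 <- filter_cells(f1)
  expect_identical(rownames(f1$rna), rownames(f2$rna))
})

test_that("QC metrics are independent of cell order", {
  sim <- small_sim()
  d <- sim$dataset
  qc1 <- compute_qc_metrics(d)
  perm <- rev(rownames(d$rna))
  qc2 <- compute_qc_metrics(subset_cells(d, perm))
  expect_equal(qc2[match(qc1$barcode, qc2$barcode), -1], qc1[, -1],
               ignore_attr = TRUE)
})

test_that("normalization matches hand arithmetic and is size-factor invariant", {
  counts <- rbind(c(2, 2), c(8, 8))   # totals 4 and 16, median 10
  d <- toy_multiome(counts, matrix(1, 2, 2))
  d <- normalize_rna(d)
  expect_equal(d$layers$lognorm,
               log1p(counts * c(10 / 4, 10 / 16)), ignore_attr = TRUE)
  ## doubling all counts of one cell leaves its normalized row unchanged
  counts2 <- counts; counts2[1, ] <- counts2[1, ] * 2
  d2 <- normalize_rna(toy_multiome(counts2, matrix(1, 2, 2)))
  ## cell 1's row: totals double, size factor halves
  expect_equal(d2$layers$lognorm[1, ] * 0 + expm1(d2$layers$lognorm[1, ]) /
                 expm1(d$layers$lognorm[1, ]),
               c(g1 = 1.2, g2 = 1.2), tolerance = 1e-9)
  ## a cell at the median total keeps log1p of its counts
  counts3 <- rbind(c(5, 5), c(2, 8), c(9, 1))  # all totals 10
  d3 <- normalize_rna(toy_multiome(counts3, matrix(1, 3, 2)))
  expect_equal(unname(d3$layers$lognorm[1, ]), log1p(c(5, 5)))
  expect_error(normalize_rna(toy_multiome(rbind(c(0, 0), c(1, 1)),
                                          matrix(1, 2, 2))), "zero")
})

test_that("PCA and LSI embeddings have the documented shape and behaviour", {
  d <- small_norm()
  emb <- reduce_dimensions(d, d_rna = 10L, d_atac = 10L, n_hvg = 150L)
  expect_equal(colnames(emb$lsi), paste0("LSI_", 2:10))
  expect_equal(ncol(emb$pca), 10L)
  ## rank-1 RNA matrix: PC1 carries essentially all variance
  u <- outer(1:10, c(1, 2, 3, 4, 5))
  dd <- toy_multiome(u, matrix(rbinom(10 * 30, 1, 0.5), 10, 30))
  dd <- normalize_rna(dd)
  dd$layers$lognorm[] <- u  # exactly rank 1, bypass log scaling
  e2 <- reduce_dimensions(dd, d_rna = 3L, d_atac = 3L, n_hvg = 5L)
  vare <- e2$rna_singular_values^2
  expect_gt(vare[1] / sum(vare), 0.999)
})

test_that("the dropped LSI component tracks depth more than any retained one", {
  cfg <- small_cfg(depth_sdlog = 0.8, junk_frac = 0)
  sim <- simulate_multiome(cfg, seed = 2)
  d <- normalize_rna(sim$dataset)
  emb <- reduce_dimensions(d, n_hvg = 150L)
  dep <- log(Matrix::rowSums(d$atac))
  r1 <- abs(stats::cor(emb$lsi_full[, 1], dep))
  expect_gt(r1, 0.9)
  expect_gt(r1, max(abs(stats::cor(emb$lsi, dep))))
})

test_that("clustering recovers planted blobs and is deterministic", {
  set.seed(99)
  blob <- rbind(matrix(rnorm(200, 0), 100, 2),
                matrix(rnorm(200, 10), 100, 2))
  rownames(blob) <- paste0("c", 1:200)
  cl <- cluster_cells(blob, k = 10L, resolution = 0.2, seed = 1)
  expect_equal(nlevels(cl), 2L)
  expect_equal(ari(cl, rep(1:2, each = 100)), 1)
  expect_identical(cl, cluster_cells(blob, k = 10L, resolution = 0.2,
                                     seed = 1))
  expect_error(cluster_cells(blob, k = 200L), "smaller")
  one <- cluster_cells(blob[1, , drop = FALSE], k = 5L)
  expect_equal(nlevels(one), 1L)
})

test_that("gene activity counts fragments in the extended gene body", {
  d <- toy_multiome(matrix(5, 1, 2), matrix(1, 1, 2),
                    strand = c("+", "-"))
  g <- d$genes
  ## gene 1 (+): window [tss-2000, tss+500); gene 2 (-): [tss-500, tss+2000)
  fr <- rbind(
    data.frame(chrom = "chr1", start = g$tss[1] + 10L,
               end = g$tss[1] + 110L, barcode = "c1", count = 1L),
    ## only in the promoter extension of the minus-strand gene
    ## (downstream of the body in genomic coordinates)
    data.frame(chrom = "chr1", start = g$tss[2] + 1500L,
               end = g$tss[2] + 1600L, barcode = "c1", count = 1L),
    ## far from both genes
    data.frame(chrom = "chr1", start = 99000L, end = 99100L,
               barcode = "c1", count = 1L))
  d$fragments <- fr
  act <- gene_activity(d)
  expect_equal(as.numeric(act[1, ]), c(1, 1))
  ## no fragments in a window -> activity 0
  d$fragments <- fr[3, , drop = FALSE]
  act0 <- gene_activity(d)
  expect_equal(as.numeric(act0[1, ]), c(0, 0))
})
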