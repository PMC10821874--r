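# The synthetic multiome generator: program construction, cell states,
# count rendering, on-disk round trips and validation assets.

test_that("regulatory program echoes its configuration and validates", {
  prog <- small_sim()$program
  cfg <- prog$config
  expect_equal(cfg$n_branches, 5L)
  expect_equal(cfg$tfs_per_branch, 2L)
  expect_equal(sum(prog$genes$type == "tf"), 10L)
  expect_equal(nrow(prog$peaks), 640L)
  expect_equal(nrow(prog$genes), 200L)
  ## every planted link within the default window of its gene's TSS
  tss <- stats::setNames(prog$genes$tss, prog$genes$gene_id)
  pk <- prog$peaks[match(prog$links$peak_id, prog$peaks$peak_id), ]
  expect_true(all(abs((pk$start + pk$end) / 2 -
                        tss[prog$links$gene_id]) <= 5e5))
  ## mitochondrial genes only on chrM
  expect_true(all((prog$genes$contig == "chrM") ==
                    (prog$genes$type == "mito")))
})

test_that("bad configurations are rejected", {
  expect_error(sim_config(n_branches = 1L), "2 branches")
  expect_error(sim_config(n_genes = 30L), "50 genes")
  expect_error(sim_config(n_genes = 200L, n_peaks = 100L), "as many peaks")
  expect_error(sim_config(nb_theta = 0), "positive")
  ## background peaks that cannot be placed within contigs
  expect_error(
    build_regulatory_program(sim_config(n_genes = 200L, n_peaks = 3000L),
                             seed = 1),
    "contig bounds")
})

test_that("identical (config, seed) reproduce the program bit-identically", {
  cfg <- small_cfg()
  p1 <- build_regulatory_program(cfg, seed = 7)
  p2 <- build_regulatory_program(cfg, seed = 7)
  g1 <- as.character(p1$genome); g2 <- as.character(p2$genome)
  p1$genome <- NULL; p2$genome <- NULL
  expect_identical(p1, p2)
  expect_identical(g1, g2)
})

test_that("each branch TF's consensus is planted in its targets' enhancers", {
  prog <- small_sim()$program
  enh <- prog$peaks[prog$peaks$role == "enhancer", ]
  tf_of <- stats::setNames(prog$genes$tf, prog$genes$gene_id)
  mm <- prog$motif_map
  targets <- prog$genes$gene_id[prog$genes$type == "target"]
  for (tg in targets) {
    e <- enh[enh$gene == tg, , drop = FALSE]
    cs <- mm$consensus[mm$tf == tf_of[[tg]]]
    found <- vapply(seq_len(nrow(e)), function(i) {
      s <- as.character(Biostrings::subseq(prog$genome[[e$contig[i]]],
                                           e$start[i] + 1L, e$end[i]))
      grepl(cs, s, fixed = TRUE)
    }, TRUE)
    expect_true(any(found), label = paste("motif found for", tg))
  }
})

test_that("cell states honour stage sizes and the branching rule", {
  prog <- small_sim()$program
  st <- simulate_cell_states(prog, c(100L, 100L, 100L, 100L), seed = 3)
  expect_equal(as.integer(table(st$stage)), rep(100L, 4L))
  expect_true(all(st$branch[st$s <= prog$branch_point] == "multipotent"))
  expect_true(all(st$branch[st$s > prog$branch_point] != "multipotent"))
  expect_error(simulate_cell_states(prog, c(0L, 10L, 10L, 10L)), "positive")
  ## determinism
  expect_identical(st, simulate_cell_states(prog, rep(100L, 4L), seed = 3))
})

test_that("terminal branch shares match configured weights (binomial CI)", {
  prog <- small_sim()$program
  st <- simulate_cell_states(prog, c(10L, 10L, 10L, 2000L), seed = 5)
  late <- st[st$stage == "t3" & st$branch != "multipotent", ]
  n <- nrow(late)
  for (b in seq_len(prog$config$n_branches)) {
    phat <- mean(late$branch == paste0("branch", b))
    p0 <- prog$branch_weights[b]
    ## 99% binomial CI around the configured weight
    half <- stats::qnorm(0.995) * sqrt(p0 * (1 - p0) / n)
    expect_true(abs(phat - p0) < half + 1e-9,
                label = sprintf("branch %d share %.3f vs %.3f", b, phat, p0))
  }
})

test_that("per-gene count variance follows the NB mean-variance law", {
  cfg <- sim_config(n_genes = 200L, n_peaks = 640L, junk_frac = 0,
                    cells_per_stage = rep(500L, 4L))
  prog <- build_regulatory_program(cfg, seed = 11)
  st <- simulate_cell_states(prog, cfg$cells_per_stage, seed = 12)
  d <- render_multiome_counts(prog, st, seed = 13)
  x <- as.matrix(d$rna)
  ## housekeeping genes have a constant per-cell mean modulation, so their
  ## pooled moments are cleanly NB around depth x baseline
  hk <- prog$genes$gene_id[prog$genes$type == "hk"]
  m <- colMeans(x[, hk]); v <- apply(x[, hk], 2, stats::var)
  ## correct for depth spread: var = E[var|depth] + var(depth) * baseline^2
  depth <- st$rna_depth
  base <- m / mean(depth)
  pred <- mean(depth) * base + (mean(depth^2) / mean(depth)^2) *
    base^2 * mean(depth)^2 / cfg$nb_theta +
    stats::var(depth) * base^2
  keep <- m > 0.5
  rel <- (v - pred)[keep] / pred[keep]
  expect_lt(abs(mean(rel)), 0.1)
  expect_lt(stats::median(abs(rel)), 0.25)
})

test_that("zero link weights leave gene-enhancer correlations at zero", {
  cfg <- small_cfg(link_weight = 0)
  sim <- simulate_multiome(cfg, seed = 21)
  d <- normalize_rna(filter_cells(sim$dataset))
  links <- sim$truth$links
  r <- vapply(seq_len(nrow(links)), function(i) {
    stats::cor(d$layers$lognorm[, links$gene_id[i]],
               as.numeric(d$atac[, links$peak_id[i]]))
  }, 0)
  ## centered on zero; individual |r| values at this cell count carry
  ## block-correlated finite-size noise (shared per-branch depth draws),
  ## so only the location and gross spread are constrained here. The
  ## formal type-I calibration at 2,000 cells is in the acceptance suite.
  expect_lt(abs(mean(r)), 0.03)
  expect_lt(mean(abs(r) > 0.3), 0.03)
})

test_that("junk barcodes fail QC at the configured rate (defaults)", {
  ## default feature scale: the QC thresholds are calibrated against it
  cfg <- sim_config(junk_frac = 0.1, cells_per_stage = rep(250L, 4L))
  sim <- simulate_multiome(cfg, seed = 31)
  qc <- compute_qc_metrics(sim$dataset)
  filt <- filter_cells(sim$dataset, qc)
  n_fail <- nrow(sim$dataset$rna) - nrow(filt$rna)
  ## 1000 real cells + 100 junk appended; roughly the junk should fail
  expect_gte(n_fail, 85)
  expect_lte(n_fail, 115)
  expect_true(all(!grepl("^junk", rownames(filt$rna))))
  ## RNA totals track the generating depth factors at default noise
  st <- sim$states
  tot <- Matrix::rowSums(sim$dataset$rna[st$barcode, ])
  expect_gt(stats::cor(tot, st$rna_depth, method = "spearman"), 0.95)
})

test_that("fragments are consistent with the ATAC count matrix", {
  sim <- small_sim()
  d <- sim$dataset
  fc <- table(d$fragments$barcode)
  rs <- Matrix::rowSums(d$atac)
  nz <- names(rs)[rs > 0]
  expect_equal(as.integer(fc[nz]), as.integer(rs[nz]))
})

test_that("datasets round-trip through the on-disk layout", {
  sim <- small_sim()
  dir <- withr::local_tempdir()
  write_dataset(sim$dataset, dir, truth = sim$truth, force = TRUE)
  expect_error(write_dataset(sim$dataset, dir), "force")
  back <- read_dataset(dir)
  expect_equal(as.matrix(back$dataset$rna), as.matrix(sim$dataset$rna))
  expect_equal(as.matrix(back$dataset$atac), as.matrix(sim$dataset$atac))
  expect_equal(back$dataset$genes, sim$dataset$genes)
  expect_equal(back$dataset$cells, sim$dataset$cells)
  expect_equal(back$dataset$fragments$start, sim$dataset$fragments$start)
  ## peaks.bed has one line per peak; MTX holds the stored nonzeros
  expect_equal(length(readLines(file.path(dir, "peaks.bed"))),
               nrow(sim$dataset$peaks))
  expect_equal(Matrix::nnzero(back$dataset$rna),
               Matrix::nnzero(sim$dataset$rna))
  ## ground truth round trip
  expect_equal(back$truth$links, sim$truth$links)
  expect_equal(back$truth$edges, sim$truth$edges)
  expect_equal(back$truth$states$s, sim$truth$states$s)
  expect_equal(back$truth$program$genes, sim$truth$program$genes)
})

test_that("validation assets have the planted structure", {
  prog <- small_sim()$program
  ## zero noise: every ChIP peak lies within 5 kb of a true-target TSS
  va0 <- simulate_validation_assets(prog, seed = 41, noise_rate = 0)
  tf <- names(va0$chip)[1]
  tg <- prog$genes$gene_id[!is.na(prog$genes$tf) & prog$genes$tf == tf]
  ann <- prog$genes[prog$genes$gene_id %in% tg, ]
  for (rep_ in va0$chip[[tf]]) {
    mid <- (rep_$start + rep_$end) / 2
    near <- vapply(seq_len(nrow(rep_)), function(i) {
      any(ann$contig == rep_$contig[i] & abs(ann$tss - mid[i]) <= 5000)
    }, TRUE)
    expect_true(all(near))
  }
  ## replicates differ but overlap substantially
  va <- simulate_validation_assets(prog, seed = 42, noise_rate = 0.2)
  reps <- va$chip[[1]]
  expect_false(identical(reps[[1]], reps[[2]]))
  expect_gt(interval_jaccard(reps[[1]], reps[[2]]), 0.3)
  ## curated list overlap honours the configured rate
  va_hit <- simulate_validation_assets(prog, seed = 43,
                                       curated_overlap = 0.5,
                                       curated_size = 40L)
  targets <- prog$genes$gene_id[prog$genes$type == "target"]
  expect_equal(sum(va_hit$curated_genes %in% targets), 20L)
  va_none <- simulate_validation_assets(prog, seed = 44,
                                        curated_overlap = 0)
  expect_equal(sum(va_none$curated_genes %in% targets), 0L)
})
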