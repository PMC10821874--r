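# Shared fixtures, built once per test session and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (is.null(.fixture_env[[name]])) assign(name, fn(), .fixture_env)
  get(name, .fixture_env)
}

## small but fully structured synthetic dataset (320 real cells)
small_cfg <- function(...) {
  sim_config(n_genes = 200L, n_peaks = 640L,
             cells_per_stage = rep(80L, 4L), ...)
}

small_sim <- function() {
  fixture("small_sim", function() simulate_multiome(small_cfg(), seed = 101))
}

small_norm <- function() {
  fixture("small_norm", function() {
    normalize_rna(filter_cells(small_sim()$dataset))
  })
}

program_motifs <- function(program) {
  ml <- mapply(function(m, id, tf) motif_model(id, tf, m),
               program$motifs, names(program$motifs),
               program$motif_map$tf, SIMPLIFY = FALSE)
  class(ml) <- "MotifModelList"
  ml
}

small_hits <- function() {
  fixture("small_hits", function() {
    d <- small_norm()
    scan_motifs(d$genome, d$peaks, program_motifs(small_sim()$program))
  })
}

## minimal hand-built paired dataset for toy QC/linkage cases
toy_multiome <- function(rna, atac, gene_contig = NULL, strand = NULL,
                         fragments = NULL, genome = NULL) {
  n_genes <- ncol(rna); n_peaks <- ncol(atac)
  if (is.null(colnames(rna))) colnames(rna) <- paste0("g", seq_len(n_genes))
  if (is.null(rownames(rna))) {
    rownames(rna) <- paste0("c", seq_len(nrow(rna)))
  }
  rownames(atac) <- rownames(rna)
  contigs <- c(chr1 = 100000L, chrM = 10000L)
  if (is.null(gene_contig)) gene_contig <- rep("chr1", n_genes)
  tss <- ifelse(gene_contig == "chrM", 1000L + seq_len(n_genes) * 200L,
                10000L + seq_len(n_genes) * 3000L)
  if (is.null(strand)) strand <- rep("+", n_genes)
  genes <- data.frame(gene_id = colnames(rna), contig = gene_contig,
                      strand = strand, tss = tss,
                      body_start = ifelse(strand == "+", tss, tss - 500L),
                      body_end = ifelse(strand == "+", tss + 500L, tss),
                      stringsAsFactors = FALSE)
  start <- 500L + seq_len(n_peaks) * 600L
  peaks <- data.frame(peak_id = make_peak_ids("chr1", start, start + 500L),
                      contig = "chr1", start = start, end = start + 500L,
                      stringsAsFactors = FALSE)
  colnames(atac) <- peaks$peak_id
  multiome_dataset(
    rna = Matrix::Matrix(rna, sparse = TRUE),
    atac = Matrix::Matrix(atac, sparse = TRUE),
    fragments = fragments, genes = genes, peaks = peaks,
    contigs = contigs, genome = genome,
    cells = data.frame(barcode = rownames(rna),
                       stage = rep_len(paste0("t", 0:3), nrow(rna)),
                       stringsAsFactors = FALSE))
}

## adjusted Rand index, independent implementation
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_ <- si * sj / n
  (sij - exp_) / ((si + sj) / 2 - exp_)
}

## interval-set Jaccard by total overlap basepairs (brute force)
interval_jaccard <- function(a, b) {
  ov <- 0
  for (i in seq_len(nrow(a))) {
    same <- b[b$contig == a$contig[i], , drop = FALSE]
    if (!nrow(same)) next
    ov <- ov + sum(pmax(0, pmin(a$end[i], same$end) -
                          pmax(a$start[i], same$start)))
  }
  la <- sum(a$end - a$start); lb <- sum(b$end - b$start)
  ov / (la + lb - ov)
}

## exact solver for small balanced transport LPs by enumerating bases
lp_transport <- function(a, b, C) {
  m <- length(a); n <- length(b)
  vars <- expand.grid(i = seq_len(m), j = seq_len(n))
  nv <- nrow(vars)
  A <- matrix(0, m + n, nv)
  for (v in seq_len(nv)) {
    A[vars$i[v], v] <- 1
    A[m + vars$j[v], v] <- 1
  }
  rhs <- c(a, b)
  A <- A[-(m + n), , drop = FALSE]   # drop one redundant constraint
  rhs <- rhs[-(m + n)]
  best <- Inf; best_x <- NULL
  for (basis in utils::combn(nv, m + n - 1, simplify = FALSE)) {
    Ab <- A[, basis, drop = FALSE]
    if (abs(det(Ab)) < 1e-10) next
    xb <- solve(Ab, rhs)
    if (any(xb < -1e-9)) next
    x <- numeric(nv); x[basis] <- xb
    cost <- sum(x * as.vector(C))
    if (cost < best - 1e-12) { best <- cost; best_x <- x }
  }
  list(cost = best, plan = matrix(best_x, m, n))
}

## hand step-up BH, independent of stats::p.adjust
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}
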