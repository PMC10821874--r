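#' Joint-modality per-cell QC metrics
#'
#' Computes the six QC quantities used to filter multiome cells:
#' \itemize{
#'   \item nCount_RNA, nFeature_RNA: total RNA counts and detected genes;
#'   \item percent.mt: percent of RNA counts on genes of contig "chrM";
#'   \item nCount_ATAC: total ATAC counts;
#'   \item nucleosome_signal: (fragments with length in [147, 294]) /
#'     max(1, fragments with length < 147), per cell;
#'   \item TSS.enrichment: mean per-base fragment coverage in TSS +/- 50 bp
#'     divided by mean coverage in the outer flanks
#'     [-1000, -901] and [901, 1000] (pseudocount 0.1 in the denominator),
#'     aggregated over all annotated TSS.
#' }
#'
#' @param dataset a \code{MultiomeDataset}. If the fragments table is
#'   missing, the fragment-based ATAC metrics are returned as NA with
#'   \code{atac_metrics_available = FALSE} (never silently zero).
#' @return a \code{CellQCTable} data.frame, one row per cell.
#' @export
compute_qc_metrics <- function(dataset) {
  stopifnot(inherits(dataset, "MultiomeDataset"))
  rna <- dataset$rna
  barcodes <- rownames(rna)
  n_count_rna <- Matrix::rowSums(rna)
  n_feature_rna <- Matrix::rowSums(rna > 0)
  mito <- dataset$genes$gene_id[dataset$genes$contig == "chrM"]
  mito <- intersect(mito, colnames(rna))
  mt_counts <- if (length(mito)) {
    Matrix::rowSums(rna[, mito, drop = FALSE])
  } else rep(0, length(barcodes))
  percent_mt <- ifelse(n_count_rna > 0, 100 * mt_counts / n_count_rna, 0)
  n_count_atac <- Matrix::rowSums(dataset$atac)

  qc <- data.frame(
    barcode = barcodes,
    nCount_RNA = as.numeric(n_count_rna),
    nFeature_RNA = as.numeric(n_feature_rna),
    percent.mt = as.numeric(percent_mt),
    nCount_ATAC = as.numeric(n_count_atac),
    nucleosome_signal = NA_real_,
    TSS.enrichment = NA_real_,
    stringsAsFactors = FALSE
  )
  atac_available <- !is.null(dataset$fragments) && nrow(dataset$fragments) > 0
  if (atac_available) {
    fr <- dataset$fragments
    len <- fr$end - fr$start
    idx <- match(fr$barcode, barcodes)
    keep <- !is.na(idx)
    mono <- tabulate(idx[keep & len >= 147 & len <= 294],
                     nbins = length(barcodes))
    sub <- tabulate(idx[keep & len < 147], nbins = length(barcodes))
    qc$nucleosome_signal <- mono / pmax(1, sub)
    qc$TSS.enrichment <- .tss_enrichment(fr, dataset$genes, barcodes)
  } else {
    warning("fragments table missing; fragment-based ATAC metrics are NA")
  }
  attr(qc, "atac_metrics_available") <- atac_available
  class(qc) <- c("CellQCTable", "data.frame")
  qc
}

## Aggregate TSS profile per cell: total fragment-overlap bp across the
## +/-50 bp windows of all TSS divided by window width, over the same for
## the outermost 100-bp flanks, with pseudocount 0.1 in the denominator.
.tss_enrichment <- function(fragments, genes, barcodes) {
  tss <- genes$tss
  contig <- genes$contig
  fr_gr <- intervals_to_granges(fragments$chrom, fragments$start,
                                fragments$end)
  win <- function(lo, hi) {
    intervals_to_granges(contig, pmax(0L, tss + lo), tss + hi)
  }
  center <- win(-50L, 50L)
  flank <- c(win(-1000L, -901L), win(901L, 1000L))
  idx <- match(fragments$barcode, barcodes)
  overlap_bp <- function(windows) {
    hits <- GenomicRanges::findOverlaps(fr_gr, windows)
    if (!length(hits)) return(rep(0, length(barcodes)))
    q <- S4Vectors::queryHits(hits)
    ov <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(fr_gr)[q],
      IRanges::ranges(windows)[S4Vectors::subjectHits(hits)]))
    cell <- idx[q]
    keep <- !is.na(cell)
    as.numeric(tapply2(ov[keep], cell[keep], length(barcodes)))
  }
  ctr_bp <- overlap_bp(center)
  flk_bp <- overlap_bp(flank)
  (ctr_bp / 101) / (flk_bp / 200 + 0.1)
}

## sum `x` by integer group id over 1..n (fast, no factor overhead)
tapply2 <- function(x, g, n) {
  out <- numeric(n)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Default QC thresholds
#'
#' All six bounds are strict inequalities: 200 < nCount_RNA < 100000,
#' nFeature_RNA < 7500, percent.mt < 20, 200 < nCount_ATAC < 100000,
#' nucleosome_signal < 2, TSS.enrichment > 1.
#' @export
qc_thresholds <- function(nCount_RNA_min = 200, nCount_RNA_max = 1e5,
                          nFeature_RNA_max = 7500, percent_mt_max = 20,
                          nCount_ATAC_min = 200, nCount_ATAC_max = 1e5,
                          nucleosome_signal_max = 2, tss_enrichment_min = 1) {
  as.list(environment())
}

#' Filter cells on joint RNA/ATAC QC criteria
#'
#' Keeps cells passing ALL six criteria (strict bounds exactly as in
#' \code{\link{qc_thresholds}}) and reports how many cells each criterion
#' removed.
#'
#' @param dataset a \code{MultiomeDataset}.
#' @param qc a \code{CellQCTable}; computed if missing.
#' @param thresholds list from \code{\link{qc_thresholds}}.
#' @return the filtered \code{MultiomeDataset}; removal counts per criterion
#'   in \code{attr(, "qc_removed")}, the QC table with pass flags in
#'   \code{attr(, "qc")}.
#' @export
filter_cells <- function(dataset, qc = NULL, thresholds = qc_thresholds()) {
  if (is.null(qc)) qc <- compute_qc_metrics(dataset)
  th <- thresholds
  crit <- cbind(
    nCount_RNA = qc$nCount_RNA > th$nCount_RNA_min &
      qc$nCount_RNA < th$nCount_RNA_max,
    nFeature_RNA = qc$nFeature_RNA < th$nFeature_RNA_max,
    percent.mt = qc$percent.mt < th$percent_mt_max,
    nCount_ATAC = qc$nCount_ATAC > th$nCount_ATAC_min &
      qc$nCount_ATAC < th$nCount_ATAC_max,
    nucleosome_signal = qc$nucleosome_signal < th$nucleosome_signal_max,
    TSS.enrichment = qc$TSS.enrichment > th$tss_enrichment_min
  )
  crit[is.na(crit)] <- FALSE
  pass <- rowSums(!crit) == 0L
  removed <- colSums(!crit)
  if (!any(pass)) {
    stop("no cells pass QC; binding criterion: ",
         names(removed)[which.max(removed)])
  }
  qc$pass <- pass
  out <- subset_cells(dataset, qc$barcode[pass])
  attr(out, "qc_removed") <- removed
  attr(out, "qc") <- qc
  out
}

#' Median-scaled log normalization of RNA counts
#'
#' Stores layer \code{lognorm = log1p(count / cell_total * median(cell
#' totals))}. Deterministic; a cell whose total equals the median keeps its
#' counts on the log1p scale, and scaling all counts of a cell leaves its
#' normalized row unchanged.
#'
#' @param dataset a \code{MultiomeDataset}.
#' @return the dataset with a dense \code{layers$lognorm} matrix added.
#' @export
normalize_rna <- function(dataset) {
  tot <- Matrix::rowSums(dataset$rna)
  if (any(tot == 0)) {
    stop("cell(s) with zero RNA counts; run filter_cells first")
  }
  sf <- stats::median(tot) / tot
  norm <- log1p(as.matrix(dataset$rna) * sf)
  dataset$layers$lognorm <- norm
  dataset
}

#' PCA (RNA) and LSI (ATAC) embeddings
#'
#' RNA: top \code{n_hvg} highly variable genes by standardized dispersion
#' (dispersion of the normalized layer, z-scored within 20 mean bins),
#' PCA on the centered HVG matrix. ATAC: binarize, term frequency =
#' count / cell total, IDF = log(1 + n_cells / (1 + peak occurrence)), SVD
#' of log1p(TF x IDF x 1e4); component 1 is dropped from the returned LSI
#' because it tracks sequencing depth. Component signs are fixed by convention (the
#' largest-magnitude loading is positive) so runs are comparable.
#'
#' @param dataset a \code{MultiomeDataset} with the \code{lognorm} layer.
#' @param d_rna,d_atac number of RNA PCs / ATAC LSI components.
#' @param n_hvg number of highly variable genes for PCA.
#' @return an \code{EmbeddingModel}: list with \code{pca} (cells x d_rna),
#'   \code{lsi} (cells x (d_atac - 1), components 2..d_atac), \code{lsi_full}
#'   (including component 1), singular values, HVG names.
#' @export
reduce_dimensions <- function(dataset, d_rna = 30L, d_atac = 30L,
                              n_hvg = 3000L) {
  if (is.null(dataset$layers$lognorm)) {
    stop("run normalize_rna() first")
  }
  x <- dataset$layers$lognorm
  if (ncol(x) < 2L || nrow(x) < 2L) stop("too few features or cells")
  d_rna <- min(d_rna, ncol(x) - 1L, nrow(x) - 1L)
  mu <- colMeans(x)
  v <- colMeans(x^2) - mu^2
  disp <- ifelse(mu > 0, v / mu, 0)
  bins <- cut(mu, breaks = unique(stats::quantile(mu, seq(0, 1, length.out = 21))),
              include.lowest = TRUE)
  zdisp <- unlist(lapply(split(disp, bins), function(d) {
    if (length(d) < 2 || stats::sd(d) == 0) return(d * 0)
    (d - mean(d)) / stats::sd(d)
  }))
  names(zdisp) <- unlist(lapply(split(colnames(x), bins), identity))
  hvg <- names(sort(zdisp, decreasing = TRUE))[seq_len(min(n_hvg, ncol(x)))]
  xc <- scale(x[, hvg, drop = FALSE], center = TRUE, scale = FALSE)
  sv <- svd(xc, nu = d_rna, nv = d_rna)
  pca <- sv$u %*% diag(sv$d[seq_len(d_rna)], d_rna)
  pca <- .fix_signs(pca, sv$v)
  dimnames(pca) <- list(rownames(x), paste0("PC_", seq_len(d_rna)))

  a <- dataset$atac
  if (ncol(a) <= d_atac) stop("fewer peaks than requested LSI components")
  bin <- a
  bin@x <- rep(1, length(bin@x))
  tot <- Matrix::rowSums(bin)
  tot[tot == 0] <- 1
  tf <- bin / tot
  occ <- Matrix::colSums(bin)
  idf <- log(1 + nrow(bin) / (1 + occ))
  xl <- log1p(as.matrix(tf %*% Matrix::Diagonal(x = idf)) * 1e4)
  svl <- svd(xl, nu = d_atac, nv = d_atac)
  lsi_full <- svl$u %*% diag(svl$d[seq_len(d_atac)], d_atac)
  lsi_full <- .fix_signs(lsi_full, svl$v)
  dimnames(lsi_full) <- list(rownames(a), paste0("LSI_", seq_len(d_atac)))

  structure(list(
    pca = pca, lsi = lsi_full[, -1L, drop = FALSE], lsi_full = lsi_full,
    rna_singular_values = sv$d, atac_singular_values = svl$d,
    hvg = hvg
  ), class = "EmbeddingModel")
}

## sign convention: largest-|loading| entry of each component positive
.fix_signs <- function(scores, loadings) {
  for (j in seq_len(ncol(scores))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) scores[, j] <- -scores[, j]
  }
  scores
}

#' Graph clustering of cells
#'
#' Builds a symmetrized k-nearest-neighbour graph (Euclidean) on the given
#' embedding and partitions it with Leiden modularity communities.
#' Deterministic given \code{seed}.
#'
#' @param embedding cells x d numeric matrix (for example
#'   \code{embedding$pca}).
#' @param k neighbours per cell.
#' @param resolution Leiden resolution parameter.
#' @param seed integer seed.
#' @return integer-coded factor of cluster labels, named by cell.
#' @export
cluster_cells <- function(embedding, k = 20L, resolution = 1, seed = 1L) {
  n <- nrow(embedding)
  if (n == 1L) return(stats::setNames(factor(1L), rownames(embedding)))
  if (k >= n) stop("k must be smaller than the number of cells")
  nn <- knn_index(embedding, k)
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nn)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  memb <- with_seed(seed, igraph::cluster_leiden(
    g, objective_function = "modularity",
    resolution = resolution, n_iterations = 5L)$membership)
  stats::setNames(factor(memb), rownames(embedding))
}

## k nearest neighbours (excluding self) by exact Euclidean distance
knn_index <- function(x, k) {
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  t(apply(d, 1L, function(r) order(r)[seq_len(k)]))
}

#' Gene activity scores from ATAC fragments
#'
#' For each cell and gene, sums fragment counts overlapping the gene body
#' extended 2,000 bp upstream of the TSS (strand-aware, 0-based half-open
#' arithmetic). Genes on contigs absent from the dataset are skipped with a
#' warning.
#'
#' @param dataset a \code{MultiomeDataset} with a fragments table.
#' @param upstream promoter extension in bp.
#' @return sparse cells x genes activity matrix.
#' @export
gene_activity <- function(dataset, upstream = 2000L) {
  if (is.null(dataset$fragments)) stop("fragments table required")
  genes <- dataset$genes
  unknown <- !(genes$contig %in% names(dataset$contigs))
  if (any(unknown)) {
    warning("skipping ", sum(unknown), " gene(s) on unknown contigs")
    genes <- genes[!unknown, , drop = FALSE]
  }
  start <- ifelse(genes$strand == "+", pmax(0L, genes$body_start - upstream),
                  genes$body_start)
  end <- ifelse(genes$strand == "+", genes$body_end,
                genes$body_end + upstream)
  win <- intervals_to_granges(genes$contig, start, end)
  fr <- dataset$fragments
  fr_gr <- intervals_to_granges(fr$chrom, fr$start, fr$end)
  hits <- GenomicRanges::findOverlaps(fr_gr, win)
  barcodes <- rownames(dataset$rna)
  cell <- match(fr$barcode[S4Vectors::queryHits(hits)], barcodes)
  keep <- !is.na(cell)
  Matrix::sparseMatrix(
    i = cell[keep], j = S4Vectors::subjectHits(hits)[keep],
    x = fr$count[S4Vectors::queryHits(hits)][keep],
    dims = c(length(barcodes), nrow(genes)),
    dimnames = list(barcodes, genes$gene_id))
}
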