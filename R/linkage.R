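#' Per-peak covariate table for background matching
#'
#' GC fraction (from the genome FASTA), overall accessibility (fraction of
#' cells with count > 0) and peak width, the covariates used to sample
#' matched background peaks for the linkage test and for chromVAR-style
#' deviations.
#'
#' @param dataset a \code{MultiomeDataset} with a genome.
#' @return a \code{PeakFeatureTable} data.frame (peak_id, gc, accessibility,
#'   width).
#' @export
peak_features <- function(dataset) {
  stopifnot(inherits(dataset, "MultiomeDataset"))
  if (is.null(dataset$genome)) stop("genome sequence required for GC content")
  pk <- dataset$peaks
  gc <- peak_gc_content(dataset$genome, pk)
  acc <- Matrix::colMeans(dataset$atac > 0)
  out <- data.frame(peak_id = pk$peak_id, gc = gc,
                    accessibility = as.numeric(acc),
                    width = pk$end - pk$start, stringsAsFactors = FALSE)
  class(out) <- c("PeakFeatureTable", "data.frame")
  out
}

## GC fraction of each peak interval, computed per contig via views
peak_gc_content <- function(genome, peaks) {
  gc <- numeric(nrow(peaks))
  for (cn in unique(peaks$contig)) {
    i <- which(peaks$contig == cn)
    v <- Biostrings::Views(genome[[cn]], start = peaks$start[i] + 1L,
                           end = peaks$end[i])
    f <- Biostrings::alphabetFrequency(v, baseOnly = TRUE)
    gc[i] <- (f[, "C"] + f[, "G"]) / pmax(1L, rowSums(f[, 1:4]))
  }
  gc
}

#' Candidate peak-gene pairs within a TSS window
#'
#' All (gene, peak) pairs on the same contig with |peak midpoint - TSS| <=
#' \code{window}.
#'
#' @param genes gene annotation data.frame (gene_id, contig, tss).
#' @param peaks peak table (peak_id, contig, start, end).
#' @param window linkage window in bp (default 5e5).
#' @return data.frame with gene_id, peak_id, tss_distance (signed,
#'   midpoint - TSS).
#' @export
candidate_pairs <- function(genes, peaks, window = 5e5) {
  mid <- (peaks$start + peaks$end) / 2
  out <- lapply(split(seq_len(nrow(genes)), genes$contig), function(gi) {
    pi <- which(peaks$contig == genes$contig[gi[1]])
    if (!length(pi)) return(NULL)
    d <- outer(mid[pi], genes$tss[gi], "-")
    sel <- which(abs(d) <= window, arr.ind = TRUE)
    if (!nrow(sel)) return(NULL)
    data.frame(gene_id = genes$gene_id[gi[sel[, 2]]],
               peak_id = peaks$peak_id[pi[sel[, 1]]],
               tss_distance = d[sel], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), peak_id = character(0),
                      tss_distance = numeric(0))
  }
  rownames(out) <- NULL
  out[order(match(out$gene_id, genes$gene_id),
            match(out$peak_id, peaks$peak_id)), , drop = FALSE]
}

#' Promoter peaks: peaks overlapping a gene's TSS
#'
#' @param genes gene annotation (gene_id, contig, tss).
#' @param peaks peak table (peak_id, contig, start, end).
#' @return data.frame gene_id, peak_id.
#' @export
promoter_peaks <- function(genes, peaks) {
  tss <- intervals_to_granges(genes$contig, genes$tss, genes$tss + 1L)
  pk <- intervals_to_granges(peaks$contig, peaks$start, peaks$end)
  h <- GenomicRanges::findOverlaps(tss, pk)
  data.frame(gene_id = genes$gene_id[S4Vectors::queryHits(h)],
             peak_id = peaks$peak_id[S4Vectors::subjectHits(h)],
             stringsAsFactors = FALSE)
}

#' Background-matched peak-gene linkage test
#'
#' For each candidate pair, the observed statistic is the Pearson
#' correlation r between the normalized gene expression and the peak's
#' ATAC counts across cells. The null model for each pair is built from
#' the \code{m_background} peaks nearest to the tested peak in standardized
#' (GC, accessibility, width) covariate space (excluding the peak itself;
#' ties broken by peak index): their correlations with the same gene give
#' the null mean and sd, z = (r - mu0) / sd0, and a one-sided upper-tail
#' normal p. BH adjustment is applied over all tested pairs.
#'
#' Pairs whose gene or peak vector is constant across cells are skipped and
#' reported via \code{attr(, "skipped")} rather than propagated as NaN.
#'
#' @param dataset a \code{MultiomeDataset} with the \code{lognorm} layer.
#' @param pairs candidate pairs from \code{\link{candidate_pairs}}.
#' @param features optional \code{PeakFeatureTable}; computed if missing.
#' @param m_background number of matched background peaks per tested peak.
#' @return a \code{PeakGeneLink} data.frame: gene_id, peak_id,
#'   tss_distance, r, null_mean, null_sd, z, p, padj, significant
#'   (r > 0 and padj < 0.05).
#' @export
link_test <- function(dataset, pairs, features = NULL, m_background = 200L) {
  if (is.null(dataset$layers$lognorm)) stop("run normalize_rna() first")
  if (is.null(features)) features <- peak_features(dataset)
  expr <- dataset$layers$lognorm
  atac <- as.matrix(dataset$atac)
  n <- nrow(expr)
  if (n < 3L) stop("need at least 3 cells")

  gene_sd <- apply(expr, 2L, stats::sd)
  peak_sd <- apply(atac, 2L, stats::sd)
  skip <- gene_sd[pairs$gene_id] == 0 | peak_sd[pairs$peak_id] == 0
  skipped <- pairs[skip, , drop = FALSE]
  pairs <- pairs[!skip, , drop = FALSE]

  genes_used <- unique(pairs$gene_id)
  peaks_all <- colnames(atac)
  ok_peak <- peak_sd > 0

  ## full standardized cross-correlation: one matrix product gives both the
  ## observed r's and every background correlation needed (columns are
  ## population-standardized, so the divisor is n)
  gs <- standardize_cols(expr[, genes_used, drop = FALSE])
  ps <- standardize_cols(atac)
  ps[, !ok_peak] <- 0
  R <- crossprod(gs, ps) / n

  ## m nearest background peaks in z-scored covariate space
  fz <- scale(as.matrix(features[, c("gc", "accessibility", "width")]))
  fz[, apply(is.na(fz), 2, any)] <- 0
  m <- min(m_background, sum(ok_peak) - 1L)
  if (m < 2L) stop("too few peaks for background matching")
  tested_peaks <- unique(pairs$peak_id)
  cand <- which(ok_peak)
  fd <- as.matrix(stats::dist(fz))
  bg_idx <- matrix(0L, length(tested_peaks), m,
                   dimnames = list(tested_peaks, NULL))
  for (pid in tested_peaks) {
    i <- match(pid, peaks_all)
    pool <- cand[cand != i]
    ## ties broken by peak index: order() is stable on the index ordering
    bg_idx[pid, ] <- pool[order(fd[i, pool], pool)[seq_len(m)]]
  }

  gi <- match(pairs$gene_id, genes_used)
  pi <- match(pairs$peak_id, peaks_all)
  r <- R[cbind(gi, pi)]
  bg_rows <- bg_idx[match(pairs$peak_id, tested_peaks), , drop = FALSE]
  M <- matrix(R[cbind(rep(gi, ncol(bg_rows)), as.vector(bg_rows))],
              nrow = nrow(pairs))
  null_mean <- rowMeans(M)
  null_sd <- sqrt(pmax(0, (rowSums(M^2) - ncol(M) * null_mean^2) /
                         (ncol(M) - 1)))
  z <- (r - null_mean) / null_sd
  p <- stats::pnorm(z, lower.tail = FALSE)
  padj <- stats::p.adjust(p, method = "BH")
  out <- data.frame(
    gene_id = pairs$gene_id, peak_id = pairs$peak_id,
    tss_distance = pairs$tss_distance, r = r,
    null_mean = null_mean, null_sd = null_sd, z = z, p = p, padj = padj,
    significant = r > 0 & padj < 0.05, stringsAsFactors = FALSE)
  class(out) <- c("PeakGeneLink", "data.frame")
  attr(out, "skipped") <- skipped
  out
}

#' Retain significant links and summarize links per gene
#'
#' Keeps pairs with r > 0 and BH-adjusted p < 0.05 and reports, per linked
#' gene, the number of links and the min/median/mean/max statistics of the
#' link count distribution across genes.
#'
#' @param links a \code{PeakGeneLink} table from \code{\link{link_test}}.
#' @return list with \code{links} (significant rows) and \code{per_gene}
#'   summary (data.frame gene_id, n_links) plus \code{summary}
#'   (n_links, n_genes, min, median, mean, max links per gene).
#' @export
filter_links <- function(links) {
  sig <- links[links$r > 0 & links$padj < 0.05, , drop = FALSE]
  if (!nrow(sig)) {
    return(list(links = sig,
                per_gene = data.frame(gene_id = character(0),
                                      n_links = integer(0)),
                summary = c(n_links = 0, n_genes = 0, min = NA, median = NA,
                            mean = NA, max = NA)))
  }
  tab <- table(sig$gene_id)
  per_gene <- data.frame(gene_id = names(tab), n_links = as.integer(tab),
                         stringsAsFactors = FALSE)
  counts <- per_gene$n_links
  list(links = sig, per_gene = per_gene,
       summary = c(n_links = nrow(sig), n_genes = nrow(per_gene),
                   min = min(counts), median = stats::median(counts),
                   mean = mean(counts), max = max(counts)))
}
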