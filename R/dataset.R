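#' Construct a paired multiome dataset
#'
#' The container consumed by every pipeline stage: paired cell x gene RNA
#' counts and cell x peak ATAC counts for the same cells, an ATAC fragments
#' table, genome annotation (genes, peaks, contigs, genome sequence) and
#' per-cell metadata. Peak intervals are 0-based half-open, as in BED;
#' peak ids are rendered \code{"contig:start-end"} in that convention.
#'
#' @param rna sparse cells x genes count matrix (non-negative integers).
#' @param atac sparse cells x peaks count matrix, same cell order as `rna`.
#' @param fragments data.frame with columns chrom, start, end, barcode, count
#'   (0-based half-open), or NULL if unavailable.
#' @param genes data.frame with columns gene_id, contig, strand, tss,
#'   body_start, body_end.
#' @param peaks data.frame with columns peak_id, contig, start, end.
#' @param contigs named integer vector of contig lengths.
#' @param genome optional \code{Biostrings::DNAStringSet} named by contig.
#' @param cells per-cell metadata data.frame with at least barcode and stage.
#'
#' @return An object of class \code{MultiomeDataset}: a list with the above
#'   fields plus an initially empty \code{layers} list for normalized data.
#' @export
multiome_dataset <- function(rna, atac, fragments = NULL, genes, peaks,
                             contigs, genome = NULL, cells) {
  rna <- methods::as(methods::as(rna, "CsparseMatrix"), "generalMatrix")
  atac <- methods::as(methods::as(atac, "CsparseMatrix"), "generalMatrix")
  if (nrow(rna) != nrow(atac)) {
    stop("RNA and ATAC matrices must have the same number of cells")
  }
  if (!identical(rownames(rna), rownames(atac))) {
    stop("RNA and ATAC matrices must share an identical cell ordering")
  }
  if (any(rna@x < 0) || any(atac@x < 0)) stop("counts must be non-negative")
  if (!all(peaks$contig %in% names(contigs))) {
    stop("peaks on unknown contigs")
  }
  lens <- contigs[peaks$contig]
  if (any(peaks$start < 0) || any(peaks$end > lens) ||
      any(peaks$start >= peaks$end)) {
    stop("peak intervals must lie within contig bounds (0-based half-open)")
  }
  if (!identical(cells$barcode, rownames(rna))) {
    stop("cell metadata must match matrix rownames")
  }
  structure(
    list(
      rna = rna, atac = atac, fragments = fragments,
      genes = genes, peaks = peaks, contigs = contigs, genome = genome,
      cells = cells, layers = list()
    ),
    class = "MultiomeDataset"
  )
}

#' @export
print.MultiomeDataset <- function(x, ...) {
  cat("MultiomeDataset:", nrow(x$rna), "cells x", ncol(x$rna), "genes (RNA),",
      ncol(x$atac), "peaks (ATAC)\n")
  cat("  fragments:", if (is.null(x$fragments)) "absent" else
    paste(nrow(x$fragments), "rows"), "\n")
  cat("  contigs:", length(x$contigs),
      " layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.MultiomeDataset <- function(x) c(nrow(x$rna), ncol(x$rna), ncol(x$atac))

n_cells <- function(dataset) nrow(dataset$rna)

#' Subset a multiome dataset to a set of cells
#'
#' Keeps both modalities, the fragments table and the per-cell metadata in
#' step. Used by QC filtering and by trajectory stages that drop cells.
#'
#' @param dataset a \code{MultiomeDataset}.
#' @param barcodes character vector of barcodes to keep (order preserved).
#' @return the restricted \code{MultiomeDataset}.
#' @export
subset_cells <- function(dataset, barcodes) {
  idx <- match(barcodes, rownames(dataset$rna))
  if (anyNA(idx)) stop("unknown barcodes in subset")
  out <- dataset
  out$rna <- dataset$rna[idx, , drop = FALSE]
  out$atac <- dataset$atac[idx, , drop = FALSE]
  out$cells <- dataset$cells[idx, , drop = FALSE]
  rownames(out$cells) <- NULL
  if (!is.null(dataset$fragments)) {
    out$fragments <-
      dataset$fragments[dataset$fragments$barcode %in% barcodes, , drop = FALSE]
  }
  out$layers <- lapply(dataset$layers, function(l) l[idx, , drop = FALSE])
  out
}
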