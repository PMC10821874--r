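# On-disk layout: MatrixMarket + barcodes/features TSV per modality,
# BED peaks, FASTA genome, 10x-style headerless fragments TSV, plain TSV
# annotation, and a truth.json for the planted ground truth.

#' Write a multiome dataset (and optional ground truth) to a directory
#'
#' @param dataset a \code{MultiomeDataset}.
#' @param dir output directory; created if absent. Refuses to overwrite an
#'   existing non-empty directory unless \code{force = TRUE}.
#' @param truth optional \code{GroundTruth} to serialize as truth.json.
#' @param force overwrite an existing non-empty directory.
#' @return the directory path, invisibly.
#' @export
write_dataset <- function(dataset, dir, truth = NULL, force = FALSE) {
  stopifnot(inherits(dataset, "MultiomeDataset"))
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force) {
    stop("directory ", dir, " is not empty; use force = TRUE to overwrite")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(...) file.path(dir, ...)

  Matrix::writeMM(Matrix::t(dataset$rna), f("rna.mtx"))
  Matrix::writeMM(Matrix::t(dataset$atac), f("atac.mtx"))
  writeLines(rownames(dataset$rna), f("barcodes.tsv"))
  writeLines(colnames(dataset$rna), f("rna_features.tsv"))
  writeLines(colnames(dataset$atac), f("atac_features.tsv"))

  pk <- dataset$peaks
  utils::write.table(
    data.frame(pk$contig, pk$start, pk$end, pk$peak_id),
    f("peaks.bed"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(dataset$genes, f("genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$cells, f("cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(contig = names(dataset$contigs),
               length = as.integer(dataset$contigs)),
    f("contigs.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(dataset$fragments)) {
    fr <- dataset$fragments[order(dataset$fragments$chrom,
                                  dataset$fragments$start), , drop = FALSE]
    utils::write.table(fr, f("fragments.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(dataset$genome)) {
    Biostrings::writeXStringSet(dataset$genome, f("genome.fa"))
  }
  if (!is.null(truth)) write_ground_truth(truth, f("truth.json"))
  invisible(dir)
}

#' Read a dataset directory written by \code{\link{write_dataset}}
#'
#' @param dir directory path.
#' @return list with \code{dataset} (a \code{MultiomeDataset}) and
#'   \code{truth} (a \code{GroundTruth} or NULL if absent).
#' @export
read_dataset <- function(dir) {
  f <- function(...) file.path(dir, ...)
  barcodes <- readLines(f("barcodes.tsv"))
  rna <- Matrix::t(Matrix::readMM(f("rna.mtx")))
  atac <- Matrix::t(Matrix::readMM(f("atac.mtx")))
  dimnames(rna) <- list(barcodes, readLines(f("rna_features.tsv")))
  dimnames(atac) <- list(barcodes, readLines(f("atac_features.tsv")))
  genes <- utils::read.table(f("genes.tsv"), sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  cells <- utils::read.table(f("cells.tsv"), sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  ctg <- utils::read.table(f("contigs.tsv"), sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  contigs <- stats::setNames(as.integer(ctg$length), ctg$contig)
  bed <- utils::read.table(f("peaks.bed"), sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("contig", "start", "end", "peak_id"))
  peaks <- bed[, c("peak_id", "contig", "start", "end")]
  fragments <- NULL
  if (file.exists(f("fragments.tsv"))) {
    fragments <- utils::read.table(
      f("fragments.tsv"), sep = "\t", stringsAsFactors = FALSE,
      col.names = c("chrom", "start", "end", "barcode", "count"))
  }
  genome <- NULL
  if (file.exists(f("genome.fa"))) {
    genome <- Biostrings::readDNAStringSet(f("genome.fa"))
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  dataset <- multiome_dataset(
    rna = rna, atac = atac, fragments = fragments, genes = genes,
    peaks = peaks, contigs = contigs, genome = genome, cells = cells)
  truth <- if (file.exists(f("truth.json"))) {
    read_ground_truth(f("truth.json"))
  }
  list(dataset = dataset, truth = truth)
}

## ---- ground-truth JSON (lossless modulo the FASTA, written separately) --

#' @rdname write_dataset
#' @param path file path for the truth JSON.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "GroundTruth"))
  p <- truth$program
  cfg <- p$config
  cfg$stage_windows <- as.data.frame(cfg$stage_windows)
  payload <- list(
    config = unclass(cfg),
    genes = p$genes, peaks = p$peaks, links = p$links,
    motif_map = p$motif_map,
    motifs = lapply(p$motifs, function(m) as.data.frame(t(m))),
    prolif_genes = p$prolif_genes,
    branch_point = p$branch_point, branch_weights = p$branch_weights,
    branch_growth = p$branch_growth,
    contigs = as.list(p$contigs),
    states = as.data.frame(truth$states), edges = truth$edges,
    terminal_branch = as.list(truth$terminal_branch),
    junk_barcodes = truth$junk_barcodes
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns", na = "null", null = "null")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  df <- function(l) as.data.frame(l, stringsAsFactors = FALSE)
  for (nm in c("genes", "peaks", "links", "motif_map", "states", "edges")) {
    x[[nm]] <- df(x[[nm]])
  }
  cfg <- x$config
  cfg$stage_windows <- as.matrix(cfg$stage_windows)
  dimnames(cfg$stage_windows) <- NULL
  cfg$phase_centers <- unlist(cfg$phase_centers)
  cfg$cells_per_stage <- as.integer(cfg$cells_per_stage)
  class(cfg) <- "sim_config"
  motifs <- lapply(x$motifs, function(d) {
    m <- t(as.matrix(df(d)))
    storage.mode(m) <- "integer"
    rownames(m) <- c("A", "C", "G", "T")
    colnames(m) <- NULL
    m
  })
  program <- structure(list(
    config = cfg, genes = x$genes, peaks = x$peaks, links = x$links,
    motifs = motifs, motif_map = x$motif_map,
    prolif_genes = x$prolif_genes, branch_point = x$branch_point,
    branch_weights = x$branch_weights, branch_growth = x$branch_growth,
    contigs = unlist(x$contigs), genome = NULL
  ), class = "RegulatoryProgram")
  states <- x$states
  class(states) <- c("CellStateTable", "data.frame")
  structure(list(
    program = program, states = states, links = x$links, edges = x$edges,
    terminal_branch = unlist(x$terminal_branch),
    junk_barcodes = as.character(x$junk_barcodes)
  ), class = "GroundTruth")
}
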