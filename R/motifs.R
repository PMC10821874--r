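# PWM models: JASPAR PFM text IO, log-odds scoring, scan-threshold
# calibration by the exact score distribution under the background model,
# and scanning of peak sequences on both strands.

#' Read motif models from a JASPAR PFM text file
#'
#' Expects the JASPAR text format: a header line \code{">ID NAME"} followed
#' by four count rows (A, C, G, T), with or without the
#' \code{"A [ 1 2 3 ]"} decoration. Probabilities use
#' \code{(count + 0.25 * pseudocount) / (colsum + pseudocount)}; log-odds
#' are taken against a uniform background by default.
#'
#' @param path PFM text file.
#' @param pseudocount total pseudocount per column (default 1).
#' @param background base frequencies (A, C, G, T); default uniform.
#' @return a \code{MotifModelList}: per motif, a list with id, tf (the
#'   JASPAR name field), counts, prob, logodds matrices.
#' @export
read_jaspar <- function(path, pseudocount = 1, background = rep(0.25, 4)) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no motif headers found in ", path)
  out <- lapply(seq_along(starts), function(i) {
    from <- starts[i]
    to <- if (i < length(starts)) starts[i + 1] - 1L else length(lines)
    block <- lines[from:to]
    if (length(block) != 5L) {
      stop("motif block for ", block[1], " must have exactly 4 count rows")
    }
    hdr <- strsplit(sub("^>", "", block[1]), "\\s+")[[1]]
    rows <- lapply(block[2:5], function(l) {
      l <- sub("^[ACGTacgt]", "", l)
      l <- gsub("[][]", " ", l)
      v <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
      if (anyNA(v)) stop("non-numeric counts in motif ", hdr[1])
      v
    })
    if (length(unique(lengths(rows))) != 1L) {
      stop("ragged count rows in motif ", hdr[1])
    }
    counts <- do.call(rbind, rows)
    rownames(counts) <- c("A", "C", "G", "T")
    motif_model(id = hdr[1], tf = if (length(hdr) > 1) hdr[2] else NA_character_,
                counts = counts, pseudocount = pseudocount,
                background = background)
  })
  names(out) <- vapply(out, `[[`, "", "id")
  class(out) <- "MotifModelList"
  out
}

#' @rdname read_jaspar
#' @param id,tf,counts motif id, TF name and 4 x L count matrix.
#' @export
motif_model <- function(id, tf, counts, pseudocount = 1,
                        background = rep(0.25, 4)) {
  stopifnot(nrow(counts) == 4L, all(counts >= 0))
  cs <- colSums(counts)
  prob <- sweep(counts + pseudocount * 0.25, 2L, cs + pseudocount, "/")
  lo <- log(prob / background)
  if (any(!is.finite(lo))) stop("non-finite log-odds in motif ", id)
  structure(list(id = id, tf = tf, counts = counts, prob = prob,
                 logodds = lo, pseudocount = pseudocount,
                 background = background),
            class = "MotifModel")
}

#' @rdname read_jaspar
#' @param motifs a \code{MotifModelList} (or list of count matrices).
#' @export
write_jaspar <- function(motifs, path) {
  lines <- unlist(lapply(motifs, function(m) {
    counts <- if (inherits(m, "MotifModel")) m$counts else m
    id <- if (inherits(m, "MotifModel")) m$id else ""
    tf <- if (inherits(m, "MotifModel")) m$tf else ""
    c(paste0(">", id, " ", tf),
      vapply(1:4, function(r) {
        paste0(c("A", "C", "G", "T")[r], " [ ",
               paste(counts[r, ], collapse = " "), " ]")
      }, ""))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Score threshold for a scan p-value
#'
#' Exact distribution of the window log-odds score under the iid
#' background model, by dynamic programming over discretized scores
#' (granularity \code{1/scale}); returns the smallest threshold t with
#' P(score >= t) <= p.
#'
#' @param motif a \code{MotifModel}.
#' @param p scan p-value (default 1e-4).
#' @param scale score discretization (integer steps per unit log-odds).
#' @return the threshold on the log-odds score scale.
#' @export
motif_score_threshold <- function(motif, p = 1e-4, scale = 1000L) {
  lo <- round(motif$logodds * scale)
  bg <- motif$background
  offset <- apply(lo, 2L, min)
  dist <- 1
  for (j in seq_len(ncol(lo))) {
    step <- lo[, j] - offset[j]
    width <- max(step)
    nd <- numeric(length(dist) + width)
    for (b in 1:4) {
      idx <- seq_along(dist) + step[b]
      nd[idx] <- nd[idx] + dist * bg[b]
    }
    dist <- nd
  }
  ## dist[k] = P(sum of shifted scores == k - 1)
  tail <- rev(cumsum(rev(dist)))
  k <- which(tail <= p)[1]
  if (is.na(k)) k <- length(dist) + 1L
  ((k - 1L) + sum(offset)) / scale
}

reverse_complement_motif <- function(motif) {
  m <- motif
  rc <- function(x) {
    x <- x[c("T", "G", "C", "A"), rev(seq_len(ncol(x))), drop = FALSE]
    rownames(x) <- c("A", "C", "G", "T")
    x
  }
  m$counts <- rc(motif$counts)
  m$prob <- rc(motif$prob)
  m$logodds <- rc(motif$logodds)
  m
}

#' Scan peak sequences for motif hits
#'
#' Scores every window of every peak sequence on both strands with the
#' motif log-odds matrix and calls a hit when the maximal window score
#' reaches the threshold corresponding to scan p-value \code{p_threshold}
#' under the background model (\code{\link{motif_score_threshold}}).
#' Windows containing non-ACGT letters never hit.
#'
#' @param genome a \code{DNAStringSet} covering all peaks.
#' @param peaks peak table (peak_id, contig, start, end), 0-based half-open.
#' @param motifs a \code{MotifModelList}.
#' @param p_threshold scan p-value (default 1e-4).
#' @return a \code{MotifHitMatrix}: sparse binary peaks x motifs matrix with
#'   the thresholds used stored in \code{attr(, "thresholds")}.
#' @export
scan_motifs <- function(genome, peaks, motifs, p_threshold = 1e-4) {
  if (!all(peaks$contig %in% names(genome))) stop("peak outside contig")
  if (any(peaks$end > vapply(as.list(genome[peaks$contig]), length, 1L))) {
    stop("peak outside contig")
  }
  maxL <- max(vapply(motifs, function(m) ncol(m$logodds), 1L))
  ## concatenate peak sequences with N spacers so no window spans two peaks
  spacer <- strrep("N", maxL)
  seqs <- vapply(seq_len(nrow(peaks)), function(i) {
    as.character(Biostrings::subseq(genome[[peaks$contig[i]]],
                                    peaks$start[i] + 1L, peaks$end[i]))
  }, "")
  big <- paste(seqs, collapse = spacer)
  code <- match(strsplit(big, "")[[1]], c("A", "C", "G", "T"))
  widths <- nchar(seqs)
  peak_of <- rep.int(seq_len(nrow(peaks)), widths + maxL)
  peak_of <- peak_of[seq_along(code)]

  thresholds <- numeric(length(motifs))
  hit_i <- integer(0)
  hit_j <- integer(0)
  for (mi in seq_along(motifs)) {
    m <- motifs[[mi]]
    thr <- motif_score_threshold(m, p = p_threshold)
    thresholds[mi] <- thr
    hits <- integer(0)
    for (mm in list(m, reverse_complement_motif(m))) {
      lo <- mm$logodds
      L <- ncol(lo)
      npos <- length(code) - L + 1L
      sc <- numeric(npos)
      ok <- !logical(npos)
      for (off in seq_len(L)) {
        b <- code[off:(off + npos - 1L)]
        miss <- is.na(b)
        ok <- ok & !miss
        b[miss] <- 1L
        sc <- sc + lo[cbind(b, off)]
      }
      ## threshold minus a discretization epsilon
      hp <- which(ok & sc >= thr - 1e-9)
      hits <- c(hits, peak_of[hp])
    }
    hits <- unique(hits)
    hit_i <- c(hit_i, hits)
    hit_j <- c(hit_j, rep.int(mi, length(hits)))
  }
  out <- Matrix::sparseMatrix(
    i = hit_i, j = hit_j, x = 1,
    dims = c(nrow(peaks), length(motifs)),
    dimnames = list(peaks$peak_id, names(motifs)))
  attr(out, "thresholds") <- stats::setNames(thresholds, names(motifs))
  attr(out, "p_threshold") <- p_threshold
  out
}

#' chromVAR-style per-cell motif deviations
#'
#' Raw deviation of cell c and motif m is (observed - expected) / expected,
#' where observed is the cell's total counts in the motif's hit peaks and
#' expected distributes the cell's total counts over peaks proportional to
#' their dataset-wide totals. Deviations are z-scored against
#' \code{n_background} permuted peak sets matched on GC and overall
#' accessibility (binned into \code{n_bins} x \code{n_bins} cells).
#'
#' @param dataset a \code{MultiomeDataset}.
#' @param hits \code{MotifHitMatrix} from \code{\link{scan_motifs}}.
#' @param features \code{PeakFeatureTable}; computed if missing.
#' @param n_background matched background peak sets.
#' @param n_bins bins per covariate for matching.
#' @param seed integer seed.
#' @return dense cells x motifs deviation z-score matrix; motifs with zero
#'   hit peaks are dropped with a warning.
#' @export
motif_deviations <- function(dataset, hits, features = NULL,
                             n_background = 50L, n_bins = 10L, seed = 1L) {
  X <- dataset$atac
  keep <- Matrix::colSums(hits) > 0
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " motif(s) with zero hit peaks")
    hits <- hits[, keep, drop = FALSE]
  }
  if (!ncol(hits)) stop("no motifs with hit peaks")
  if (is.null(features)) features <- peak_features(dataset)
  cell_tot <- Matrix::rowSums(X)
  peak_tot <- Matrix::colSums(X)
  w <- peak_tot / sum(peak_tot)

  dev_of <- function(H) {
    obs <- as.matrix(X %*% H)
    expd <- cell_tot %o% as.numeric(Matrix::t(H) %*% w)
    (obs - expd) / pmax(expd, .Machine$double.eps)
  }
  dev0 <- dev_of(hits)

  ## background: permute each hit peak within its (GC, accessibility) bin
  qbin <- function(x, n) {
    br <- unique(stats::quantile(x, seq(0, 1, length.out = n + 1)))
    as.integer(cut(x, br, include.lowest = TRUE))
  }
  bin <- paste(qbin(features$gc, n_bins), qbin(features$accessibility, n_bins))
  bin_members <- split(seq_len(nrow(features)), bin)
  bin_of <- match(bin, names(bin_members))

  with_seed(seed, {
    bg_sum <- matrix(0, nrow(dev0), ncol(dev0))
    bg_sumsq <- matrix(0, nrow(dev0), ncol(dev0))
    ht <- methods::as(hits, "TsparseMatrix")
    npk <- nrow(features)
    for (b in seq_len(n_background)) {
      ## one matched replacement per peak, shared by all motifs, so
      ## identical hit columns get identical backgrounds
      bg_map <- vapply(seq_len(npk), function(p) {
        mem <- bin_members[[bin_of[p]]]
        mem[sample.int(length(mem), 1L)]
      }, 1L)
      Hb <- Matrix::sparseMatrix(i = bg_map[ht@i + 1L], j = ht@j + 1L,
                                 x = 1, dims = dim(hits))
      db <- dev_of(Hb)
      bg_sum <- bg_sum + db
      bg_sumsq <- bg_sumsq + db^2
    }
    mu <- bg_sum / n_background
    sd <- sqrt(pmax(0, bg_sumsq / n_background - mu^2) *
                 n_background / (n_background - 1))
    z <- (dev0 - mu) / pmax(sd, .Machine$double.eps)
    dimnames(z) <- list(rownames(X), colnames(hits))
    z
  })
}
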