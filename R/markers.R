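# Marker statistics: vectorized one-vs-rest Wilcoxon rank-sum tests,
# dual-modality marker TF calling, motif enrichment and generic ORA.

#' Two-sample Wilcoxon rank-sum test
#'
#' Exact tail probability (via the null rank-sum distribution) when both
#' samples are small and tie-free; otherwise the normal approximation with
#' tie correction and continuity correction.
#'
#' @param x,y numeric samples.
#' @param alternative "two.sided", "greater" (x tends larger) or "less".
#' @param exact_max use the exact distribution when both sizes are <= this
#'   and there are no ties.
#' @return list with statistic (Mann-Whitney U for x), p.value, exact flag.
#' @export
wilcox_rank_sum_test <- function(x, y, alternative = "two.sided",
                                 exact_max = 50L) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  ties <- anyDuplicated(c(x, y)) > 0L
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (!ties && n1 <= exact_max && n2 <= exact_max) {
    p <- switch(alternative,
      two.sided = {
        p1 <- stats::pwilcox(U, n1, n2)
        p2 <- stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
        min(1, 2 * min(p1, p2))
      },
      greater = stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE),
      less = stats::pwilcox(U, n1, n2))
    return(list(statistic = U, p.value = p, exact = TRUE))
  }
  mu <- n1 * n2 / 2
  tie_term <- {
    tt <- table(c(x, y))
    sum(tt^3 - tt)
  }
  n <- n1 + n2
  sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1))))
  z <- U - mu
  corr <- switch(alternative, two.sided = sign(z) * 0.5, greater = 0.5,
                 less = -0.5)
  z <- (z - corr) / sigma
  p <- switch(alternative,
    two.sided = 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)),
    greater = stats::pnorm(z, lower.tail = FALSE),
    less = stats::pnorm(z))
  list(statistic = U, p.value = min(1, p), exact = FALSE)
}

#' One-vs-rest Wilcoxon marker tests per group
#'
#' For every feature and group, tests the group's cells against all other
#' cells (normal approximation with tie and continuity correction,
#' vectorized over features) and reports an effect size: the natural-log
#' fold change of pseudocounted mean normalized expression
#' (\code{fc = "logratio"}, for expression layers) or the difference of
#' means (\code{fc = "diff"}, for deviation scores). BH adjustment is
#' applied across features within each group; the marker flag is
#' padj < 0.05 and effect > \code{logfc_min}.
#'
#' @param mat cells x features matrix (dense or sparse).
#' @param groups factor of group labels, one per cell (>= 2 groups, no
#'   empty groups).
#' @param logfc_min effect threshold for the marker flag (default 0.1).
#' @param fc effect type; "logratio" treats the layer as log1p-normalized
#'   expression and compares mean de-logged values with pseudocount 1.
#' @return a \code{MarkerTable} data.frame: feature, group, effect, p,
#'   padj, pct_in, pct_out, marker.
#' @export
rank_sum_markers <- function(mat, groups, logfc_min = 0.1,
                             fc = c("logratio", "diff")) {
  fc <- match.arg(fc)
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) == 0L)) stop("empty group")
  x <- as_dense(mat)
  n <- nrow(x)
  if (length(groups) != n) stop("groups must match rows of mat")

  R <- apply(x, 2L, rank)
  tie_term <- apply(x, 2L, function(col) {
    tt <- rle(sort(col))$lengths
    sum(tt^3 - tt)
  })
  vals <- if (fc == "logratio") expm1(x) else x
  res <- lapply(levels(groups), function(g) {
    in_g <- groups == g
    n1 <- sum(in_g); n2 <- n - n1
    U <- colSums(R[in_g, , drop = FALSE]) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1))))
    zc <- U - mu
    z <- (zc - sign(zc) * 0.5) / pmax(sigma, .Machine$double.eps)
    p <- 2 * stats::pnorm(-abs(z))
    p <- pmin(1, p)
    m_in <- colMeans(vals[in_g, , drop = FALSE])
    m_out <- colMeans(vals[!in_g, , drop = FALSE])
    effect <- if (fc == "logratio") log((m_in + 1) / (m_out + 1)) else
      m_in - m_out
    padj <- stats::p.adjust(p, method = "BH")
    data.frame(feature = colnames(x), group = g, effect = effect, p = p,
               padj = padj,
               pct_in = colMeans(x[in_g, , drop = FALSE] > 0),
               pct_out = colMeans(x[!in_g, , drop = FALSE] > 0),
               marker = padj < 0.05 & effect > logfc_min,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, res)
  class(out) <- c("MarkerTable", "data.frame")
  out
}

#' Motif enrichment in a foreground peak set
#'
#' Compares the motif hit rate in the foreground against a background peak
#' set: either supplied explicitly or sampled GC-matched from the peak
#' universe (per foreground peak, \code{bg_per_peak} draws from the same GC
#' decile). One-sided hypergeometric p on the hit counts, BH across motifs.
#'
#' @param foreground peak ids (subset of the hit matrix rows).
#' @param hits \code{MotifHitMatrix}.
#' @param background optional explicit background peak ids.
#' @param features \code{PeakFeatureTable} (needed for GC matching when
#'   background is NULL).
#' @param bg_per_peak GC-matched draws per foreground peak.
#' @param seed integer seed for background sampling.
#' @return data.frame: motif, n_fg, hit_fg, n_bg, hit_bg, fold_change, p,
#'   padj.
#' @export
motif_enrichment <- function(foreground, hits, background = NULL,
                             features = NULL, bg_per_peak = 40L, seed = 1L) {
  if (!length(foreground)) stop("empty foreground")
  univ <- rownames(hits)
  stopifnot(all(foreground %in% univ))
  if (is.null(background)) {
    if (is.null(features)) stop("features required for GC-matched background")
    gc <- stats::setNames(features$gc, features$peak_id)[univ]
    br <- unique(stats::quantile(gc, seq(0, 1, 0.1)))
    bin <- cut(gc, br, include.lowest = TRUE)
    members <- split(univ, bin)
    background <- with_seed(seed, unlist(lapply(foreground, function(p) {
      mem <- setdiff(members[[bin[match(p, univ)]]], p)
      if (!length(mem)) return(character(0))
      mem[sample.int(length(mem), min(bg_per_peak, length(mem)),
                     replace = length(mem) < bg_per_peak)]
    }), use.names = FALSE))
  }
  Hf <- hits[foreground, , drop = FALSE]
  Hb <- hits[background, , drop = FALSE]
  k_fg <- Matrix::colSums(Hf > 0)
  k_bg <- Matrix::colSums(Hb > 0)
  n_fg <- length(foreground); n_bg <- length(background)
  fold <- (k_fg / n_fg) / (k_bg / n_bg)
  K <- k_fg + k_bg
  N <- n_fg + n_bg
  p <- stats::phyper(k_fg - 1, K, N - K, n_fg, lower.tail = FALSE)
  out <- data.frame(motif = colnames(hits), n_fg = n_fg, hit_fg = k_fg,
                    n_bg = n_bg, hit_bg = k_bg, fold_change = fold, p = p,
                    padj = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p), , drop = FALSE]
}

#' Dual-modality marker transcription factors
#'
#' A TF is reported as a marker of a group iff (1) its gene is enriched at
#' the RNA level (padj < 0.05, effect > 0) and (2) its binding-motif
#' accessibility is enriched in the deviation scores (padj < 0.05,
#' effect > 0) for the same group. TFs without a mapped motif are excluded
#' and listed in \code{attr(, "unmapped")}.
#'
#' @param rna_markers \code{MarkerTable} on expression (features are genes).
#' @param dev_markers \code{MarkerTable} on motif deviations (features are
#'   motif ids).
#' @param motif_map data.frame with columns motif_id and tf.
#' @return data.frame: group, tf, rna_p, rna_padj, motif_id, motif_p,
#'   motif_padj.
#' @export
call_multiomic_markers <- function(rna_markers, dev_markers, motif_map) {
  tfs <- unique(rna_markers$feature)
  mapped <- motif_map[motif_map$tf %in% tfs, , drop = FALSE]
  unmapped <- setdiff(tfs, mapped$tf)
  rna_up <- rna_markers[rna_markers$padj < 0.05 & rna_markers$effect > 0, ]
  dev_up <- dev_markers[dev_markers$padj < 0.05 & dev_markers$effect > 0, ]
  rows <- merge(
    merge(mapped, rna_up, by.x = "tf", by.y = "feature"),
    dev_up, by.x = c("motif_id", "group"), by.y = c("feature", "group"),
    suffixes = c("_rna", "_dev"))
  out <- data.frame(group = rows$group, tf = rows$tf,
                    rna_p = rows$p_rna, rna_padj = rows$padj_rna,
                    motif_id = rows$motif_id, motif_p = rows$p_dev,
                    motif_padj = rows$padj_dev, stringsAsFactors = FALSE)
  out <- out[order(out$group, out$rna_p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmapped") <- unmapped
  out
}

#' Over-representation analysis against a gene-set collection
#'
#' Hypergeometric ORA. Sets are restricted to the universe; sets with
#' fewer than \code{min_size} or more than \code{max_size} genes (after
#' restriction) are excluded before testing. Enrichment ratio is
#' (k / n_query) / (K / N_universe).
#'
#' @param query query genes (must be a subset of the universe).
#' @param collection named list of gene sets.
#' @param universe universe genes.
#' @param min_size,max_size set size bounds (defaults 5 and 500).
#' @return data.frame: set, size, overlap, enrichment_ratio, p, padj.
#' @export
ora_enrichment <- function(query, collection, universe, min_size = 5L,
                           max_size = 500L) {
  if (!length(universe)) stop("empty universe")
  if (!all(query %in% universe)) stop("query must be a subset of the universe")
  query <- unique(query)
  sets <- lapply(collection, function(s) intersect(unique(s), universe))
  size <- lengths(sets)
  keep <- size >= min_size & size <= max_size
  sets <- sets[keep]
  N <- length(unique(universe))
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    K <- length(sets[[nm]])
    k <- length(intersect(query, sets[[nm]]))
    data.frame(set = nm, size = K, overlap = k,
               enrichment_ratio = (k / n) / (K / N),
               p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(set = character(0), size = integer(0),
                      overlap = integer(0), enrichment_ratio = numeric(0),
                      p = numeric(0), padj = numeric(0)))
  }
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}
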