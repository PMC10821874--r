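# Validation statistics: ChIP TSS-proximity rates with replicate
# comparison, interval-overlap and gene-set Fisher tests, and cell-type
# composition summaries.

#' TSS-proximity rate of ChIP peaks, with replicate comparison
#'
#' Per replicate, the rate of peaks whose midpoint falls within
#' \code{window} bp of any TSS of the gene set (peak-centric counting;
#' \code{position = "edge"} instead counts a peak when any part of it is
#' within the window). When two TFs' replicate lists are supplied, a
#' one-sided two-sample t test on the replicate rates is reported together
#' with a pooled-count Fisher test (the t test is underpowered at n = 2
#' replicates, so the Fisher companion is always shown).
#'
#' @param chip named list: TF -> list of replicate interval data.frames
#'   (contig, start, end; 0-based half-open).
#' @param gene_set gene ids whose TSS define proximity.
#' @param annotation gene annotation (gene_id, contig, tss).
#' @param window proximity window in bp (default 5000).
#' @param position "midpoint" (default) or "edge".
#' @param alternative alternative for the t test comparing the first TF
#'   against the second ("greater" by default).
#' @return list with \code{rates} (data.frame tf, replicate, n_peaks,
#'   n_near, rate) and, when two TFs are given, \code{t_test} and
#'   \code{fisher} comparisons.
#' @export
tss_proximity_rate <- function(chip, gene_set, annotation, window = 5000L,
                               position = c("midpoint", "edge"),
                               alternative = "greater") {
  position <- match.arg(position)
  ann <- annotation[annotation$gene_id %in% gene_set, , drop = FALSE]
  if (!nrow(ann)) stop("empty gene set")
  ## +/- window inclusive on both sides (0-based half-open arithmetic)
  win <- intervals_to_granges(ann$contig, pmax(0L, ann$tss - window),
                              ann$tss + window + 1L)
  rates <- do.call(rbind, lapply(names(chip), function(tf) {
    reps <- chip[[tf]]
    do.call(rbind, lapply(seq_along(reps), function(r) {
      pk <- reps[[r]]
      if (!nrow(pk)) stop("replicate ", r, " of ", tf, " has zero peaks")
      gr <- if (position == "midpoint") {
        mid <- (pk$start + pk$end) %/% 2L
        intervals_to_granges(pk$contig, mid, mid + 1L)
      } else {
        intervals_to_granges(pk$contig, pk$start, pk$end)
      }
      near <- IRanges::overlapsAny(gr, win)
      data.frame(tf = tf, replicate = r, n_peaks = nrow(pk),
                 n_near = sum(near), rate = mean(near),
                 stringsAsFactors = FALSE)
    }))
  }))
  out <- list(rates = rates)
  if (length(chip) == 2L) {
    a <- rates[rates$tf == names(chip)[1], ]
    b <- rates[rates$tf == names(chip)[2], ]
    if (nrow(a) >= 2L && nrow(b) >= 2L) {
      out$t_test <- tryCatch(
        stats::t.test(a$rate, b$rate, alternative = alternative),
        error = function(e) NULL)   # degenerate replicate rates
    }
    tab <- matrix(c(sum(a$n_near), sum(a$n_peaks) - sum(a$n_near),
                    sum(b$n_near), sum(b$n_peaks) - sum(b$n_near)),
                  2L, byrow = TRUE)
    out$fisher <- stats::fisher.test(tab, alternative = alternative)
  }
  out
}

#' Fisher test of interval-set overlap against a universe
#'
#' 2 x 2 table of {in A / not in A} x {overlaps track B by >= 1 bp / does
#' not} over the universe intervals, with Fisher's exact test. Overlap
#' uses half-open semantics: bookended intervals do not overlap.
#'
#' @param setA intervals (contig, start, end), a subset of the universe.
#' @param trackB intervals to overlap against.
#' @param universe all candidate intervals.
#' @param alternative passed to \code{fisher.test} (default "greater").
#' @return a \code{ContingencyResult}: list with table, odds_ratio
#'   (Haldane-Anscombe corrected when a zero cell), p, alternative.
#' @export
interval_overlap_fisher <- function(setA, trackB, universe,
                                    alternative = "greater") {
  if (!nrow(universe)) stop("empty universe")
  key <- function(d) paste(d$contig, d$start, d$end)
  inA <- key(universe) %in% key(setA)
  gr_u <- intervals_to_granges(universe$contig, universe$start,
                               universe$end)
  gr_b <- intervals_to_granges(trackB$contig, trackB$start, trackB$end)
  hit <- IRanges::overlapsAny(gr_u, gr_b)
  contingency_result(table = matrix(c(sum(inA & hit), sum(inA & !hit),
                                      sum(!inA & hit), sum(!inA & !hit)),
                                    2L, byrow = TRUE,
                                    dimnames = list(c("inA", "notA"),
                                                    c("hit", "nohit"))),
                     alternative = alternative)
}

#' Fisher test of gene-set overlap
#'
#' Standard 2 x 2 membership test of two gene sets over a universe.
#'
#' @param genesA,genesB gene sets (subsets of the universe).
#' @param universe universe genes.
#' @param alternative test sidedness (default "greater").
#' @return a \code{ContingencyResult}.
#' @export
set_overlap_fisher <- function(genesA, genesB, universe,
                               alternative = "greater") {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  if (!all(genesA %in% universe) || !all(genesB %in% universe)) {
    stop("gene sets must be subsets of the universe")
  }
  inA <- universe %in% genesA
  inB <- universe %in% genesB
  contingency_result(table = matrix(c(sum(inA & inB), sum(inA & !inB),
                                      sum(!inA & inB), sum(!inA & !inB)),
                                    2L, byrow = TRUE,
                                    dimnames = list(c("inA", "notA"),
                                                    c("inB", "notB"))),
                     alternative = alternative)
}

## shared construction: Fisher p from stats::fisher.test, odds ratio as
## the sample (cross-product) ratio with Haldane-Anscombe correction when
## a zero cell is present
contingency_result <- function(table, alternative) {
  stopifnot(all(table >= 0))
  ft <- stats::fisher.test(table, alternative = alternative)
  t2 <- table
  if (any(table == 0)) t2 <- table + 0.5
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  structure(list(table = table, odds_ratio = unname(or),
                 p = ft$p.value, alternative = alternative,
                 fisher = ft),
            class = "ContingencyResult")
}

#' @export
print.ContingencyResult <- function(x, ...) {
  print(x$table)
  cat("odds ratio:", signif(x$odds_ratio, 4), " Fisher p:",
      signif(x$p, 4), "(", x$alternative, ")\n")
  invisible(x)
}

#' Cell-type composition summary
#'
#' Counts and percentages (half-up rounding to 2 decimals, matching the
#' usual printed style) per label.
#'
#' @param labels character vector of per-cell labels.
#' @param digits decimals for the percentage (default 2).
#' @return data.frame label, n, pct, sorted by decreasing n.
#' @export
composition_summary <- function(labels, digits = 2L) {
  if (!length(labels)) stop("labels must be non-empty")
  tab <- sort(table(labels), decreasing = TRUE)
  data.frame(label = names(tab), n = as.integer(tab),
             pct = round_half_up(100 * as.integer(tab) / length(labels),
                                 digits),
             stringsAsFactors = FALSE, row.names = NULL)
}
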