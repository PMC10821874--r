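# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG state. All stochastic operations in the package go through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  expr
}

## round-half-up (printed-style percentages); round() is half-even
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

make_peak_ids <- function(contig, start, end) {
  sprintf("%s:%d-%d", contig, as.integer(start), as.integer(end))
}

parse_peak_ids <- function(ids) {
  m <- regmatches(ids, regexec("^(.+):([0-9]+)-([0-9]+)$", ids))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stop("malformed peak id(s): ", paste(ids[bad][1], collapse = ", "))
  data.frame(
    peak_id = ids,
    contig = vapply(m, `[`, "", 2L),
    start = as.integer(vapply(m, `[`, "", 3L)),
    end = as.integer(vapply(m, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
}

## 0-based half-open intervals -> GRanges (1-based closed)
intervals_to_granges <- function(contig, start, end) {
  GenomicRanges::GRanges(contig, IRanges::IRanges(start = start + 1L, end = end))
}

## column-standardize a dense matrix; constant columns -> NA columns
standardize_cols <- function(x) {
  mu <- colMeans(x)
  sd <- sqrt(colMeans(x^2) - mu^2)
  sd[sd < .Machine$double.eps^.5] <- NA_real_
  sweep(sweep(x, 2L, mu, "-"), 2L, sd, "/")
}

as_dense <- function(x) {
  if (methods::is(x, "sparseMatrix")) as.matrix(x) else as.matrix(x)
}

stopifnot_scalar_int <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x)) {
    stop("'", name, "' must be a single integer")
  }
}
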