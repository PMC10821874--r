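# Motif-prior GRN inference and in silico TF knockouts: candidate edges
# from motif hits in linked peaks, bagged ridge fits per cluster on
# kNN-imputed expression, linear KO propagation, embedding-shift vector
# fields, pseudotime-derived developmental flow and inner-product
# perturbation scores.

#' kNN imputation of normalized expression
#'
#' Averages each cell's expression with its k nearest embedding
#' neighbours. Single-cell counts make TF-target dependences almost
#' invisible at the per-cell level; GRN fitting and knockout simulation
#' operate on this smoothed layer.
#'
#' @param expr cells x genes normalized expression.
#' @param embedding cells x d embedding used for the neighbour graph.
#' @param k neighbours averaged with each cell (default 30).
#' @return dense smoothed matrix, same dimnames.
#' @export
knn_smooth <- function(expr, embedding, k = 30L) {
  x <- as_dense(expr)
  n <- nrow(x)
  k <- min(k, n - 1L)
  nn <- knn_index(embedding, k)
  out <- x
  for (i in seq_len(n)) {
    out[i, ] <- colMeans(x[c(i, nn[i, ]), , drop = FALSE])
  }
  dimnames(out) <- dimnames(expr)
  out
}

#' Candidate TF -> gene edges from motif hits in linked peaks
#'
#' A TF is a candidate regulator of a gene iff the TF's motif hits a peak
#' linked to the gene: either a significantly linked peak (primary mode)
#' or a peak coaccessible with the gene's promoter peak at
#' \code{coaccess >= coaccess_min} (alternate mode). Promoter peaks of the
#' gene itself are always eligible. Self-edges are excluded.
#'
#' @param links data.frame with gene_id, peak_id (significant links), or
#'   NULL when using coaccessibility.
#' @param hits \code{MotifHitMatrix}.
#' @param motif_map data.frame with motif_id, tf.
#' @param promoters optional data.frame gene_id, peak_id of promoter peaks
#'   (always eligible for their gene).
#' @param coaccess optional data.frame peak1, peak2, coaccess; pairs at or
#'   above \code{coaccess_min} connect a peak to the genes whose promoter
#'   peak it touches.
#' @param coaccess_min coaccessibility threshold (default 0.8).
#' @return data.frame tf, target, peak_id, motif_id (one row per
#'   justification).
#' @export
base_grn <- function(links = NULL, hits, motif_map, promoters = NULL,
                     coaccess = NULL, coaccess_min = 0.8) {
  if (!nrow(motif_map)) stop("empty motif map")
  gene_peaks <- list()
  add <- function(gp, gene, peak) {
    rbind(gp, data.frame(gene_id = gene, peak_id = peak,
                         stringsAsFactors = FALSE))
  }
  gp <- NULL
  if (!is.null(links) && nrow(links)) {
    gp <- add(gp, links$gene_id, links$peak_id)
  }
  if (!is.null(promoters) && nrow(promoters)) {
    gp <- add(gp, promoters$gene_id, promoters$peak_id)
  }
  if (!is.null(coaccess) && !is.null(promoters)) {
    ca <- coaccess[coaccess$coaccess >= coaccess_min, , drop = FALSE]
    if (nrow(ca)) {
      ca2 <- rbind(ca, data.frame(peak1 = ca$peak2, peak2 = ca$peak1,
                                  coaccess = ca$coaccess))
      m <- merge(ca2, promoters, by.x = "peak2", by.y = "peak_id")
      if (nrow(m)) gp <- add(gp, m$gene_id, m$peak1)
    }
  }
  if (is.null(gp) || !nrow(gp)) {
    return(data.frame(tf = character(0), target = character(0),
                      peak_id = character(0), motif_id = character(0)))
  }
  gp <- unique(gp)
  gp <- gp[gp$peak_id %in% rownames(hits), , drop = FALSE]
  ht <- methods::as(methods::as(hits, "TsparseMatrix"), "generalMatrix")
  hit_df <- data.frame(peak_id = rownames(hits)[ht@i + 1L],
                       motif_id = colnames(hits)[ht@j + 1L],
                       stringsAsFactors = FALSE)
  hit_df <- merge(hit_df, motif_map[, c("motif_id", "tf")], by = "motif_id")
  out <- merge(gp, hit_df, by = "peak_id")
  out <- out[out$tf != out$gene_id, , drop = FALSE]
  out <- unique(data.frame(tf = out$tf, target = out$gene_id,
                           peak_id = out$peak_id, motif_id = out$motif_id,
                           stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Fit per-cluster GRN coefficients by bagged ridge regression
#'
#' Per cluster (>= \code{min_cells}) and per target gene, the target's
#' normalized expression is regressed on its candidate TFs' expression
#' over \code{n_bags} bootstrap bags of cells (ridge penalty chosen by
#' generalized cross-validation on a small grid, per bag). The coefficient
#' is the bag mean; its p-value comes from the bag t-statistic with the
#' spread of bag coefficients as the scale. (Bootstrap bags share cells,
#' so the naive standard error sd/sqrt(n_bags) is anti-conservative;
#' scaling by the bag sd keeps permuted targets filtered at p < 0.001.)
#' Edges are kept at p < \code{p_max} and at most \code{max_edges} per
#' cluster by |coefficient|.
#'
#' @param expr cells x genes normalized expression.
#' @param clusters factor of cluster labels per cell.
#' @param candidates candidate edges from \code{\link{base_grn}}.
#' @param n_bags bootstrap bags (default 20).
#' @param p_max edge significance threshold (default 0.001).
#' @param max_edges maximum retained edges per cluster (default 2000).
#' @param min_cells minimum cluster size (default 50).
#' @param lambda_grid ridge penalties searched by GCV.
#' @param seed integer seed.
#' @return a \code{GRNModel}: list with \code{edges} (data.frame cluster,
#'   tf, target, coef, p, n_bags) and the filter settings.
#' @export
fit_grn <- function(expr, clusters, candidates, n_bags = 20L,
                    p_max = 0.001, max_edges = 2000L, min_cells = 50L,
                    lambda_grid = c(0.01, 0.1, 1, 10, 100), seed = 1L) {
  clusters <- droplevels(as.factor(clusters))
  cand <- split(candidates$tf, candidates$target)
  cand <- lapply(cand, unique)
  edges <- with_seed(seed, {
    rows <- list()
    for (cl in levels(clusters)) {
      cells <- which(clusters == cl)
      if (length(cells) < min_cells) next
      X <- expr[cells, , drop = FALSE]
      for (target in names(cand)) {
        tfs <- intersect(cand[[target]], colnames(X))
        if (!length(tfs) || !(target %in% colnames(X))) next
        y <- X[, target]
        P <- X[, tfs, drop = FALSE]
        if (stats::sd(y) == 0) next
        coefs <- matrix(NA_real_, n_bags, length(tfs))
        for (b in seq_len(n_bags)) {
          idx <- sample.int(length(y), replace = TRUE)
          coefs[b, ] <- .ridge_gcv(P[idx, , drop = FALSE], y[idx],
                                   lambda_grid)
        }
        cm <- colMeans(coefs)
        se <- apply(coefs, 2L, stats::sd)
        tstat <- cm / pmax(se, .Machine$double.eps)
        p <- 2 * stats::pt(-abs(tstat), df = n_bags - 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          cluster = cl, tf = tfs, target = target, coef = cm, p = p,
          stringsAsFactors = FALSE)
      }
    }
    if (!length(rows)) {
      data.frame(cluster = character(0), tf = character(0),
                 target = character(0), coef = numeric(0), p = numeric(0))
    } else do.call(rbind, rows)
  })
  kept <- do.call(rbind, lapply(split(edges, edges$cluster), function(e) {
    e <- e[e$p < p_max, , drop = FALSE]
    e[utils::head(order(-abs(e$coef)), max_edges), , drop = FALSE]
  }))
  if (is.null(kept)) kept <- edges[0, ]
  rownames(kept) <- NULL
  structure(list(edges = kept, all_edges = edges,
                 settings = list(p_max = p_max, max_edges = max_edges,
                                 weight_criterion = "coef_abs",
                                 n_bags = n_bags)),
            class = "GRNModel")
}

## ridge with intercept on standardized predictors; lambda by GCV
.ridge_gcv <- function(X, y, lambda_grid) {
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  keep <- sd > 0
  if (!any(keep)) return(rep(0, ncol(X)))
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2L, mu[keep], "-"), 2L,
              sd[keep], "/")
  yc <- y - mean(y)
  n <- nrow(Xs); p <- ncol(Xs)
  sv <- svd(Xs)
  uy <- crossprod(sv$u, yc)
  best <- NULL; best_gcv <- Inf
  for (lam in lambda_grid) {
    shrink <- sv$d / (sv$d^2 + lam)
    beta <- sv$v %*% (shrink * uy)
    df <- sum(sv$d^2 / (sv$d^2 + lam))
    rss <- sum((yc - Xs %*% beta)^2)
    gcv <- rss / (n * (1 - df / n)^2)
    if (gcv < best_gcv) { best_gcv <- gcv; best <- beta }
  }
  out <- rep(0, ncol(X))
  out[keep] <- best / sd[keep]   # back to the original predictor scale
  out
}

#' Propagate an in silico TF knockout through the GRN
#'
#' The perturbed TF's expression is set to 0 (shift -x_TF per cell); the
#' shift is propagated \code{n_propagation} times through each cell's
#' cluster GRN as linear signal flow (delta_target += coef * delta_tf),
#' clipping so no gene's shifted value goes below zero. The KO gene's
#' coordinate is held at its knockout shift.
#'
#' @param grn a \code{GRNModel}.
#' @param expr cells x genes normalized expression.
#' @param clusters factor of cluster labels per cell.
#' @param tf the TF gene to knock out.
#' @param n_propagation propagation rounds (default 3).
#' @return dense cells x genes shift matrix delta; zero (with a warning)
#'   if the TF is absent from every cluster GRN.
#' @export
simulate_knockout <- function(grn, expr, clusters, tf, n_propagation = 3L) {
  if (!(tf %in% colnames(expr))) stop("TF not in gene catalog")
  clusters <- droplevels(as.factor(clusters))
  delta <- matrix(0, nrow(expr), ncol(expr), dimnames = dimnames(expr))
  edges <- grn$edges
  if (!nrow(edges) || !(tf %in% edges$tf)) {
    if (!nrow(edges[edges$tf == tf, ])) {
      warning("TF ", tf, " has no outgoing edges in any cluster GRN")
    }
  }
  genes <- colnames(expr)
  for (cl in levels(clusters)) {
    cells <- which(clusters == cl)
    e <- edges[edges$cluster == cl, , drop = FALSE]
    W <- Matrix::sparseMatrix(
      i = match(e$target, genes), j = match(e$tf, genes), x = e$coef,
      dims = c(length(genes), length(genes)))
    x <- expr[cells, , drop = FALSE]
    d0 <- matrix(0, length(cells), length(genes))
    d0[, match(tf, genes)] <- -x[, tf]
    acc <- d0
    cur <- d0
    for (step in seq_len(n_propagation)) {
      cur <- as.matrix(Matrix::tcrossprod(cur, W))
      cur[, match(tf, genes)] <- 0
      ## clip: shifted expression cannot go below zero
      cur <- pmax(cur, -(x + acc))
      acc <- acc + cur
    }
    acc[, match(tf, genes)] <- d0[, match(tf, genes)]
    delta[cells, ] <- acc
  }
  delta
}

#' Project gene-space knockout shifts onto a 2-D embedding
#'
#' For each cell i and its \code{n_neighbors} nearest embedding
#' neighbours j, transition probabilities P_ij are proportional to
#' exp(corr(delta_i, x_j - x_i) / sigma_corr) (correlation over the GRN
#' gene space); the 2-D shift is sum_j P_ij (e_j - e_i) minus the
#' unweighted mean of (e_j - e_i). The per-cell shifts are averaged onto
#' an n x n grid with a Gaussian kernel.
#'
#' @param delta cells x genes shift matrix from
#'   \code{\link{simulate_knockout}}.
#' @param expr cells x genes normalized expression (same columns).
#' @param embedding2d cells x 2 embedding.
#' @param n_neighbors neighbours per cell (default 200; clipped with a
#'   warning when >= n_cells).
#' @param sigma_corr softmax temperature (default 0.05).
#' @param genes genes used for the correlation (default: all genes; the
#'   zero coordinates of delta anchor the pattern, so restricting to the
#'   shifted genes alone would degrade the matching).
#' @param grid_n grid resolution per axis (default 40).
#' @return list with \code{shift} (cells x 2), \code{grid} (grid_n^2 x 2
#'   centers), \code{field} (grid_n^2 x 2 mean shifts), \code{grid_count}
#'   (cells per grid box).
#' @export
embedding_shift <- function(delta, expr, embedding2d, n_neighbors = 200L,
                            sigma_corr = 0.05, genes = NULL, grid_n = 40L,
                            cache = NULL) {
  if (is.null(cache)) {
    cache <- shift_cache(expr, embedding2d, n_neighbors = n_neighbors,
                         genes = genes)
  }
  n <- nrow(embedding2d)
  X <- cache$X
  nn <- cache$nn
  k <- ncol(nn)
  D <- as_dense(delta[, colnames(X), drop = FALSE])
  G <- ncol(X)

  ## correlation of delta_i with (x_j - x_i) over all genes, for all
  ## neighbour pairs, via shared matrix products
  A <- tcrossprod(D, X)                 # sum_g delta_ig x_jg
  B <- rowSums(D * X)                   # sum_g delta_ig x_ig
  mD <- rowMeans(D)
  sdD <- sqrt(pmax(rowMeans(D^2) - mD^2, 0))
  ii <- rep(seq_len(n), k)
  jj <- as.vector(nn)
  mv <- cache$mX[jj] - cache$mX[ii]
  ssv <- cache$q[jj] + cache$q[ii] - 2 * cache$S[cbind(ii, jj)]
  sdv <- sqrt(pmax(ssv / G - mv^2, 0))
  cov <- (A[cbind(ii, jj)] - B[ii]) / G - mD[ii] * mv
  cc <- cov / (sdD[ii] * sdv)
  cc[!is.finite(cc)] <- 0
  W <- matrix(exp(cc / sigma_corr), n, k)
  W <- W / rowSums(W)

  ex <- matrix(embedding2d[jj, 1], n, k) - embedding2d[, 1]
  ey <- matrix(embedding2d[jj, 2], n, k) - embedding2d[, 2]
  shift <- cbind(rowSums(W * ex) - rowMeans(ex),
                 rowSums(W * ey) - rowMeans(ey))
  shift[sdD == 0, ] <- 0                # cells with zero delta do not move
  rownames(shift) <- rownames(embedding2d)
  gr <- .grid_average(embedding2d, shift, grid_n)
  list(shift = shift, grid = gr$grid, field = gr$field,
       grid_count = gr$count)
}

#' @rdname embedding_shift
#' @description \code{shift_cache} precomputes the expression cross
#'   products and the kNN table shared by every knockout scored on the
#'   same dataset and embedding.
#' @export
shift_cache <- function(expr, embedding2d, n_neighbors = 200L,
                        genes = NULL) {
  n <- nrow(embedding2d)
  if (n_neighbors >= n) {
    warning("n_neighbors >= n_cells; clipping")
    n_neighbors <- n - 1L
  }
  if (is.null(genes)) genes <- colnames(expr)
  X <- as_dense(expr[, genes, drop = FALSE])
  list(X = X, nn = knn_index(embedding2d, n_neighbors),
       S = tcrossprod(X), q = rowSums(X^2), mX = rowMeans(X))
}

## Gaussian-kernel average of per-cell vectors on a regular grid
.grid_average <- function(embedding2d, values, grid_n, bw = NULL) {
  rx <- range(embedding2d[, 1]); ry <- range(embedding2d[, 2])
  gx <- seq(rx[1], rx[2], length.out = grid_n)
  gy <- seq(ry[1], ry[2], length.out = grid_n)
  grid <- cbind(rep(gx, times = grid_n), rep(gy, each = grid_n))
  if (is.null(bw)) bw <- mean(c(diff(gx)[1], diff(gy)[1]))
  field <- matrix(0, nrow(grid), ncol(values))
  count <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    d2 <- (embedding2d[, 1] - grid[gi, 1])^2 +
      (embedding2d[, 2] - grid[gi, 2])^2
    w <- exp(-d2 / (2 * bw^2))
    count[gi] <- sum(d2 <= (1.5 * bw)^2)
    if (sum(w) > 0) field[gi, ] <- colSums(values * w) / sum(w)
  }
  list(grid = grid, field = field, count = count, bw = bw)
}

#' Developmental flow field from diffusion pseudotime
#'
#' Smooths pseudotime onto the embedding grid with a Gaussian kernel and
#' takes the finite-difference spatial gradient (pointing toward
#' increasing pseudotime). Grid boxes without nearby cells are masked.
#'
#' @param embedding2d cells x 2 embedding.
#' @param tau named pseudotime vector.
#' @param grid_n grid resolution (must match the shift field's).
#' @return list with \code{grid}, \code{flow} (grid_n^2 x 2), \code{mask}
#'   (boxes with cells), smoothed \code{tau_grid}.
#' @export
developmental_flow <- function(embedding2d, tau, grid_n = 40L) {
  tau <- tau[rownames(embedding2d)]
  gr <- .grid_average(embedding2d, cbind(tau), grid_n)
  tg <- matrix(gr$field[, 1], grid_n, grid_n)
  mask <- matrix(gr$count > 0, grid_n, grid_n)
  dx <- matrix(0, grid_n, grid_n); dy <- matrix(0, grid_n, grid_n)
  hx <- diff(gr$grid[1:2, 1]); hy <- hx
  for (i in seq_len(grid_n)) {
    dx[, i] <- .central_diff(tg[, i]) / hx
    dy[i, ] <- .central_diff(tg[i, ]) / hy
  }
  flow <- cbind(as.vector(dx), as.vector(dy))
  flow[!as.vector(mask), ] <- 0
  list(grid = gr$grid, flow = flow, mask = as.vector(mask), tau_grid = tg)
}

.central_diff <- function(v) {
  n <- length(v)
  out <- numeric(n)
  if (n >= 3L) out[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / 2
  out[1] <- v[2] - v[1]
  out[n] <- v[n] - v[n - 1]
  out
}

#' Inner-product perturbation score over a lineage mask
#'
#' score = - sum over masked grid boxes of <shift, flow>; positive scores
#' mean the knockout field opposes the developmental flow (development
#' reversed).
#'
#' @param field grid shift field (from \code{\link{embedding_shift}}).
#' @param flow grid flow field (from \code{\link{developmental_flow}}).
#' @param mask logical vector over grid boxes (the lineage's territory).
#' @return list with \code{score} and per-box \code{contributions}.
#' @export
perturbation_score <- function(field, flow, mask) {
  if (!any(mask)) stop("empty lineage mask")
  ip <- rowSums(field * flow)
  contributions <- -ip * mask
  list(score = sum(contributions), contributions = contributions)
}

#' Grid mask of a lineage from per-cell labels
#'
#' A grid box belongs to the lineage iff the majority of the cells nearest
#' to it carry the lineage label.
#'
#' @param embedding2d cells x 2 embedding.
#' @param labels named character vector of per-cell lineage labels.
#' @param lineage the lineage label.
#' @param grid_n grid resolution.
#' @return logical vector over the grid_n^2 boxes.
#' @export
lineage_mask <- function(embedding2d, labels, lineage, grid_n = 40L) {
  labels <- labels[rownames(embedding2d)]
  gr <- .grid_average(embedding2d, cbind(as.numeric(labels == lineage)),
                      grid_n)
  gr$count > 0 & gr$field[, 1] > 0.5
}

#' Degree-matched random-TF null scores for a knockout
#'
#' Builds \code{n} random pseudo-TFs with the same out-degree as the real
#' TF: each is a randomly drawn gene, assigned that many random target
#' genes, with edge coefficients re-fit per cluster by the same
#' bagged-ridge machinery and edge filter as \code{\link{fit_grn}}, and
#' scored by the same knockout path. Random TF-to-gene dependences are
#' weak, so the resulting score distribution calibrates how specific the
#' real TF's score is.
#'
#' @param grn a \code{GRNModel} (supplies the filter settings).
#' @param expr,clusters,embedding2d,tau as for the real scoring path.
#' @param tf the TF whose degree (candidate regulon size) is matched.
#' @param mask lineage mask.
#' @param n number of null draws (default 20).
#' @param n_propagation,n_neighbors,sigma_corr,grid_n forwarded.
#' @param min_cells minimum cluster size, as in \code{\link{fit_grn}}.
#' @param seed integer seed.
#' @return numeric vector of n null scores.
#' @export
perturbation_null_scores <- function(grn, expr, clusters, embedding2d, tau,
                                     tf, mask, n = 20L, n_propagation = 3L,
                                     n_neighbors = 200L, sigma_corr = 0.05,
                                     grid_n = 40L, min_cells = 50L,
                                     seed = 1L) {
  flow <- developmental_flow(embedding2d, tau, grid_n)
  clusters <- droplevels(as.factor(clusters))
  genes <- colnames(expr)
  cache <- shift_cache(expr, embedding2d, n_neighbors = n_neighbors)
  deg <- length(unique(grn$edges$target[grn$edges$tf == tf]))
  if (!deg) stop("TF has no edges to match")
  n_bags <- grn$settings$n_bags %||% 20L
  p_max <- grn$settings$p_max %||% 0.001
  with_seed(seed, {
    vapply(seq_len(n), function(r) {
      pseudo <- sample(setdiff(genes, tf), 1L)
      targets <- sample(setdiff(genes, pseudo), deg)
      rows <- list()
      for (cl in levels(clusters)) {
        cells <- which(clusters == cl)
        if (length(cells) < min_cells) next
        xtf <- expr[cells, pseudo]
        if (stats::sd(xtf) == 0) next
        for (target in targets) {
          y <- expr[cells, target]
          if (stats::sd(y) == 0) next
          coefs <- vapply(seq_len(n_bags), function(b) {
            idx <- sample.int(length(y), replace = TRUE)
            .ridge_gcv(cbind(xtf[idx]), y[idx], c(0.01, 0.1, 1, 10, 100))
          }, 0)
          cm <- mean(coefs)
          se <- stats::sd(coefs)
          p <- 2 * stats::pt(-abs(cm / max(se, .Machine$double.eps)),
                             df = n_bags - 1L)
          if (p < p_max) {
            rows[[length(rows) + 1L]] <- data.frame(
              cluster = cl, tf = pseudo, target = target, coef = cm, p = p,
              stringsAsFactors = FALSE)
          }
        }
      }
      g2 <- grn
      g2$edges <- if (length(rows)) do.call(rbind, rows) else
        grn$edges[0, c("cluster", "tf", "target", "coef", "p")]
      delta <- suppressWarnings(
        simulate_knockout(g2, expr, clusters, pseudo,
                          n_propagation = n_propagation))
      es <- embedding_shift(delta, expr, embedding2d,
                            n_neighbors = n_neighbors,
                            sigma_corr = sigma_corr, grid_n = grid_n,
                            cache = cache)
      perturbation_score(es$field, flow$flow, mask)$score
    }, 0)
  })
}
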