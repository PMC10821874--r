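# Optimal-transport trajectory machinery: growth rates, entropic unbalanced
# Sinkhorn couplings with growth iterations, the layered global transition
# matrix, random walks, macrostates and absorption fate probabilities,
# diffusion pseudotime, driver genes and stage-resolved profiles.

#' Initial growth rates from a proliferation gene set
#'
#' Mean normalized expression of the proliferation set, z-scored across
#' cells; g = exp(z). Bounded, positive, and documented as the initial
#' estimate that the OT growth iterations refine.
#'
#' @param dataset a \code{MultiomeDataset} with the \code{lognorm} layer.
#' @param prolif_genes gene ids of the proliferation program.
#' @return named numeric vector of growth rates, one per cell.
#' @export
growth_rates <- function(dataset, prolif_genes) {
  if (is.null(dataset$layers$lognorm)) stop("run normalize_rna() first")
  set <- intersect(prolif_genes, colnames(dataset$layers$lognorm))
  if (!length(set)) stop("proliferation gene set disjoint from gene catalog")
  score <- rowMeans(dataset$layers$lognorm[, set, drop = FALSE])
  z <- if (stats::sd(score) > 0) (score - mean(score)) / stats::sd(score)
       else score * 0
  stats::setNames(exp(z), rownames(dataset$rna))
}

#' Entropic unbalanced optimal-transport coupling between two stages
#'
#' Solves min <gamma, C> + eps * KL(gamma | a x b) with a soft (KL, penalty
#' \code{lambda}) source marginal proportional to g^delta_t and a hard
#' uniform target marginal, by Sinkhorn-style scaling. After each of
#' \code{growth_iters} iterations the growth rates are re-estimated from
#' each source cell's transported mass and the problem is re-solved.
#' \code{lambda = Inf} gives the balanced (hard both marginals) problem.
#'
#' @param source,target embeddings (cells x d) of the two stages; the cost
#'   is squared Euclidean distance in this shared space.
#' @param g growth rates of the source cells.
#' @param eps entropic regularization; default \code{eps_frac * mean(C)}.
#' @param eps_frac used when eps is NULL (default 0.05).
#' @param lambda unbalanced penalty on the source marginal (default 1).
#' @param growth_iters growth re-estimation rounds (default 3).
#' @param delta_t time gap between the stages (default 1).
#' @param max_iter,tol Sinkhorn iteration budget and convergence tolerance
#'   on the scaling updates; non-convergence is an error reporting the
#'   residual.
#' @return the coupling matrix gamma (source x target, mass units) with
#'   the final growth estimates in \code{attr(, "growth")}.
#' @export
ot_coupling <- function(source, target, g = NULL, eps = NULL,
                        eps_frac = 0.05, lambda = 1, growth_iters = 3L,
                        delta_t = 1, max_iter = 5000L, tol = 1e-8) {
  n1 <- nrow(source); n2 <- nrow(target)
  if (!n1 || !n2) stop("both stages must be non-empty")
  if (is.null(g)) g <- rep(1, n1)
  stopifnot(length(g) == n1, all(g > 0))
  C <- outer(rowSums(source^2), rowSums(target^2), "+") -
    2 * source %*% t(target)
  C <- pmax(C, 0)
  if (is.null(eps)) eps <- eps_frac * mean(C)
  if (eps <= 0) stop("eps must be positive")
  expo <- if (is.infinite(lambda)) 1 else lambda / (lambda + eps)
  b <- rep(1 / n2, n2)
  lse_rows <- function(S) {
    m <- apply(S, 1L, max)
    log(rowSums(exp(S - m))) + m
  }
  gamma <- NULL
  for (it in seq_len(max(1L, growth_iters))) {
    a <- g^delta_t
    a <- a / sum(a)
    ## stabilized log-domain scaling with potentials f, g2
    f <- rep(0, n1); g2 <- rep(0, n2)
    converged <- FALSE
    for (s in seq_len(max_iter)) {
      f_new <- expo *
        (eps * log(a) - eps * lse_rows(sweep(-C, 2L, g2, "+") / eps))
      g2 <- eps * log(b) -
        eps * lse_rows(t(sweep(-C, 1L, f_new, "+")) / eps)
      delta <- max(abs(f_new - f)) / (1 + max(abs(f_new)))
      f <- f_new
      if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged) {
      stop("Sinkhorn did not converge within ", max_iter,
           " iterations (last update ", signif(delta, 3), ")")
    }
    gamma <- exp((outer(f, g2, "+") - C) / eps)
    g <- rowSums(gamma)
    g <- g / mean(g)
  }
  dimnames(gamma) <- list(rownames(source), rownames(target))
  attr(gamma, "growth") <- g
  attr(gamma, "eps") <- eps
  gamma
}

#' Symmetric kNN connectivity kernel
#'
#' Gaussian weights on the union kNN graph (bandwidth = median kNN
#' distance), symmetrized by averaging. Used for the last sampling stage of
#' the transition matrix and for diffusion pseudotime.
#'
#' @param embedding cells x d matrix.
#' @param k neighbours per cell.
#' @return dense symmetric weight matrix with zero diagonal.
#' @export
connectivity_kernel <- function(embedding, k = 15L) {
  n <- nrow(embedding)
  k <- min(k, n - 1L)
  d <- as.matrix(stats::dist(embedding))
  diag(d) <- Inf
  nn <- t(apply(d, 1L, function(r) order(r)[seq_len(k)]))
  sigma <- stats::median(d[cbind(rep(seq_len(n), each = k),
                                 as.vector(t(nn)))])
  W <- matrix(0, n, n, dimnames = list(rownames(embedding),
                                       rownames(embedding)))
  idx <- cbind(rep(seq_len(n), each = k), as.vector(t(nn)))
  W[idx] <- exp(-(d[idx] / sigma)^2)
  (W + t(W)) / 2
}

#' Assemble the global transition matrix across stages
#'
#' Rows of cells in stage i < last are their row-normalized OT coupling to
#' stage i+1; rows of last-stage cells are the row-normalized symmetric
#' kNN connectivity kernel within that stage, so the last stage is closed
#' under the chain. Zero rows get a self-loop with a warning.
#'
#' @param couplings list of coupling matrices for adjacent stage pairs, in
#'   stage order, with cell barcodes as dimnames.
#' @param last_kernel symmetric within-stage kernel for the last stage
#'   (from \code{\link{connectivity_kernel}}).
#' @return a row-stochastic dense matrix over all cells, with per-stage
#'   index lists in \code{attr(, "stages")}.
#' @export
transition_matrix <- function(couplings, last_kernel) {
  stage_cells <- c(lapply(couplings, rownames),
                   list(rownames(last_kernel)))
  for (i in seq_along(couplings)) {
    nxt <- if (i < length(couplings)) rownames(couplings[[i + 1]]) else
      rownames(last_kernel)
    if (!identical(colnames(couplings[[i]]), nxt)) {
      stop("coupling ", i, " target cells do not match stage ", i + 1)
    }
  }
  cells <- unlist(stage_cells)
  n <- length(cells)
  T_ <- matrix(0, n, n, dimnames = list(cells, cells))
  offset <- 0L
  for (i in seq_along(couplings)) {
    gam <- couplings[[i]]
    rs <- rowSums(gam)
    zero <- rs == 0
    if (any(zero)) {
      warning(sum(zero), " isolated cell(s) in stage ", i,
              "; inserting self-loops")
    }
    rows <- offset + seq_len(nrow(gam))
    cols <- offset + nrow(gam) + seq_len(ncol(gam))
    T_[rows, cols] <- gam / pmax(rs, .Machine$double.xmin)
    if (any(zero)) {
      T_[cbind(rows[zero], rows[zero])] <- 1
      T_[rows[zero], cols] <- 0
    }
    offset <- offset + nrow(gam)
  }
  rows <- offset + seq_len(nrow(last_kernel))
  rs <- rowSums(last_kernel)
  zero <- rs == 0
  if (any(zero)) {
    warning(sum(zero), " isolated cell(s) in the last stage; self-loops")
  }
  T_[rows, rows] <- last_kernel / pmax(rs, .Machine$double.xmin)
  if (any(zero)) T_[cbind(rows[zero], rows[zero])] <- 1
  attr(T_, "stages") <- lapply(stage_cells, function(s) match(s, cells))
  T_
}

#' Simulate random walks on a transition matrix
#'
#' Categorical stepping per row for \code{n_steps} steps; deterministic
#' given the seed.
#'
#' @param T_ row-stochastic matrix.
#' @param start integer indices (or names) of start cells, one per walk.
#' @param n_sims number of walks (start cells recycled).
#' @param n_steps steps per walk (>= 1).
#' @param seed integer seed.
#' @return list with \code{paths} (n_sims x (n_steps + 1) index matrix),
#'   \code{endpoints} and per-state \code{visits} counts.
#' @export
random_walks <- function(T_, start, n_sims = 300L, n_steps = 10L,
                         seed = 1L) {
  if (n_steps < 1L) stop("n_steps must be >= 1")
  n <- nrow(T_)
  if (is.character(start)) start <- match(start, rownames(T_))
  stopifnot(all(start >= 1L & start <= n))
  with_seed(seed, {
    cur <- rep_len(start, n_sims)
    paths <- matrix(0L, n_sims, n_steps + 1L)
    paths[, 1L] <- cur
    for (s in seq_len(n_steps)) {
      for (st in unique(cur)) {
        idx <- which(cur == st)
        pr <- T_[st, ]
        cur[idx] <- sample.int(n, length(idx), replace = TRUE, prob = pr)
      }
      paths[, s + 1L] <- cur
    }
    list(paths = paths, endpoints = cur,
         visits = tabulate(paths, nbins = n))
  })
}

#' Absorption probabilities toward labelled terminal cells
#'
#' Makes the terminal cells absorbing and solves (I - Q) F = R for the
#' probability that a walk from each transient cell is absorbed in each
#' terminal state. Terminal-cell rows are their own state's indicator.
#'
#' @param T_ row-stochastic matrix.
#' @param terminal named list: terminal state name -> integer indices (or
#'   names) of its cells.
#' @return cells x terminal-states probability matrix (rows sum to 1).
#' @export
absorption_probabilities <- function(T_, terminal) {
  n <- nrow(T_)
  terminal <- lapply(terminal, function(x) {
    if (is.character(x)) match(x, rownames(T_)) else as.integer(x)
  })
  term_idx <- unlist(terminal)
  if (anyDuplicated(term_idx)) stop("terminal states overlap")
  trans <- setdiff(seq_len(n), term_idx)
  R <- matrix(0, length(trans), length(terminal),
              dimnames = list(NULL, names(terminal)))
  for (k in seq_along(terminal)) {
    R[, k] <- rowSums(T_[trans, terminal[[k]], drop = FALSE])
  }
  Q <- T_[trans, trans, drop = FALSE]
  Fm <- solve(diag(length(trans)) - Q, R)
  out <- matrix(0, n, length(terminal),
                dimnames = list(rownames(T_), names(terminal)))
  out[trans, ] <- Fm
  for (k in seq_along(terminal)) out[terminal[[k]], k] <- 1
  bad <- abs(rowSums(out) - 1) > 1e-6
  if (any(bad)) {
    warning(sum(bad), " cell(s) cannot reach any terminal state; ",
            "their rows do not sum to 1")
  }
  out
}

#' Macrostates, terminal states and fate probabilities
#'
#' Approximates GPCCA: cells are clustered (seeded k-means) in the space of
#' the dominant right eigenvectors of the transition matrix. For the
#' layered chains built by \code{\link{transition_matrix}} the spectrum
#' lives in the closed last-stage block, so eigenvectors are computed there
#' and extended backward through the stages via v = (T v) / lambda.
#' The coarse-grained transition matrix is computed with
#' stationary-distribution weights (power iteration), which concentrates on
#' the recurrent cells; macrostates whose coarse self-transition reaches
#' \code{self_transition_min} (or those named explicitly) are terminal, and
#' fate probabilities are the absorption probabilities toward them. The
#' default threshold 0.8 is calibrated to this hard-partition
#' approximation of GPCCA (soft-membership coarse matrices concentrate
#' nearer 1, where a 0.95 cut is customary).
#'
#' @param T_ transition matrix from \code{\link{transition_matrix}} (or any
#'   row-stochastic matrix for the generic eigen path).
#' @param n_macrostates number of macrostates (default 6).
#' @param self_transition_min coarse self-transition threshold (default
#'   0.8, see Details).
#' @param terminal_states optional explicit terminal macrostate ids.
#' @param seed integer seed for k-means.
#' @return a \code{FateModel}: list with macrostates (factor per cell),
#'   terminal (macrostate ids), fate (cells x terminal absorption matrix),
#'   terminal_likelihood (max fate probability per cell), coarse (coarse
#'   transition matrix).
#' @export
fate_probabilities <- function(T_, n_macrostates = 6L,
                               self_transition_min = 0.8,
                               terminal_states = NULL, seed = 1L) {
  n <- nrow(T_)
  k <- n_macrostates
  stages <- attr(T_, "stages")
  if (!is.null(stages)) {
    last <- stages[[length(stages)]]
    TL <- T_[last, last, drop = FALSE]
    eig <- eigen(TL)
    ord <- order(Mod(eig$values), decreasing = TRUE)[seq_len(min(k, length(last)))]
    V <- matrix(0, n, length(ord))
    V[last, ] <- Re(eig$vectors[, ord, drop = FALSE])
    lam <- Re(eig$values[ord])
    ## extend eigenvectors backward: v_stage_i = (T v) / lambda
    for (si in rev(seq_len(length(stages) - 1L))) {
      rows <- stages[[si]]
      nxt <- stages[[si + 1L]]
      V[rows, ] <- (T_[rows, nxt, drop = FALSE] %*% V[nxt, , drop = FALSE]) %*%
        diag(1 / pmax(abs(lam), 1e-12) * sign(lam), length(lam))
    }
  } else {
    eig <- eigen(T_)
    ord <- order(Mod(eig$values), decreasing = TRUE)[seq_len(min(k, n))]
    V <- Re(eig$vectors[, ord, drop = FALSE])
  }
  V <- scale(V, center = FALSE, scale = pmax(apply(abs(V), 2, max), 1e-12))
  km <- with_seed(seed, stats::kmeans(V, centers = k, nstart = 10L,
                                      iter.max = 100L))
  macro <- factor(paste0("ms", km$cluster),
                  levels = paste0("ms", seq_len(k)))
  names(macro) <- rownames(T_)

  ## stationary weights concentrate the coarse matrix on recurrent cells
  pi_ <- rep(1 / n, n)
  for (i in seq_len(300L)) pi_ <- as.numeric(pi_ %*% T_)
  coarse <- matrix(0, k, k, dimnames = list(levels(macro), levels(macro)))
  for (a in seq_len(k)) {
    rows <- which(km$cluster == a)
    if (!length(rows)) next
    wa <- pi_[rows]
    agg <- if (sum(wa) > 0) {
      colSums(T_[rows, , drop = FALSE] * wa) / sum(wa)
    } else colSums(T_[rows, , drop = FALSE]) / length(rows)
    coarse[a, ] <- vapply(seq_len(k), function(b) {
      sum(agg[km$cluster == b])
    }, 0)
  }
  ## a macrostate with no stationary mass is transient regardless of its
  ## unweighted diagonal
  has_mass <- vapply(seq_len(k), function(a) {
    sum(pi_[km$cluster == a]) > 1e-8
  }, TRUE)
  terminal <- terminal_states %||%
    levels(macro)[diag(coarse) >= self_transition_min & has_mass &
                    tabulate(km$cluster, k) > 0]
  if (!length(terminal)) stop("no terminal macrostate found; lower ",
                              "self_transition_min or name them explicitly")
  term_cells <- lapply(terminal, function(m) which(macro == m))
  names(term_cells) <- terminal
  fate <- absorption_probabilities(T_, term_cells)
  structure(list(macrostates = macro, terminal = terminal, fate = fate,
                 terminal_likelihood = apply(fate, 1L, max),
                 coarse = coarse),
            class = "FateModel")
}

#' Diffusion pseudotime from a root cell
#'
#' Diffusion map of the symmetrized kNN transition kernel on the given
#' embedding; pseudotime is the diffusion distance to the root
#' (eigenvalue-weighted, components 2..n_comps), rescaled to [0, 1].
#'
#' @param embedding cells x d matrix (for example RNA PCs).
#' @param root root cell (index or name); tau(root) = 0.
#' @param k kNN for the kernel.
#' @param n_comps diffusion components used.
#' @return named numeric vector tau in [0, 1].
#' @export
diffusion_pseudotime <- function(embedding, root, k = 15L, n_comps = 10L) {
  n <- nrow(embedding)
  if (is.character(root)) root <- match(root, rownames(embedding))
  stopifnot(root >= 1L, root <= n)
  W <- connectivity_kernel(embedding, k)
  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    stop("kNN graph is disconnected (", comp$no, " components of sizes ",
         paste(comp$csize, collapse = ", "), ")")
  }
  d <- rowSums(W)
  S <- W / sqrt(d %o% d)
  eig <- eigen(S, symmetric = TRUE)
  m <- min(n_comps, n - 1L)
  lam <- eig$values[2:(m + 1L)]
  psi <- eig$vectors[, 2:(m + 1L), drop = FALSE] / sqrt(d)
  wts <- lam / (1 - pmin(lam, 1 - 1e-10))
  diff_coord <- sweep(psi, 2L, wts, "*")
  tau <- sqrt(rowSums((diff_coord -
                         matrix(diff_coord[root, ], n, m, byrow = TRUE))^2))
  tau <- tau / max(tau)
  stats::setNames(tau, rownames(embedding))
}

#' Driver genes of a lineage
#'
#' Pearson correlation between each gene's expression and the fate
#' probability toward the lineage, t-approximation p-values, BH adjustment;
#' drivers satisfy rho > 0.05 and padj < 0.05. Constant genes are skipped.
#'
#' @param expr cells x genes normalized expression.
#' @param fate fate probability matrix from \code{\link{fate_probabilities}}.
#' @param lineage column of \code{fate} to use.
#' @return a \code{DriverTable} data.frame: gene, rho, p, padj, driver.
#' @export
driver_genes <- function(expr, fate, lineage) {
  f <- fate[rownames(expr), lineage]
  sds <- apply(expr, 2L, stats::sd)
  keep <- sds > 0 & stats::sd(f) > 0
  x <- expr[, keep, drop = FALSE]
  n <- nrow(x)
  rho <- as.numeric(stats::cor(x, f))
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-12))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  padj <- stats::p.adjust(p, method = "BH")
  out <- data.frame(gene = colnames(x), rho = rho, p = p, padj = padj,
                    driver = rho > 0.05 & padj < 0.05,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("DriverTable", "data.frame")
  out
}

#' Stage grouping and smoothed profiles of driver genes along a lineage
#'
#' Cells with fate probability above the lineage's \code{quantile} are
#' extracted and ordered by diffusion pseudotime; each driver's expression
#' is smoothed with a centered rolling mean (window 5 percent of the
#' extracted cells, at least 11), standardized, and the drivers grouped by
#' seeded k-means (k = 3) into start/middle/end by the tertile of each
#' cluster's mean peak position. \code{method = "quantile"} instead cuts
#' drivers into three equal groups by peak-position quantiles.
#'
#' @param expr cells x genes normalized expression.
#' @param drivers \code{DriverTable}; only rows with driver = TRUE are used.
#' @param tau diffusion pseudotime (named).
#' @param fate fate matrix; \code{lineage} names the column.
#' @param lineage lineage id.
#' @param quantile fate-probability quantile for cell extraction
#'   (default 0.75, per lineage).
#' @param k number of driver groups (default 3).
#' @param method "kmeans" (primary) or "quantile" (fallback).
#' @param seed integer seed for k-means.
#' @return list with \code{groups} (data.frame gene, stage_group,
#'   peak_position), \code{profiles} (drivers x positions standardized
#'   smoothed matrix), \code{cells} (ordered barcodes used).
#' @export
stage_profiles <- function(expr, drivers, tau, fate, lineage,
                           quantile = 0.75, k = 3L,
                           method = c("kmeans", "quantile"), seed = 1L) {
  method <- match.arg(method)
  genes <- drivers$gene[drivers$driver]
  if (length(genes) < k) stop("fewer drivers than groups")
  f <- fate[, lineage]
  thr <- stats::quantile(f, quantile)
  cells <- rownames(fate)[f > thr]
  if (quantile == 0) cells <- rownames(fate)
  cells <- cells[order(tau[cells])]
  x <- expr[cells, genes, drop = FALSE]
  w <- max(11L, round(0.05 * length(cells)))
  sm <- apply(x, 2L, .rolling_mean, w = w)
  sm <- scale(sm)
  sm[is.na(sm)] <- 0
  peak <- apply(sm, 2L, which.max) / nrow(sm)
  if (method == "kmeans") {
    cluster <- if (length(genes) == k) {
      seq_len(k)                      # one driver per group
    } else {
      with_seed(seed, stats::kmeans(t(sm), centers = k, nstart = 10L,
                                    iter.max = 100L))$cluster
    }
    cl_peak <- tapply(peak, cluster, mean)
    lab <- c("start", "middle", "end")[rank(cl_peak)]
    group <- lab[cluster]
  } else {
    br <- stats::quantile(peak, seq(0, 1, length.out = k + 1L))
    group <- c("start", "middle", "end")[
      as.integer(cut(peak, unique(br), include.lowest = TRUE))]
  }
  list(groups = data.frame(gene = genes, stage_group = group,
                           peak_position = peak, stringsAsFactors = FALSE,
                           row.names = NULL),
       profiles = t(sm), cells = cells)
}

.rolling_mean <- function(x, w) {
  n <- length(x)
  half <- w %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(0L, seq_len(n) - half - 1L)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

#' Stage-resolved motif enrichment along a lineage
#'
#' Per stage group, the foreground is the set of peaks significantly
#' linked to that stage's driver genes and the background is all peaks
#' linked to any driver of the lineage; enrichment via
#' \code{\link{motif_enrichment}}.
#'
#' @param stage_groups data.frame from \code{\link{stage_profiles}}.
#' @param sig_links significant links (from \code{\link{filter_links}}).
#' @param hits \code{MotifHitMatrix}.
#' @return data.frame of per-stage motif enrichment rows (stage column
#'   added); stages with no linked peaks are skipped with a warning.
#' @export
stage_motif_enrichment <- function(stage_groups, sig_links, hits) {
  lineage_peaks <- unique(
    sig_links$peak_id[sig_links$gene_id %in% stage_groups$gene])
  if (!length(lineage_peaks)) {
    warning("no peaks linked to any driver")
    return(data.frame())
  }
  out <- lapply(c("start", "middle", "end"), function(st) {
    g <- stage_groups$gene[stage_groups$stage_group == st]
    fg <- unique(sig_links$peak_id[sig_links$gene_id %in% g])
    if (!length(fg)) {
      warning("no linked peaks for stage ", st)
      return(NULL)
    }
    cbind(stage = st,
          motif_enrichment(fg, hits, background = lineage_peaks))
  })
  do.call(rbind, out)
}
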