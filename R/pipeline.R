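#' Run the optimal-transport trajectory stage end to end
#'
#' Convenience orchestration: growth rates from the proliferation set, OT
#' couplings between adjacent stages in RNA PC space, global transition
#' matrix with a connectivity kernel for the last stage, macrostates and
#' fate probabilities, and diffusion pseudotime from a root cell in the
#' earliest stage (the cell with the highest proliferation score unless
#' given).
#'
#' @param dataset a filtered, normalized \code{MultiomeDataset} whose
#'   \code{cells$stage} column has the four stage labels in sorted order.
#' @param embedding an \code{EmbeddingModel} from
#'   \code{\link{reduce_dimensions}}.
#' @param prolif_genes proliferation gene set for growth rates.
#' @param n_macrostates,self_transition_min passed to
#'   \code{\link{fate_probabilities}}.
#' @param root optional root cell barcode for pseudotime.
#' @param k_last kNN for the last-stage kernel (and pseudotime).
#' @param lambda,eps_frac,growth_iters OT parameters (see
#'   \code{\link{ot_coupling}}).
#' @param seed integer seed.
#' @return list with growth, couplings, transition, fate_model, tau, root.
#' @export
run_trajectory <- function(dataset, embedding, prolif_genes,
                           n_macrostates = 6L, self_transition_min = 0.8,
                           root = NULL, k_last = 15L, lambda = 1,
                           eps_frac = 0.05, growth_iters = 3L, seed = 1L) {
  stages <- sort(unique(dataset$cells$stage))
  pcs <- embedding$pca
  by_stage <- lapply(stages, function(s) {
    dataset$cells$barcode[dataset$cells$stage == s]
  })
  g <- growth_rates(dataset, prolif_genes)
  couplings <- lapply(seq_len(length(stages) - 1L), function(i) {
    ot_coupling(pcs[by_stage[[i]], , drop = FALSE],
                pcs[by_stage[[i + 1L]], , drop = FALSE],
                g = g[by_stage[[i]]], lambda = lambda,
                eps_frac = eps_frac, growth_iters = growth_iters)
  })
  last_kernel <- connectivity_kernel(
    pcs[by_stage[[length(stages)]], , drop = FALSE], k = k_last)
  T_ <- transition_matrix(couplings, last_kernel)
  fm <- fate_probabilities(T_, n_macrostates = n_macrostates,
                           self_transition_min = self_transition_min,
                           seed = seed)
  if (is.null(root)) {
    first <- by_stage[[1L]]
    score <- rowMeans(dataset$layers$lognorm[first, prolif_genes,
                                             drop = FALSE])
    root <- first[which.max(score)]
  }
  ord <- match(rownames(T_), rownames(pcs))
  tau <- diffusion_pseudotime(pcs[ord, , drop = FALSE], root = root,
                              k = k_last)
  list(growth = g, couplings = couplings, transition = T_,
       fate_model = fm, tau = tau, root = root)
}

#' Set up the in silico perturbation stage on a two-lineage subsystem
#'
#' Mirrors the perturbation workflow: restrict to the cells of two
#' lineages plus their progenitors, recompute the expression embedding and
#' clustering on the subset, build the motif-prior GRN, estimate diffusion
#' pseudotime from an early root, and precompute the developmental flow,
#' lineage masks and the shift cache shared by every knockout.
#'
#' @param dataset a filtered, normalized \code{MultiomeDataset} (full).
#' @param cells barcodes of the subsystem (two lineages + progenitors).
#' @param links significant peak-gene links.
#' @param hits \code{MotifHitMatrix}.
#' @param motif_map data.frame motif_id, tf.
#' @param lineage_labels named per-cell lineage annotation (curated
#'   subtypes or fate-derived labels).
#' @param lineages the two lineage labels to score against.
#' @param root optional root barcode for pseudotime (default: subset cell
#'   with the lowest pseudotime potential, i.e. chosen by the caller or
#'   the first stage's highest-proliferation cell).
#' @param prolif_genes used to pick a default root.
#' @param k_cluster,resolution clustering knobs.
#' @param k_smooth neighbours for kNN imputation of the expression layer
#'   the GRN machinery operates on (see \code{\link{knn_smooth}}).
#' @param n_neighbors,sigma_corr,grid_n field parameters.
#' @param seed integer seed.
#' @return a \code{PerturbationContext} list: subset dataset, the smoothed
#'   expression layer \code{expr}, embedding2d, clusters, grn, tau, flow,
#'   masks (per lineage), cache and parameters.
#' @export
run_perturbation <- function(dataset, cells, links, hits, motif_map,
                             lineage_labels, lineages, root = NULL,
                             prolif_genes = NULL, k_cluster = 20L,
                             resolution = 1, k_smooth = 30L,
                             n_neighbors = 200L,
                             sigma_corr = 0.05, grid_n = 40L, seed = 1L) {
  stopifnot(length(lineages) == 2L)
  ds <- subset_cells(dataset, cells)
  emb <- reduce_dimensions(ds)
  clusters <- cluster_cells(emb$pca, k = k_cluster,
                            resolution = resolution, seed = seed)
  prom <- promoter_peaks(ds$genes, ds$peaks)
  cand <- base_grn(links, hits, motif_map, promoters = prom)
  expr <- knn_smooth(ds$layers$lognorm, emb$pca, k = k_smooth)
  grn <- fit_grn(expr, clusters, cand, seed = seed)
  if (is.null(root)) {
    if (is.null(prolif_genes)) stop("need root or prolif_genes")
    first <- ds$cells$barcode[ds$cells$stage == min(ds$cells$stage)]
    score <- rowMeans(ds$layers$lognorm[first, intersect(prolif_genes,
                                                         colnames(ds$rna)),
                                        drop = FALSE])
    root <- first[which.max(score)]
  }
  tau <- diffusion_pseudotime(emb$pca, root)
  e2d <- emb$pca[, 1:2]
  flow <- developmental_flow(e2d, tau, grid_n)
  masks <- lapply(lineages, function(l) {
    lineage_mask(e2d, lineage_labels, l, grid_n)
  })
  names(masks) <- lineages
  cache <- shift_cache(expr, e2d, n_neighbors = n_neighbors)
  structure(list(dataset = ds, expr = expr, embedding2d = e2d,
                 clusters = clusters, grn = grn, tau = tau, flow = flow,
                 masks = masks, cache = cache, n_neighbors = n_neighbors,
                 sigma_corr = sigma_corr, grid_n = grid_n, root = root),
            class = "PerturbationContext")
}

#' @rdname run_perturbation
#' @param ctx a \code{PerturbationContext}.
#' @param tf TF gene to knock out.
#' @param lineage which lineage mask to score on.
#' @param n_propagation propagation rounds.
#' @return \code{knockout_score}: the perturbation score (positive means
#'   development reversed on that lineage).
#' @export
knockout_score <- function(ctx, tf, lineage, n_propagation = 3L) {
  delta <- suppressWarnings(
    simulate_knockout(ctx$grn, ctx$expr, ctx$clusters, tf,
                      n_propagation = n_propagation))
  es <- embedding_shift(delta, ctx$expr, ctx$embedding2d,
                        n_neighbors = ctx$n_neighbors,
                        sigma_corr = ctx$sigma_corr, grid_n = ctx$grid_n,
                        cache = ctx$cache)
  perturbation_score(es$field, ctx$flow$flow, ctx$masks[[lineage]])$score
}

#' Majority terminal-branch label of each terminal macrostate
#'
#' Labels each terminal macrostate by the most frequent value of a
#' per-cell annotation (for example the planted branch in simulations, or
#' a curated subtype label) among its member cells.
#'
#' @param fate_model a \code{FateModel}.
#' @param labels named character vector of per-cell labels.
#' @return named character vector: terminal macrostate -> label.
#' @export
label_terminal_states <- function(fate_model, labels) {
  vapply(fate_model$terminal, function(m) {
    cells <- names(fate_model$macrostates)[fate_model$macrostates == m]
    lab <- labels[cells]
    names(sort(table(lab), decreasing = TRUE))[1]
  }, "", USE.NAMES = TRUE) -> out
  stats::setNames(out, fate_model$terminal)
}
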