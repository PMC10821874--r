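# GRN candidates and fits, knockout propagation, vector fields and
# perturbation scores.

test_that("GRN candidates require a motif hit in a linked or promoter peak", {
  hits <- Matrix::sparseMatrix(i = c(1, 3), j = c(1, 2), x = 1,
                               dims = c(3, 2),
                               dimnames = list(c("p1", "p2", "p3"),
                                               c("mA", "mB")))
  map <- data.frame(motif_id = c("mA", "mB"), tf = c("TFA", "TFB"),
                    stringsAsFactors = FALSE)
  links <- data.frame(gene_id = c("g1", "g2"), peak_id = c("p1", "p2"),
                      stringsAsFactors = FALSE)
  prom <- data.frame(gene_id = "g3", peak_id = "p3",
                     stringsAsFactors = FALSE)
  out <- base_grn(links, hits, map, promoters = prom)
  ## TFA hits p1 (linked to g1); TFB hits p3 (promoter of g3).
  ## p2 has no motif hit, so TFB -> g2 is absent.
  expect_setequal(paste(out$tf, out$target), c("TFA g1", "TFB g3"))
  ## a TF whose motif hits no linked peak has no outgoing candidates
  expect_false("TFB g2" %in% paste(out$tf, out$target))
  ## coaccessibility mode: a threshold above 1 yields nothing
  ca <- data.frame(peak1 = "p1", peak2 = "p3", coaccess = 0.9,
                   stringsAsFactors = FALSE)
  out2 <- base_grn(NULL, hits, map, promoters = prom, coaccess = ca,
                   coaccess_min = 1.01)
  expect_false(any(out2$peak_id == "p1" & out2$target == "g3"))
  out3 <- base_grn(NULL, hits, map, promoters = prom, coaccess = ca,
                   coaccess_min = 0.8)
  expect_true(any(out3$tf == "TFA" & out3$target == "g3"))
  expect_error(base_grn(links, hits, map[0, ]), "motif map")
})

test_that("bagged ridge recovers a planted linear dependence", {
  set.seed(31)
  n <- 200
  tfx <- rnorm(n, 2, 1)
  expr <- cbind(TF1 = tfx, target = 2 * tfx + rnorm(n, sd = 0.5),
                noise = rnorm(n))
  rownames(expr) <- paste0("c", 1:n)
  cand <- data.frame(tf = "TF1", target = c("target", "noise"),
                     stringsAsFactors = FALSE)
  grn <- fit_grn(expr, rep("cl1", n), cand, seed = 1)
  e <- grn$edges
  tgt <- e[e$target == "target", ]
  expect_equal(nrow(tgt), 1L)
  expect_gt(tgt$coef, 1.5)
  expect_lt(tgt$p, 0.001)
  ## permuted target: filtered out at p < 0.001 in most replicates
  hits <- vapply(1:20, function(r) {
    set.seed(100 + r)
    ex2 <- expr
    ex2[, "target"] <- sample(ex2[, "target"])
    g2 <- fit_grn(ex2, rep("cl1", n),
                  data.frame(tf = "TF1", target = "target"), seed = r)
    nrow(g2$edges) > 0
  }, TRUE)
  expect_lte(mean(hits), 0.05)
})

test_that("the edge cap keeps the largest coefficients", {
  set.seed(33)
  n <- 300
  tfx <- rnorm(n)
  targets <- sapply(1:10, function(i) (i / 2) * tfx + rnorm(n, sd = 0.3))
  colnames(targets) <- paste0("t", 1:10)
  expr <- cbind(TF1 = tfx, targets)
  rownames(expr) <- paste0("c", 1:n)
  cand <- data.frame(tf = "TF1", target = colnames(targets),
                     stringsAsFactors = FALSE)
  full <- fit_grn(expr, rep("cl1", n), cand, seed = 1)
  capped <- fit_grn(expr, rep("cl1", n), cand, max_edges = 4L, seed = 1)
  expect_equal(nrow(capped$edges), 4L)
  ord <- order(-abs(full$edges$coef))
  expect_setequal(capped$edges$target, full$edges$target[ord[1:4]])
  ## filter monotonicity: a looser p threshold never loses an edge
  strict <- fit_grn(expr, rep("cl1", n), cand, p_max = 1e-6, seed = 1)
  loose <- fit_grn(expr, rep("cl1", n), cand, p_max = 1e-2, seed = 1)
  expect_true(all(paste(strict$edges$tf, strict$edges$target) %in%
                    paste(loose$edges$tf, loose$edges$target)))
})

test_that("knockout propagation follows the linear hand calculation", {
  n <- 5
  expr <- cbind(TF1 = c(1, 2, 3, 4, 5), g = rep(10, n), h = rep(10, n))
  rownames(expr) <- paste0("c", 1:n)
  cl <- rep("cl1", n)
  grn <- structure(list(
    edges = data.frame(cluster = "cl1", tf = "TF1", target = "g",
                       coef = 0.5, p = 0, stringsAsFactors = FALSE),
    settings = list(p_max = 0.001, max_edges = 2000, n_bags = 20)),
    class = "GRNModel")
  d1 <- simulate_knockout(grn, expr, cl, "TF1", n_propagation = 1L)
  ## delta_g = coef * (-x_TF); h untouched; TF coordinate = -x_TF
  expect_equal(unname(d1[, "g"]), -0.5 * expr[, "TF1"], ignore_attr = TRUE)
  expect_equal(unname(d1[, "TF1"]), -expr[, "TF1"], ignore_attr = TRUE)
  expect_equal(unname(d1[, "h"]), rep(0, n))
  ## doubling coefficients doubles the first-order target shift
  grn2 <- grn; grn2$edges$coef <- 1
  d2 <- simulate_knockout(grn2, expr, cl, "TF1", n_propagation = 1L)
  expect_equal(d2[, "g"], 2 * d1[, "g"])
  ## KO gene shift is never positive
  expect_true(all(d1[, "TF1"] <= 0))
  ## clipping: shifts cannot push expression below zero
  grn3 <- grn; grn3$edges$coef <- 10
  d3 <- simulate_knockout(grn3, expr, cl, "TF1", n_propagation = 3L)
  expect_true(all(expr[, "g"] + d3[, "g"] >= -1e-9))
  ## a TF with no outgoing edges shifts only its own coordinate
  grn0 <- grn; grn0$edges <- grn$edges[0, ]
  expect_warning(d0 <- simulate_knockout(grn0, expr, cl, "TF1"), "edges")
  expect_equal(unname(d0[, "TF1"]), -expr[, "TF1"], ignore_attr = TRUE)
  expect_true(all(d0[, c("g", "h")] == 0))
  expect_error(simulate_knockout(grn, expr, cl, "nope"), "catalog")
})

test_that("embedding shifts behave at the limits", {
  set.seed(35)
  n <- 60
  emb <- cbind(runif(n), runif(n))
  rownames(emb) <- paste0("c", 1:n)
  expr <- matrix(rnorm(n * 20), n, 20,
                 dimnames = list(rownames(emb), paste0("g", 1:20)))
  ## zero delta: zero shift everywhere
  es0 <- embedding_shift(matrix(0, n, 20, dimnames = dimnames(expr)),
                         expr, emb, n_neighbors = 10L)
  expect_true(all(es0$shift == 0))
  ## delta equal to one neighbour's expression difference, tiny sigma:
  ## the shift points at that neighbour minus the local mean offset
  cache <- shift_cache(expr, emb, n_neighbors = 10L)
  j <- cache$nn[1, 4]
  delta <- matrix(0, n, 20, dimnames = dimnames(expr))
  delta[1, ] <- expr[j, ] - expr[1, ]
  es <- embedding_shift(delta, expr, emb, n_neighbors = 10L,
                        sigma_corr = 0.01, cache = cache)
  nbr_off <- sweep(emb[cache$nn[1, ], ], 2L, emb[1, ])
  expect_equal(es$shift[1, ], unname(emb[j, ] - emb[1, ] -
                                       colMeans(nbr_off)),
               tolerance = 1e-6)
  ## clipping warning when n_neighbors >= n_cells
  expect_warning(shift_cache(expr, emb, n_neighbors = n), "clipping")
})

test_that("developmental flow is the gradient of smoothed pseudotime", {
  set.seed(37)
  n <- 400
  emb <- cbind(runif(n, 0, 10), runif(n, 0, 10))
  rownames(emb) <- paste0("c", 1:n)
  tau <- stats::setNames(emb[, 1] / 10, rownames(emb))
  fl <- developmental_flow(emb, tau, grid_n = 15L)
  live <- fl$mask & abs(fl$flow[, 1]) > 1e-9
  ## pseudotime increasing along x: flow points in +x, tiny y component
  expect_true(all(fl$flow[live, 1] > 0))
  expect_gt(mean(abs(fl$flow[live, 1])), 10 * mean(abs(fl$flow[live, 2])))
  ## constant pseudotime: zero flow
  fl0 <- developmental_flow(emb, tau * 0 + 0.5, grid_n = 15L)
  expect_lt(max(abs(fl0$flow)), 1e-9)
})

test_that("perturbation scores follow the inner-product algebra", {
  flow <- cbind(c(1, 2, 0.5), c(-1, 0, 2))
  mask <- c(TRUE, TRUE, TRUE)
  ## shift exactly opposite to flow: score = sum |flow|^2
  sc <- perturbation_score(-flow, flow, mask)
  expect_equal(sc$score, sum(flow^2))
  ## orthogonal shift: zero score
  orth <- cbind(flow[, 2], -flow[, 1])
  expect_equal(perturbation_score(orth, flow, mask)$score, 0)
  expect_error(perturbation_score(flow, flow, c(FALSE, FALSE, FALSE)),
               "mask")
})

test_that("a zero-coefficient GRN produces zero scores", {
  set.seed(39)
  n <- 80
  emb <- cbind(runif(n), runif(n))
  rownames(emb) <- paste0("c", 1:n)
  expr <- matrix(abs(rnorm(n * 10)), n, 10,
                 dimnames = list(rownames(emb), paste0("g", 1:10)))
  tau <- stats::setNames(runif(n), rownames(emb))
  grn <- structure(list(
    edges = data.frame(cluster = "cl1", tf = "g1",
                       target = c("g2", "g3"), coef = 0, p = 0,
                       stringsAsFactors = FALSE),
    settings = list(p_max = 0.001, max_edges = 2000, n_bags = 20)),
    class = "GRNModel")
  delta <- simulate_knockout(grn, expr, rep("cl1", n), "g1")
  ## only the TF's own coordinate moves; with coef 0 no propagation
  expect_true(all(delta[, -1] == 0))
  grn$edges <- grn$edges[0, ]
  delta0 <- suppressWarnings(
    simulate_knockout(grn, expr, rep("cl1", n), "g2"))
  es <- embedding_shift(delta0 * 0, expr, emb, n_neighbors = 10L,
                        grid_n = 10L)
  fl <- developmental_flow(emb, tau, grid_n = 10L)
  sc <- perturbation_score(es$field, fl$flow, rep(TRUE, 100))
  expect_equal(sc$score, 0)
})
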