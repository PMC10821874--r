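# OT couplings, the layered transition matrix, random walks, absorption
# probabilities, diffusion pseudotime, drivers and stage profiles.

test_that("growth rates respond to the proliferation program", {
  d <- small_norm()
  prolif <- small_sim()$program$prolif_genes
  g <- growth_rates(d, prolif)
  ## multipotent cells grow faster than committed ones (planted truth)
  st <- small_sim()$states
  mp <- intersect(st$barcode[st$branch == "multipotent"], names(g))
  br <- intersect(st$barcode[st$branch != "multipotent"], names(g))
  expect_gt(mean(g[mp]), mean(g[br]))
  ## uniform expression: g identically 1
  d2 <- d
  d2$layers$lognorm[, prolif] <- 1
  expect_equal(unname(growth_rates(d2, prolif)), rep(1, nrow(d2$rna)))
  ## raising one cell's proliferation genes raises its growth
  d3 <- d
  d3$layers$lognorm[5, prolif] <- d3$layers$lognorm[5, prolif] + 1
  expect_gt(growth_rates(d3, prolif)[5], g[5])
  expect_error(growth_rates(d, "no_such_gene"), "disjoint")
})

test_that("zero-cost balanced coupling is uniform", {
  src <- matrix(0, 2, 2, dimnames = list(c("s1", "s2"), NULL))
  tgt <- matrix(0, 2, 2, dimnames = list(c("t1", "t2"), NULL))
  gam <- ot_coupling(src, tgt, eps = 0.1, lambda = Inf, growth_iters = 1L)
  expect_equal(unname(as.matrix(gam)), matrix(0.25, 2, 2),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("Sinkhorn approaches the exact LP plan for small epsilon", {
  set.seed(3)
  src <- matrix(rnorm(6), 3, 2)
  tgt <- matrix(rnorm(6) + 1, 3, 2)
  rownames(src) <- paste0("s", 1:3); rownames(tgt) <- paste0("t", 1:3)
  C <- outer(rowSums(src^2), rowSums(tgt^2), "+") - 2 * src %*% t(tgt)
  a <- rep(1 / 3, 3); b <- rep(1 / 3, 3)
  exact <- lp_transport(a, b, C)
  gam <- ot_coupling(src, tgt, eps = 0.002 * mean(C), lambda = Inf,
                     growth_iters = 1L, max_iter = 100000L, tol = 1e-6)
  expect_lt(abs(sum(gam * C) - exact$cost) / abs(exact$cost), 1e-3)
  expect_lt(max(abs(gam - exact$plan)), 0.01)
})

test_that("growth rates tilt the transported source mass", {
  set.seed(4)
  src <- matrix(rnorm(8, sd = 0.1), 4, 2)
  tgt <- matrix(rnorm(8, sd = 0.1), 4, 2)
  rownames(src) <- paste0("s", 1:4); rownames(tgt) <- paste0("t", 1:4)
  g <- c(2, 1, 1, 1)
  gam <- ot_coupling(src, tgt, g = g, eps = 0.5, lambda = 50,
                     growth_iters = 1L)
  rs <- rowSums(gam)
  expect_equal(unname(rs[1] / mean(rs[2:4])), 2, tolerance = 0.15)
})

test_that("transition matrix assembles couplings row-stochastically", {
  gam1 <- matrix(c(1, 1, 2, 0), 2, 2,
                 dimnames = list(c("a1", "a2"), c("b1", "b2")))
  gam2 <- matrix(c(1, 3, 1, 1), 2, 2,
                 dimnames = list(c("b1", "b2"), c("c1", "c2")))
  kern <- matrix(c(0, 2, 2, 0), 2, 2,
                 dimnames = list(c("c1", "c2"), c("c1", "c2")))
  T_ <- transition_matrix(list(gam1, gam2), kern)
  expect_equal(unname(rowSums(T_)), rep(1, 6))
  ## hand assembly of one row: a1 -> (b1, b2) = (1, 2) / 3
  expect_equal(unname(T_["a1", c("b1", "b2")]), c(1 / 3, 2 / 3))
  expect_equal(unname(T_["b2", c("c1", "c2")]), c(3 / 4, 1 / 4))
  ## last-stage rows have support only within the last stage
  expect_equal(unname(T_["c1", ]), c(0, 0, 0, 0, 0, 1))
  ## mismatched stage cells error
  bad <- gam2; colnames(bad) <- c("x1", "x2")
  expect_error(transition_matrix(list(gam1, bad), kern), "match")
})

test_that("random walks reproduce analytic endpoint frequencies", {
  ## absorbing 3-state chain: C -> A w.p. 0.3, C -> B w.p. 0.7
  T_ <- rbind(A = c(1, 0, 0), B = c(0, 1, 0), C = c(0.3, 0.7, 0))
  colnames(T_) <- rownames(T_)
  rw <- random_walks(T_, start = 3L, n_sims = 10000L, n_steps = 5L,
                     seed = 5)
  expect_equal(mean(rw$endpoints == 1L), 0.3, tolerance = 0.015)
  ## identity transition: endpoints equal starts
  rw2 <- random_walks(diag(3), start = c(1L, 2L, 3L), n_sims = 9L,
                      n_steps = 3L, seed = 1)
  expect_equal(rw2$endpoints, rep_len(c(1L, 2L, 3L), 9L))
  ## determinism
  expect_identical(rw$paths,
                   random_walks(T_, 3L, 10000L, 5L, seed = 5)$paths)
  expect_error(random_walks(T_, 3L, 10L, 0L), "n_steps")
})

test_that("absorption probabilities match the one-step chain exactly", {
  T_ <- rbind(A = c(1, 0, 0), B = c(0, 1, 0), C = c(0.3, 0.7, 0))
  colnames(T_) <- rownames(T_)
  f <- absorption_probabilities(T_, list(stateA = 1L, stateB = 2L))
  expect_equal(unname(f["C", ]), c(0.3, 0.7))
  expect_equal(unname(f["A", ]), c(1, 0))
})

test_that("absorption matches Monte-Carlo endpoints on a random chain", {
  set.seed(8)
  n <- 30
  T_ <- matrix(runif(n * n), n, n)
  ## make states 1..4 absorbing
  T_[1:4, ] <- 0; T_[cbind(1:4, 1:4)] <- 1
  T_ <- T_ / rowSums(T_)
  rownames(T_) <- colnames(T_) <- paste0("s", 1:n)
  terminal <- list(t1 = 1L, t2 = 2L, t3 = 3L, t4 = 4L)
  f <- absorption_probabilities(T_, terminal)
  rw <- random_walks(T_, start = 10L, n_sims = 100000L, n_steps = 60L,
                     seed = 9)
  for (k in 1:4) {
    phat <- mean(rw$endpoints == k)
    se <- sqrt(phat * (1 - phat) / 100000)
    expect_lt(abs(f["s10", k] - phat), 3 * se + 1e-6)
  }
  expect_equal(unname(rowSums(f)), rep(1, n), tolerance = 1e-8)
})

test_that("pseudotime increases along a path graph and is 0 at the root", {
  ## ten cells along a line
  emb <- cbind(seq(0, 9), 0)
  rownames(emb) <- paste0("c", 1:10)
  tau <- diffusion_pseudotime(emb, root = 1L, k = 2L, n_comps = 5L)
  expect_equal(unname(tau["c1"]), 0)
  expect_true(all(diff(tau) > 0))
  ## disconnected graphs are an error naming the components
  emb2 <- rbind(emb, cbind(seq(1000, 1009), 0))
  rownames(emb2) <- paste0("c", 1:20)
  expect_error(diffusion_pseudotime(emb2, 1L, k = 2L), "disconnected")
})

test_that("driver genes follow the correlation and threshold rules", {
  set.seed(10)
  n <- 200
  f <- cbind(lin = runif(n), other = runif(n))
  f <- f / rowSums(f)
  rownames(f) <- paste0("c", 1:n)
  expr <- cbind(affine = 2 * f[, "lin"] + 1,
                weak = 0.04 * scale(f[, "lin"])[, 1] + rnorm(n),
                noise = rnorm(n), constant = rep(1, n))
  rownames(expr) <- rownames(f)
  dr <- driver_genes(expr, f, "lin")
  expect_equal(dr$rho[dr$gene == "affine"], 1, tolerance = 1e-9)
  expect_true(dr$driver[dr$gene == "affine"])
  expect_false("constant" %in% dr$gene)   # skipped
  ## below the correlation floor: never a driver no matter the p
  weak_rho <- dr$rho[dr$gene == "weak"]
  if (weak_rho <= 0.05) expect_false(dr$driver[dr$gene == "weak"])
  dr2 <- driver_genes(cbind(x = 0.04 * f[, "lin"] * 25 + 0.00001 *
                              seq_len(n)), f, "lin")
  ## construct exact rho = 0.04 case via direct check of the rule
  expect_true(all(dr$driver == (dr$rho > 0.05 & dr$padj < 0.05)))
})

test_that("stage profiles group constructed drivers by peak position", {
  set.seed(12)
  n <- 300
  tau <- sort(runif(n))
  names(tau) <- paste0("c", 1:n)
  f <- cbind(lin = rep(0.9, n), other = rep(0.1, n))
  rownames(f) <- names(tau)
  bump <- function(mu) exp(-((tau - mu) / 0.12)^2)
  expr <- sapply(c(d1 = 0.1, d2 = 0.5, d3 = 0.9),
                 function(mu) bump(mu) + rnorm(n, sd = 0.05))
  rownames(expr) <- names(tau)
  drivers <- data.frame(gene = colnames(expr), rho = 0.5, p = 0,
                        padj = 0, driver = TRUE, stringsAsFactors = FALSE)
  sp <- stage_profiles(expr, drivers, tau, f, "lin", quantile = 0,
                       seed = 1)
  expect_equal(length(sp$cells), n)   # quantile 0 extracts every cell
  got <- stats::setNames(sp$groups$stage_group, sp$groups$gene)
  expect_equal(unname(got[c("d1", "d2", "d3")]),
               c("start", "middle", "end"))
  ## deterministic under the seed
  sp2 <- stage_profiles(expr, drivers, tau, f, "lin", quantile = 0,
                        seed = 1)
  expect_identical(sp$groups, sp2$groups)
  ## quantile-cut fallback gives one gene per tertile here
  spq <- stage_profiles(expr, drivers, tau, f, "lin", quantile = 0,
                        method = "quantile")
  expect_equal(unname(stats::setNames(spq$groups$stage_group,
                                      spq$groups$gene)[c("d1", "d2", "d3")]),
               c("start", "middle", "end"))
  expect_error(stage_profiles(expr, drivers[1:2, ], tau, f, "lin"),
               "fewer")
})

test_that("stage grouping and enrichment track the planted phase programs", {
  p <- acceptance_pipeline()
  labs <- p$terminal_labels
  fate <- p$trajectory$fate_model$fate
  lin <- names(labs)[labs == "branch1"][1]
  dr <- driver_genes(p$dataset$layers$lognorm, fate, lin)
  ## quantile grouping resolves the plateau-shaped phase programs
  sp <- stage_profiles(p$dataset$layers$lognorm, dr, p$trajectory$tau,
                       fate, lin, method = "quantile", seed = 1)
  pg <- p$sim$program$genes
  ph <- pg$phase[match(sp$groups$gene, pg$gene_id)]
  tab <- table(sp$groups$stage_group, ph)
  expect_equal(unname(tab["start", "start"]), 4L)
  expect_equal(unname(tab["start", "end"]), 0L)
  expect_equal(unname(tab["end", "start"]), 0L)
  ## the early TF's motif is most enriched in the start stage: its fold
  ## change there tops every other stage and every other planted motif
  en <- stage_motif_enrichment(sp$groups, p$sig$links, p$hits)
  mm <- p$sim$program$motif_map
  m_early <- mm$motif_id[mm$tf == "Tf1.1"]
  row <- en[en$stage == "start" & en$motif == m_early, ]
  expect_gt(row$fold_change, 1.5)
  expect_lt(row$p, 0.05)
  expect_gt(row$fold_change,
            max(en$fold_change[en$motif == m_early & en$stage != "start"]))
})

test_that("stage motif enrichment uses lineage-linked peaks as background", {
  hits <- Matrix::sparseMatrix(i = 1:4, j = rep(1, 4), x = 1,
                               dims = c(10, 1),
                               dimnames = list(paste0("p", 1:10), "m"))
  links <- data.frame(gene_id = c("a", "a", "b", "c"),
                      peak_id = c("p1", "p2", "p3", "p9"),
                      stringsAsFactors = FALSE)
  groups <- data.frame(gene = c("a", "b", "c"),
                       stage_group = c("start", "middle", "end"),
                       stringsAsFactors = FALSE)
  out <- stage_motif_enrichment(groups, links, hits)
  expect_setequal(unique(out$stage), c("start", "middle", "end"))
  ## foreground == background when one stage owns all linked peaks
  groups2 <- data.frame(gene = "a", stage_group = "start",
                        stringsAsFactors = FALSE)
  out2 <- suppressWarnings(stage_motif_enrichment(groups2, links, hits))
  expect_equal(out2$fold_change[out2$stage == "start"], 1)
  ## empty driver set
  expect_warning(out0 <- stage_motif_enrichment(groups[0, ], links, hits),
                 "no peaks")
  expect_equal(nrow(out0), 0L)
})
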