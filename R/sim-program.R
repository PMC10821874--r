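#' Simulation parameters for the synthetic multiome generator
#'
#' Defaults describe the study conditions the generator emulates: four
#' sampling stages spanning a latent developmental time s in [0,1], a
#' branching lineage field with five terminal branches and two
#' lineage-determining TFs per branch, enhancer-to-gene links with a strong
#' planted effect size, motif occurrences embedded in enhancer sequences,
#' elevated growth of multipotent cells, negative-binomial RNA counts and
#' sparse near-binary ATAC counts. Sizes default to 1,000 genes, 3,000 peaks
#' and 500 cells per stage.
#'
#' @param n_genes total genes (>= 50); includes TF, target, proliferation,
#'   housekeeping and mitochondrial genes.
#' @param n_peaks total peaks (>= n_genes): one promoter per gene, enhancers
#'   for target genes, the remainder background peaks.
#' @param n_branches number of terminal branches B (>= 2).
#' @param tfs_per_branch lineage TFs per branch.
#' @param targets_per_tf target genes regulated by each lineage TF.
#' @param enhancers_per_target enhancer peaks per target gene.
#' @param n_mito mitochondrial genes, placed on contig "chrM".
#' @param n_prolif genes in the proliferation program (decline with s).
#' @param n_matur genes in the global maturation program (rise with s);
#'   together with the proliferation set these encode latent time the way
#'   broad developmental programs do in real tissue.
#' @param n_decoy_motifs extra PWMs mapped to housekeeping genes, never
#'   planted; they exercise motif-enrichment null behaviour.
#' @param link_weight planted enhancer->gene effect size; the documented
#'   "strong" setting is the default 3. Zero gives a null dataset.
#' @param nb_theta negative-binomial dispersion of RNA counts.
#' @param branch_point latent time at which the lineage field branches.
#' @param stage_windows 4 x 2 matrix of latent-time windows per sampling
#'   stage; windows cover [0,1] with configured overlap.
#' @param branch_weights branch probabilities at the branch point.
#' @param branch_growth per-branch growth multipliers.
#' @param junk_frac fraction of junk barcodes appended (violating QC).
#' @param cells_per_stage default stage sizes used by convenience wrappers.
#' @param ... further knobs: genome layout (contig_length, genes_per_contig,
#'   gene_slot, peak_width), count model (rna_baseline_meanlog/sdlog,
#'   depth_sdlog, atac_scale, atac_max_count), activity shapes (tf_amplitude,
#'   prolif_amplitude, enhancer_slope, bump_width, phase_centers), fragment
#'   length mixture (frag_sub_frac, frag_sub_mean, frag_sub_sd,
#'   frag_mono_mean, frag_mono_sd), motif_length.
#'
#' @return a validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 1000L, n_peaks = 3000L, n_branches = 5L,
                       tfs_per_branch = 2L, targets_per_tf = 8L,
                       enhancers_per_target = 2L, n_mito = 10L,
                       n_prolif = 40L, n_matur = 40L, n_decoy_motifs = 6L,
                       link_weight = 5, nb_theta = 10,
                       branch_point = 0.3,
                       stage_windows = rbind(c(0, 0.3), c(0.2, 0.55),
                                             c(0.45, 0.8), c(0.7, 1)),
                       branch_weights = NULL,
                       branch_growth = NULL,
                       junk_frac = 0.1,
                       cells_per_stage = c(500L, 500L, 500L, 500L),
                       ...) {
  extra <- list(...)
  defaults <- list(
    genes_per_contig = 10L, gene_slot = 6000L, contig_length = 80000L,
    chrM_length = 30000L, peak_width = 500L,
    rna_baseline_meanlog = log(0.8), rna_baseline_sdlog = 0.6,
    depth_sdlog = 0.3, atac_scale = 0.5, atac_max_count = 5L,
    tf_amplitude = 2, prolif_amplitude = 3, matur_amplitude = 3,
    enhancer_slope = 6,
    enhancer_floor = 0.15, enhancer_span = 0.8, enhancer_atac_scale = 1.5,
    target_baseline_meanlog = log(1.5), target_baseline_sdlog = 0.3,
    bump_width = 0.22, bump_floor = 0.5,
    phase_centers = c(start = 0.5, middle = 0.7, end = 0.9),
    frag_sub_frac = 0.7, frag_sub_mean = 80, frag_sub_sd = 10,
    frag_mono_mean = 200, frag_mono_sd = 20, motif_length = 8L
  )
  unknown <- setdiff(names(extra), names(defaults))
  if (length(unknown)) stop("unknown sim_config option(s): ",
                            paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, extra)
  cfg <- c(list(
    n_genes = as.integer(n_genes), n_peaks = as.integer(n_peaks),
    n_branches = as.integer(n_branches),
    tfs_per_branch = as.integer(tfs_per_branch),
    targets_per_tf = as.integer(targets_per_tf),
    enhancers_per_target = as.integer(enhancers_per_target),
    n_mito = as.integer(n_mito), n_prolif = as.integer(n_prolif),
    n_matur = as.integer(n_matur),
    n_decoy_motifs = as.integer(n_decoy_motifs),
    link_weight = link_weight, nb_theta = nb_theta,
    branch_point = branch_point, stage_windows = stage_windows,
    junk_frac = junk_frac, cells_per_stage = as.integer(cells_per_stage)
  ), cfg)

  if (cfg$n_branches < 2L) stop("need at least 2 branches (B >= 2)")
  if (cfg$n_genes < 50L) stop("need at least 50 genes")
  if (cfg$n_peaks < cfg$n_genes) stop("need at least as many peaks as genes")
  if (cfg$nb_theta <= 0) stop("NB dispersion theta must be positive")
  if (nrow(cfg$stage_windows) != 4L) stop("exactly 4 sampling stages required")
  n_tf <- cfg$n_branches * cfg$tfs_per_branch
  n_targets <- n_tf * cfg$targets_per_tf
  n_special <- n_tf + n_targets + cfg$n_prolif + cfg$n_matur + cfg$n_mito
  if (n_special + 10L > cfg$n_genes) {
    stop("n_genes too small for the configured TF/target/proliferation sets")
  }
  cfg$branch_weights <- branch_weights %||% rep(1 / cfg$n_branches,
                                                cfg$n_branches)
  if (length(cfg$branch_weights) != cfg$n_branches ||
      any(cfg$branch_weights <= 0)) {
    stop("branch_weights must be positive, one per branch")
  }
  cfg$branch_weights <- cfg$branch_weights / sum(cfg$branch_weights)
  cfg$branch_growth <- branch_growth %||%
    rep_len(c(1, 1.1, 0.9, 1.05, 0.95), cfg$n_branches)
  class(cfg) <- "sim_config"
  cfg
}

## Placement geometry shared by program construction and validation.
## Genes sit in fixed slots; enhancers flank the TSS at +/- ~2.6 kb so that
## adjacent slots never collide; background peaks occupy a reserved region.
.sim_geometry <- function(cfg) {
  list(
    tss0 = 4000L, enh_off = c(-2900L, 2400L), body_len = 1500L,
    prom_half = 250L, bg0 = cfg$genes_per_contig * cfg$gene_slot + 2500L,
    bg_slot = 700L
  )
}

#' Build a regulatory program with planted structure
#'
#' Lays out the gene and peak catalog on a small synthetic genome, plants
#' enhancer->gene links for every lineage-TF target, generates one PWM per
#' lineage TF (plus unplanted decoys) and embeds each TF's consensus in its
#' targets' enhancer sequences. Emits a genome in which every peak interval
#' exists, with GC content varying across peaks so GC-matched background
#' sampling is non-degenerate.
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed integer seed; identical (config, seed) give byte-identical
#'   programs.
#' @return an object of class \code{RegulatoryProgram}.
#' @export
build_regulatory_program <- function(config = sim_config(), seed = 1L) {
  cfg <- config
  stopifnot(inherits(cfg, "sim_config"))
  stopifnot_scalar_int(seed, "seed")
  geo <- .sim_geometry(cfg)
  with_seed(seed, {
    B <- cfg$n_branches
    n_tf <- B * cfg$tfs_per_branch
    n_targets <- n_tf * cfg$targets_per_tf
    n_auto <- cfg$n_genes - cfg$n_mito
    n_contigs <- ceiling(n_auto / cfg$genes_per_contig)
    contig_names <- paste0("chr", seq_len(n_contigs))
    contigs <- stats::setNames(rep(cfg$contig_length, n_contigs), contig_names)
    contigs["chrM"] <- cfg$chrM_length

    ## ---- gene catalog -------------------------------------------------
    phases <- names(cfg$phase_centers)
    genes <- list()
    k <- 0L
    for (b in seq_len(B)) {
      for (tfi in seq_len(cfg$tfs_per_branch)) {
        k <- k + 1L
        genes[[k]] <- data.frame(
          gene_id = sprintf("Tf%d.%d", b, tfi), type = "tf", branch = b,
          tf = NA_character_, phase = NA_character_, tf_index = tfi,
          stringsAsFactors = FALSE)
      }
    }
    for (b in seq_len(B)) {
      for (tfi in seq_len(cfg$tfs_per_branch)) {
        tf_id <- sprintf("Tf%d.%d", b, tfi)
        for (tg in seq_len(cfg$targets_per_tf)) {
          k <- k + 1L
          ## early TF drives start/middle targets, late TF middle/end
          ph <- if (cfg$tfs_per_branch == 1L) {
            phases[1L + (tg - 1L) %% length(phases)]
          } else if (tfi == 1L) {
            if (tg <= ceiling(cfg$targets_per_tf / 2)) "start" else "middle"
          } else {
            if (tg <= floor(cfg$targets_per_tf / 2)) "middle" else "end"
          }
          genes[[k]] <- data.frame(
            gene_id = sprintf("Tg%d.%d.%d", b, tfi, tg), type = "target",
            branch = b, tf = tf_id, phase = ph, tf_index = tfi,
            stringsAsFactors = FALSE)
        }
      }
    }
    branch_genes <- do.call(rbind, genes)
    ## interleave: the g-th gene of every branch goes on contig g, so no two
    ## co-regulated (same-branch) genes share a contig and candidate windows
    per_branch <- split(branch_genes, branch_genes$branch)
    max_per <- max(vapply(per_branch, nrow, 1L))
    if (max_per > n_contigs) stop("too few contigs to separate branch genes")
    if (B > cfg$genes_per_contig) {
      stop("genes_per_contig too small to interleave branches")
    }
    ord <- order(unlist(lapply(per_branch, function(d) seq_len(nrow(d)))))
    branch_genes <- do.call(rbind, per_branch)[ord, , drop = FALSE]
    branch_genes$contig <- contig_names[
      rep(seq_len(max_per), each = B)[seq_len(nrow(branch_genes))]]

    ## proliferation genes carry only promoter peaks (no enhancers track
    ## them), so they may share contigs; prefer contigs without target
    ## genes so no enhancer lies in their candidate window
    n_prolif <- cfg$n_prolif
    used <- as.integer(table(factor(branch_genes$contig,
                                    levels = contig_names)))
    has_target <- contig_names %in%
      branch_genes$contig[branch_genes$type == "target"]
    free <- rep(cfg$genes_per_contig, n_contigs) - used
    ord <- order(has_target, used, seq_len(n_contigs))
    slots <- rep(contig_names[ord], free[ord])
    if (length(slots) < n_prolif) stop("contig capacity exceeded")
    prolif <- data.frame(
      gene_id = sprintf("Prolif%d", seq_len(n_prolif)), type = "prolif",
      branch = NA_integer_, tf = NA_character_, phase = NA_character_,
      tf_index = NA_integer_, contig = slots[seq_len(n_prolif)],
      stringsAsFactors = FALSE)
    n_matur <- cfg$n_matur
    matur <- data.frame(
      gene_id = sprintf("Matur%d", seq_len(n_matur)), type = "matur",
      branch = NA_integer_, tf = NA_character_, phase = NA_character_,
      tf_index = NA_integer_, contig = slots[n_prolif + seq_len(n_matur)],
      stringsAsFactors = FALSE)

    n_hk <- n_auto - nrow(branch_genes) - n_prolif - n_matur
    hk_contigs <- slots[n_prolif + n_matur + seq_len(n_hk)]
    if (anyNA(hk_contigs) || length(hk_contigs) < n_hk) {
      stop("contig capacity exceeded")
    }
    hk <- data.frame(
      gene_id = sprintf("Hk%d", seq_len(n_hk)), type = "hk",
      branch = NA_integer_, tf = NA_character_, phase = NA_character_,
      tf_index = NA_integer_, contig = hk_contigs, stringsAsFactors = FALSE)
    mito <- data.frame(
      gene_id = sprintf("mt-Gene%d", seq_len(cfg$n_mito)), type = "mito",
      branch = NA_integer_, tf = NA_character_, phase = NA_character_,
      tf_index = NA_integer_, contig = "chrM", stringsAsFactors = FALSE)

    cat_genes <- rbind(branch_genes, prolif, matur, hk, mito)
    ## slot index within contig, in catalog order
    slot <- stats::ave(seq_len(nrow(cat_genes)), cat_genes$contig,
                       FUN = seq_along) - 1L
    is_m <- cat_genes$contig == "chrM"
    tss <- ifelse(is_m, 2000L + slot * 2500L, geo$tss0 + slot * cfg$gene_slot)
    strand <- ifelse(seq_len(nrow(cat_genes)) %% 2L == 0L, "-", "+")
    body_len <- ifelse(is_m, 800L, geo$body_len)
    cat_genes$strand <- strand
    cat_genes$tss <- as.integer(tss)
    cat_genes$body_start <- as.integer(ifelse(strand == "+", tss,
                                              tss - body_len))
    cat_genes$body_end <- as.integer(ifelse(strand == "+", tss + body_len,
                                            tss))
    cat_genes$baseline <- stats::rlnorm(nrow(cat_genes),
                                        cfg$rna_baseline_meanlog,
                                        cfg$rna_baseline_sdlog)
    ## lineage TFs and their targets are well-expressed markers
    lineage <- cat_genes$type %in% c("tf", "target")
    cat_genes$baseline[lineage] <- stats::rlnorm(sum(lineage),
                                                 cfg$target_baseline_meanlog,
                                                 cfg$target_baseline_sdlog)
    rownames(cat_genes) <- NULL
    if (any(cat_genes$tss + 3000L > contigs[cat_genes$contig]) ||
        any(cat_genes$tss - 3000L < 0L & !is_m)) {
      stop("gene/peak placement exceeds contig bounds; ",
           "increase contig_length or reduce genes_per_contig")
    }

    ## ---- peak catalog -------------------------------------------------
    pw <- cfg$peak_width
    prom <- data.frame(
      contig = cat_genes$contig,
      start = cat_genes$tss - geo$prom_half,
      end = cat_genes$tss - geo$prom_half + pw,
      role = "promoter", gene = cat_genes$gene_id, stringsAsFactors = FALSE)
    tgt <- cat_genes[cat_genes$type == "target", , drop = FALSE]
    E <- cfg$enhancers_per_target
    if (E > length(geo$enh_off)) stop("at most 2 enhancers per target supported")
    enh <- do.call(rbind, lapply(seq_len(E), function(e) {
      data.frame(contig = tgt$contig, start = tgt$tss + geo$enh_off[e],
                 end = tgt$tss + geo$enh_off[e] + pw, role = "enhancer",
                 gene = tgt$gene_id, stringsAsFactors = FALSE)
    }))
    n_bg <- cfg$n_peaks - nrow(prom) - nrow(enh)
    if (n_bg < 0L) stop("n_peaks too small for promoters plus enhancers")
    bg_cap <- floor((cfg$contig_length - geo$bg0 - pw) / geo$bg_slot)
    if (n_bg > bg_cap * n_contigs) {
      stop("background peaks cannot be placed without exceeding contig bounds")
    }
    bg_contig <- rep(contig_names, length.out = n_bg)
    bg_rank <- stats::ave(seq_len(n_bg), bg_contig, FUN = seq_along) - 1L
    bg <- data.frame(contig = bg_contig,
                     start = geo$bg0 + bg_rank * geo$bg_slot,
                     end = geo$bg0 + bg_rank * geo$bg_slot + pw,
                     role = "background", gene = NA_character_,
                     stringsAsFactors = FALSE)
    peaks <- rbind(prom, enh, bg)
    peaks$start <- as.integer(peaks$start)
    peaks$end <- as.integer(peaks$end)
    peaks$peak_id <- make_peak_ids(peaks$contig, peaks$start, peaks$end)
    peaks$gc_target <- stats::runif(nrow(peaks), 0.25, 0.75)
    peaks <- peaks[, c("peak_id", "contig", "start", "end", "role", "gene",
                       "gc_target")]
    rownames(peaks) <- NULL
    if (any(peaks$end > contigs[peaks$contig]) || any(peaks$start < 0L)) {
      stop("peaks cannot be placed without exceeding contig bounds")
    }

    links <- data.frame(
      peak_id = peaks$peak_id[peaks$role == "enhancer"],
      gene_id = peaks$gene[peaks$role == "enhancer"],
      weight = cfg$link_weight, stringsAsFactors = FALSE)

    ## ---- motifs -------------------------------------------------------
    tf_ids <- cat_genes$gene_id[cat_genes$type == "tf"]
    decoys <- utils::head(cat_genes$gene_id[cat_genes$type == "hk"],
                          cfg$n_decoy_motifs)
    motif_tfs <- c(tf_ids, decoys)
    L <- cfg$motif_length
    consensus <- character(0)
    taken <- character(0)
    for (i in seq_along(motif_tfs)) {
      repeat {
        cs <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                    collapse = "")
        rc <- .revcomp_string(cs)
        if (!(cs %in% taken) && !(rc %in% taken)) break
      }
      consensus[i] <- cs
      taken <- c(taken, cs, rc)
    }
    motifs <- lapply(seq_along(motif_tfs), function(i) {
      m <- matrix(5L, 4L, L, dimnames = list(c("A", "C", "G", "T"), NULL))
      idx <- match(strsplit(consensus[i], "")[[1]], rownames(m))
      m[cbind(idx, seq_len(L))] <- 85L
      m
    })
    motif_ids <- sprintf("SY%04d.1", seq_along(motif_tfs))
    names(motifs) <- motif_ids
    motif_map <- data.frame(motif_id = motif_ids, tf = motif_tfs,
                            consensus = consensus,
                            planted = motif_tfs %in% tf_ids,
                            stringsAsFactors = FALSE)

    ## ---- genome -------------------------------------------------------
    genome <- .build_genome(contigs, peaks, motif_map, cat_genes, cfg)

    program <- structure(list(
      config = cfg, genes = cat_genes, peaks = peaks, links = links,
      motifs = motifs, motif_map = motif_map,
      prolif_genes = prolif$gene_id,
      branch_point = cfg$branch_point,
      branch_weights = cfg$branch_weights,
      branch_growth = cfg$branch_growth,
      contigs = contigs, genome = genome
    ), class = "RegulatoryProgram")
    .validate_program(program)
    program
  })
}

.revcomp_string <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

## genome with baseline GC 0.4, peak intervals rewritten at their GC target,
## and each lineage TF's consensus planted once per target enhancer
.build_genome <- function(contigs, peaks, motif_map, genes, cfg) {
  base <- c("A", "C", "G", "T")
  seqs <- lapply(names(contigs), function(cn) {
    len <- contigs[[cn]]
    s <- sample(base, len, replace = TRUE, prob = c(0.3, 0.2, 0.2, 0.3))
    pk <- peaks[peaks$contig == cn, , drop = FALSE]
    for (i in seq_len(nrow(pk))) {
      gc <- pk$gc_target[i]
      w <- pk$end[i] - pk$start[i]
      s[(pk$start[i] + 1L):pk$end[i]] <-
        sample(base, w, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    }
    s
  })
  names(seqs) <- names(contigs)
  planted <- motif_map[motif_map$planted, , drop = FALSE]
  enh <- peaks[peaks$role == "enhancer", , drop = FALSE]
  tf_of_gene <- stats::setNames(genes$tf, genes$gene_id)
  for (i in seq_len(nrow(enh))) {
    tf <- tf_of_gene[[enh$gene[i]]]
    row <- planted[planted$tf == tf, , drop = FALSE]
    if (!nrow(row)) next
    cs <- strsplit(row$consensus[1], "")[[1]]
    w <- enh$end[i] - enh$start[i]
    off <- sample.int(w - length(cs) + 1L, 1L) - 1L
    pos <- enh$start[i] + off
    seqs[[enh$contig[i]]][(pos + 1L):(pos + length(cs))] <- cs
  }
  Biostrings::DNAStringSet(vapply(seqs, paste, "", collapse = ""))
}

.validate_program <- function(p) {
  cfg <- p$config
  win <- 5e5
  tss <- stats::setNames(p$genes$tss, p$genes$gene_id)
  gcontig <- stats::setNames(p$genes$contig, p$genes$gene_id)
  pk <- p$peaks[match(p$links$peak_id, p$peaks$peak_id), ]
  mid <- (pk$start + pk$end) / 2
  if (any(pk$contig != gcontig[p$links$gene_id]) ||
      any(abs(mid - tss[p$links$gene_id]) > win)) {
    stop("planted link outside the linkage window of its gene")
  }
  if (any(p$peaks$end > p$contigs[p$peaks$contig])) {
    stop("peak beyond contig bounds")
  }
  mt <- p$genes$type == "mito"
  if (any(p$genes$contig[mt] != "chrM") || any(p$genes$contig[!mt] == "chrM")) {
    stop("mitochondrial genes must lie only on chrM")
  }
  tf_ids <- p$genes$gene_id[p$genes$type == "tf"]
  tgt_tf <- p$genes$tf[p$genes$type == "target"]
  if (!all(tf_ids %in% tgt_tf)) {
    stop("every lineage TF needs at least one target with an enhancer")
  }
  invisible(TRUE)
}

#' @export
print.RegulatoryProgram <- function(x, ...) {
  cfg <- x$config
  cat("RegulatoryProgram:", cfg$n_branches, "branches,",
      cfg$tfs_per_branch, "lineage TFs/branch,",
      nrow(x$genes), "genes,", nrow(x$peaks), "peaks,",
      nrow(x$links), "planted links,", length(x$motifs), "motifs\n")
  invisible(x)
}
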