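#' Simulate per-cell latent states over four sampling stages
#'
#' Draws a latent developmental time s in [0,1] per cell from its stage
#' window, assigns cells past the branch point to a terminal branch by a
#' Markov branching rule, and attaches true growth rates (elevated for
#' multipotent cells through the proliferation program, scaled by per-branch
#' growth multipliers) plus RNA/ATAC depth factors.
#'
#' @param program a \code{RegulatoryProgram}.
#' @param n_cells_per_stage integer vector of length 4, all positive.
#' @param seed integer seed.
#' @return a \code{CellStateTable} data.frame: barcode, stage, s, branch
#'   ("multipotent" or "branchK"), g_true, rna_depth, atac_depth.
#' @export
simulate_cell_states <- function(program,
                                 n_cells_per_stage = program$config$cells_per_stage,
                                 seed = 1L) {
  stopifnot(inherits(program, "RegulatoryProgram"))
  cfg <- program$config
  if (length(n_cells_per_stage) != 4L || any(n_cells_per_stage < 1L)) {
    stop("need a positive cell count for each of the 4 stages")
  }
  with_seed(seed, {
    stages <- paste0("t", 0:3)
    n <- as.integer(n_cells_per_stage)
    stage <- rep(stages, n)
    win <- cfg$stage_windows
    s <- unlist(lapply(1:4, function(i) stats::runif(n[i], win[i, 1],
                                                     win[i, 2])))
    branch <- rep("multipotent", length(s))
    post <- s > program$branch_point
    branch[post] <- paste0("branch", sample.int(cfg$n_branches, sum(post),
                                                replace = TRUE,
                                                prob = program$branch_weights))
    bmult <- rep(1, length(s))
    bi <- match(branch, paste0("branch", seq_len(cfg$n_branches)))
    bmult[!is.na(bi)] <- program$branch_growth[bi[!is.na(bi)]]
    g_true <- exp(0.7 * (1 - s)) * bmult
    out <- data.frame(
      barcode = sprintf("cell_%05d", seq_along(s)),
      stage = stage, s = s, branch = branch, g_true = g_true,
      rna_depth = pmax(0.6, stats::rlnorm(length(s), 0, cfg$depth_sdlog)),
      atac_depth = pmax(0.6, stats::rlnorm(length(s), 0, cfg$depth_sdlog)),
      stringsAsFactors = FALSE
    )
    class(out) <- c("CellStateTable", "data.frame")
    out
  })
}

## ---- planted activity model ------------------------------------------

## ramp from 0 at the branch point to 1 shortly after
.branch_ramp <- function(s, bp) pmin(1, pmax(0, (s - bp) / 0.2))

## lineage-TF activity over latent time; later TF indices switch on later
.tf_activity <- function(s, bp, tf_index) {
  pmin(1, pmax(0, (s - bp - 0.2 * (tf_index - 1)) / 0.25))
}

## phase-specific drive of a target gene: a Gaussian rise to the phase
## center, decaying only to `floor` x peak afterwards (activated programs
## stay partially on), gated to cells of the owning branch
.phase_bump <- function(s, center, width, floor) {
  b <- exp(-((s - center) / width)^2)
  ifelse(s > center, floor + (1 - floor) * b, b)
}

## cells x targets drive matrix (zero outside the owning branch)
.drive_matrix <- function(program, states) {
  cfg <- program$config
  tgt <- program$genes[program$genes$type == "target", , drop = FALSE]
  centers <- cfg$phase_centers[tgt$phase]
  d <- matrix(0, nrow(states), nrow(tgt),
              dimnames = list(states$barcode, tgt$gene_id))
  for (b in seq_len(cfg$n_branches)) {
    rows <- which(states$branch == paste0("branch", b))
    cols <- which(tgt$branch == b)
    if (!length(rows) || !length(cols)) next
    d[rows, cols] <- outer(states$s[rows], centers[cols],
                           function(s, mu) .phase_bump(s, mu, cfg$bump_width,
                                                       cfg$bump_floor)) *
      .branch_ramp(states$s[rows], program$branch_point)
  }
  d
}

#' Render paired multiome count matrices from a program and cell states
#'
#' RNA counts are negative binomial with mean depth x baseline x
#' (1 + sum of link weight x enhancer activity), where enhancer activity is
#' a logistic of the planted TF drive; ATAC counts are Poisson (truncated to
#' small integers) around depth x peak activity. A fragments table is
#' generated consistent with the ATAC counts, with fragment lengths drawn
#' from a sub-nucleosomal/mononucleosomal mixture so nucleosome-signal and
#' TSS-enrichment QC metrics are exercised. A configured fraction of junk
#' barcodes violating the QC thresholds is appended.
#'
#' @param program a \code{RegulatoryProgram}.
#' @param states a \code{CellStateTable} from \code{simulate_cell_states}.
#' @param seed integer seed.
#' @return a \code{MultiomeDataset}; the generator bookkeeping needed by
#'   \code{\link{ground_truth}} travels in \code{attr(, "sim")}.
#' @export
render_multiome_counts <- function(program, states, seed = 1L) {
  stopifnot(inherits(program, "RegulatoryProgram"))
  cfg <- program$config
  if (cfg$nb_theta <= 0) stop("NB dispersion theta must be positive")
  genes <- program$genes
  peaks <- program$peaks
  with_seed(seed, {
    n_real <- nrow(states)
    n_junk <- round(cfg$junk_frac * n_real)

    ## ---- RNA ----------------------------------------------------------
    mod <- matrix(1, n_real, nrow(genes),
                  dimnames = list(states$barcode, genes$gene_id))
    drive <- .drive_matrix(program, states)
    enh_act <- cfg$enhancer_floor +
      cfg$enhancer_span * stats::plogis(cfg$enhancer_slope * (drive - 0.5))
    tgt_idx <- match(colnames(drive), genes$gene_id)
    w <- cfg$link_weight
    mod[, tgt_idx] <- 1 + w * cfg$enhancers_per_target * enh_act
    tf_rows <- which(genes$type == "tf")
    for (j in tf_rows) {
      rows <- which(states$branch == paste0("branch", genes$branch[j]))
      if (!length(rows)) next
      mod[rows, j] <- 1 + cfg$tf_amplitude *
        .tf_activity(states$s[rows], program$branch_point, genes$tf_index[j])
    }
    prolif_idx <- which(genes$type == "prolif")
    mod[, prolif_idx] <- 1 + cfg$prolif_amplitude * (1 - states$s)
    matur_idx <- which(genes$type == "matur")
    mod[, matur_idx] <- 1 + cfg$matur_amplitude * states$s
    mu_rna <- states$rna_depth * sweep(mod, 2L, genes$baseline, "*")
    if (any(mu_rna < 0)) stop("negative RNA means")
    rna <- matrix(stats::rnbinom(length(mu_rna), size = cfg$nb_theta,
                                 mu = mu_rna),
                  n_real, ncol(mu_rna), dimnames = dimnames(mu_rna))

    ## ---- ATAC ---------------------------------------------------------
    peak_scale <- cfg$atac_scale * stats::runif(nrow(peaks), 0.5, 1.5)
    is_enh <- peaks$role == "enhancer"
    peak_scale[is_enh] <- cfg$enhancer_atac_scale *
      stats::runif(sum(is_enh), 0.9, 1.1)
    base_act <- ifelse(peaks$role == "promoter", 0.7,
                       stats::runif(nrow(peaks), 0.05, 0.6))
    act <- matrix(rep(base_act, each = n_real), n_real, nrow(peaks),
                  dimnames = list(states$barcode, peaks$peak_id))
    enh_pk <- which(peaks$role == "enhancer")
    act[, enh_pk] <- enh_act[, peaks$gene[enh_pk], drop = FALSE]
    mu_atac <- states$atac_depth * sweep(act, 2L, peak_scale, "*")
    if (any(mu_atac < 0)) stop("negative ATAC means")
    atac <- matrix(pmin(stats::rpois(length(mu_atac), mu_atac),
                        cfg$atac_max_count),
                   n_real, ncol(mu_atac), dimnames = dimnames(mu_atac))

    ## ---- junk barcodes --------------------------------------------
    cells <- data.frame(barcode = states$barcode, stage = states$stage,
                        stringsAsFactors = FALSE)
    junk_barcodes <- character(0)
    if (n_junk > 0L) {
      junk_barcodes <- sprintf("junk_%05d", seq_len(n_junk))
      base_j <- genes$baseline
      base_j[genes$type == "mito"] <- base_j[genes$type == "mito"] * 50
      mu_j <- 0.08 * matrix(rep(base_j, each = n_junk), n_junk, ncol(rna))
      rna_j <- matrix(stats::rnbinom(length(mu_j), size = cfg$nb_theta,
                                     mu = mu_j), n_junk, ncol(rna))
      mu_aj <- 0.12 * matrix(rep(peak_scale * base_act, each = n_junk),
                             n_junk, ncol(atac))
      atac_j <- matrix(pmin(stats::rpois(length(mu_aj), mu_aj),
                            cfg$atac_max_count), n_junk, ncol(atac))
      rownames(rna_j) <- rownames(atac_j) <- junk_barcodes
      rna <- rbind(rna, rna_j)
      atac <- rbind(atac, atac_j)
      cells <- rbind(cells, data.frame(
        barcode = junk_barcodes,
        stage = sample(paste0("t", 0:3), n_junk, replace = TRUE),
        stringsAsFactors = FALSE))
    }

    ## ---- fragments ------------------------------------------------
    frag <- .render_fragments(atac, peaks, junk_barcodes, cfg)

    dataset <- multiome_dataset(
      rna = methods::as(rna, "CsparseMatrix"),
      atac = methods::as(atac, "CsparseMatrix"),
      fragments = frag, genes = genes[, c("gene_id", "contig", "strand",
                                          "tss", "body_start", "body_end")],
      peaks = peaks[, c("peak_id", "contig", "start", "end")],
      contigs = program$contigs, genome = program$genome, cells = cells)
    attr(dataset, "sim") <- list(junk_barcodes = junk_barcodes,
                                 peak_scale = peak_scale,
                                 base_activity = base_act)
    dataset
  })
}

## one fragment row per ATAC count, placed inside the counted peak;
## real cells draw lengths from the sub/mono mixture, junk cells are
## all mononucleosomal (so their nucleosome signal fails QC)
.render_fragments <- function(atac, peaks, junk_barcodes, cfg) {
  sm <- Matrix::summary(methods::as(atac, "TsparseMatrix"))
  if (is.null(dim(sm))) sm <- as.data.frame(sm)
  reps <- rep.int(seq_len(nrow(sm)), sm$x)
  cell_i <- sm$i[reps]
  peak_j <- sm$j[reps]
  n <- length(cell_i)
  barcode <- rownames(atac)[cell_i]
  is_junk <- barcode %in% junk_barcodes
  sub <- stats::runif(n) < cfg$frag_sub_frac & !is_junk
  len <- integer(n)
  len[sub] <- pmax(30L, as.integer(round(stats::rnorm(sum(sub),
                                                      cfg$frag_sub_mean,
                                                      cfg$frag_sub_sd))))
  len[!sub] <- pmax(150L, as.integer(round(stats::rnorm(sum(!sub),
                                                        cfg$frag_mono_mean,
                                                        cfg$frag_mono_sd))))
  pw <- peaks$end[peak_j] - peaks$start[peak_j]
  len <- pmin(len, pw - 1L)
  start <- peaks$start[peak_j] +
    as.integer(floor(stats::runif(n) * (pw - len + 1L)))
  frag <- data.frame(chrom = peaks$contig[peak_j], start = start,
                     end = start + len, barcode = barcode,
                     count = 1L, stringsAsFactors = FALSE)
  frag <- frag[order(frag$chrom, frag$start), , drop = FALSE]
  rownames(frag) <- NULL
  frag
}

#' Assemble the planted ground truth of a simulated dataset
#'
#' @param program,states the objects the dataset was rendered from.
#' @param dataset the rendered \code{MultiomeDataset} (supplies the junk
#'   barcode list).
#' @return an object of class \code{GroundTruth}: the regulatory program,
#'   cell-state table, planted link list, signed TF->target edge list and
#'   terminal-branch label per cell.
#' @export
ground_truth <- function(program, states, dataset = NULL) {
  tgt <- program$genes[program$genes$type == "target", , drop = FALSE]
  edges <- data.frame(tf = tgt$tf, target = tgt$gene_id, sign = 1L,
                      stringsAsFactors = FALSE)
  structure(list(
    program = program, states = states, links = program$links,
    edges = edges,
    terminal_branch = stats::setNames(states$branch, states$barcode),
    junk_barcodes = if (is.null(dataset)) character(0) else
      attr(dataset, "sim")$junk_barcodes
  ), class = "GroundTruth")
}

#' One-call simulation of a full synthetic multiome dataset
#'
#' Convenience wrapper: builds the regulatory program, simulates cell
#' states, renders counts and assembles the ground truth. Sub-seeds are
#' derived deterministically from \code{seed}.
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed integer master seed.
#' @return list with elements \code{dataset}, \code{truth}, \code{program},
#'   \code{states}.
#' @export
simulate_multiome <- function(config = sim_config(), seed = 1L) {
  program <- build_regulatory_program(config, seed = seed)
  states <- simulate_cell_states(program, config$cells_per_stage,
                                 seed = seed + 1L)
  dataset <- render_multiome_counts(program, states, seed = seed + 2L)
  list(dataset = dataset, truth = ground_truth(program, states, dataset),
       program = program, states = states)
}

#' Simulate validation assets: ChIP replicates, bulk DEG table, curated list
#'
#' ChIP peaks are placed at the (motif-bearing) enhancers of each assayed
#' TF's true targets with positional jitter, plus uniform background noise
#' peaks; two replicates per TF share anchors and therefore overlap. The
#' bulk DEG table contrasts two regions built from the first two branches'
#' programs; the curated disease-gene list overlaps true targets at a
#' configured rate.
#'
#' @param program a \code{RegulatoryProgram}.
#' @param seed integer seed.
#' @param tfs TF gene ids to assay; default the first lineage TF of
#'   branches 1 and 2.
#' @param n_replicates ChIP replicates per TF (>= 2 lineage TFs required).
#' @param noise_rate fraction of each replicate's peaks that are background
#'   noise (0 gives pure signal).
#' @param jitter_sd positional jitter (bp) of peak centers around anchors.
#' @param chip_width width (bp) of simulated ChIP peaks.
#' @param curated_size,curated_overlap size of the curated gene list and the
#'   fraction of it drawn from true targets.
#' @return list with \code{chip} (per TF, a list of replicate interval
#'   data.frames), \code{bulk_deg} and \code{curated_genes}.
#' @export
simulate_validation_assets <- function(program, seed = 1L, tfs = NULL,
                                       n_replicates = 2L, noise_rate = 0.3,
                                       jitter_sd = 100, chip_width = 400L,
                                       curated_size = 40L,
                                       curated_overlap = 0.3) {
  stopifnot(inherits(program, "RegulatoryProgram"))
  genes <- program$genes
  tf_ids <- genes$gene_id[genes$type == "tf"]
  if (length(tf_ids) < 2L) stop("need at least 2 lineage TFs")
  if (is.null(tfs)) {
    tfs <- c(genes$gene_id[genes$type == "tf" & genes$branch == 1][1],
             genes$gene_id[genes$type == "tf" & genes$branch == 2][1])
  }
  stopifnot(all(tfs %in% tf_ids))
  with_seed(seed, {
    enh <- program$peaks[program$peaks$role == "enhancer", , drop = FALSE]
    chip <- lapply(tfs, function(tf) {
      tg <- genes$gene_id[!is.na(genes$tf) & genes$tf == tf]
      anchors <- enh[enh$gene %in% tg, , drop = FALSE]
      mid <- (anchors$start + anchors$end) %/% 2L
      lapply(seq_len(n_replicates), function(r) {
        center <- mid + as.integer(round(stats::rnorm(length(mid), 0,
                                                      jitter_sd)))
        sig <- data.frame(contig = anchors$contig,
                          start = center - chip_width %/% 2L,
                          end = center + chip_width %/% 2L,
                          stringsAsFactors = FALSE)
        n_noise <- round(nrow(sig) * noise_rate / max(1e-12, 1 - noise_rate))
        if (n_noise > 0) {
          ctg <- sample(names(program$contigs), n_noise, replace = TRUE)
          st <- as.integer(floor(stats::runif(n_noise) *
                                   (program$contigs[ctg] - chip_width)))
          sig <- rbind(sig, data.frame(contig = ctg, start = st,
                                       end = st + chip_width,
                                       stringsAsFactors = FALSE))
        }
        sig <- sig[order(sig$contig, sig$start), , drop = FALSE]
        rownames(sig) <- NULL
        sig
      })
    })
    names(chip) <- tfs

    b1 <- genes$gene_id[!is.na(genes$branch) & genes$branch == 1]
    b2 <- genes$gene_id[!is.na(genes$branch) & genes$branch == 2]
    hk <- genes$gene_id[genes$type == "hk"]
    null_genes <- sample(hk, min(50L, length(hk)))
    bulk_deg <- rbind(
      data.frame(gene = b1, log2fc = stats::rnorm(length(b1), 2, 0.3),
                 padj = 10^stats::runif(length(b1), -30, -5),
                 region = "regionA", stringsAsFactors = FALSE),
      data.frame(gene = b2, log2fc = stats::rnorm(length(b2), -2, 0.3),
                 padj = 10^stats::runif(length(b2), -30, -5),
                 region = "regionB", stringsAsFactors = FALSE),
      data.frame(gene = null_genes,
                 log2fc = stats::rnorm(length(null_genes), 0, 0.2),
                 padj = stats::runif(length(null_genes), 0.2, 1),
                 region = "none", stringsAsFactors = FALSE))

    targets <- genes$gene_id[genes$type == "target"]
    n_hit <- round(curated_overlap * curated_size)
    pool <- setdiff(genes$gene_id[!genes$type %in% c("target", "tf")],
                    null_genes)
    curated <- c(sample(targets, min(n_hit, length(targets))),
                 sample(pool, min(curated_size - n_hit, length(pool))))
    list(chip = chip, bulk_deg = bulk_deg, curated_genes = curated)
  })
}
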