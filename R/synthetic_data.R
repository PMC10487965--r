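## Synthetic data with planted ground truth.
##
## The generator emulates the statistical structure the downstream analysis
## assumes: multi-cell-type negative-binomial UMI matrices over a 2-group
## (Ctrl/DKD) x 4-replicate design, two planted pathway-activity states per
## cell type (health-dominant vs disease-dominant), an optional known doublet
## fraction, a planted ligand -> receptor -> TF -> target causal chain, and
## per-type mean profiles for bulk mixing.

#' Configuration for the synthetic-data generator
#'
#' Defaults mirror the study design the pipeline targets: two groups
#' (Ctrl/DKD) with four replicate samples each, a minority disease-dominant
#' (DDC) state that dominates the DKD group (85% of DKD cells vs 10% of
#' Ctrl cells), 40% of the pathway sets shifted three log2 units in DDC
#' cells, and mitochondrially encoded mRNA genes present so that
#' mitochondrial content can be computed.
#'
#' @param n_cell_types number of annotated cell types.
#' @param cells_per_type_per_sample cells simulated per type per sample.
#' @param samples_per_group replicate samples per group (4 + 4 by default).
#' @param groups two group labels, reference first.
#' @param n_genes total genes (includes the 13 mito-mRNA genes, pathway
#'   genes, cascade genes, markers and filler).
#' @param n_sets,set_size pathway collection dimensions (sets drawn from a
#'   nuclear mitochondria-associated gene pool).
#' @param frac_sets_shifted fraction of sets whose genes shift in DDC cells.
#' @param shift_log2fc per-gene log2 fold shift applied in DDC cells.
#' @param ddc_frac_dkd,ddc_frac_ctrl planted DDC state probability per cell
#'   in each group.
#' @param doublet_fraction fraction of emitted cells that are doublets
#'   (count sums of two distinct same-sample cells).
#' @param n_traj_genes number of non-MANG genes whose mean scales
#'   continuously with the latent severity driving the planted trajectory.
#' @param traj_log2fc log2 fold range of trajectory genes across severity.
#' @param n_tfs,targets_per_tf planted regulatory cascade dimensions.
#' @param cascade_log2fc effect size along the receptor-TF-target chain.
#' @param lr_fc fold elevation of the planted ligand (in the source type)
#'   and receptor (in the target type).
#' @param baseline_meanlog,baseline_sdlog log-normal law of per-gene
#'   baseline negative-binomial means.
#' @param dispersion_meanlog,dispersion_sdlog log-normal law of per-gene NB
#'   size parameters.
#' @param size_factor_sdlog log-normal sd of per-cell library size factors.
#' @param n_markers_per_type,marker_fc per-type marker genes and their fold
#'   elevation.
#' @param seed RNG seed; a fixed seed makes the output byte-identical.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_cell_types = 2,
                       cells_per_type_per_sample = 40,
                       samples_per_group = 4,
                       groups = c("Ctrl", "DKD"),
                       n_genes = 400,
                       n_sets = 60,
                       set_size = 8,
                       frac_sets_shifted = 0.4,
                       shift_log2fc = 3,
                       ddc_frac_dkd = 0.85,
                       ddc_frac_ctrl = 0.1,
                       doublet_fraction = 0,
                       n_traj_genes = 20,
                       traj_log2fc = 2,
                       n_tfs = 4,
                       targets_per_tf = 10,
                       cascade_log2fc = 2,
                       lr_fc = 8,
                       baseline_meanlog = log(2),
                       baseline_sdlog = 0.8,
                       dispersion_meanlog = log(4),
                       dispersion_sdlog = 0.5,
                       size_factor_sdlog = 0.25,
                       n_markers_per_type = 10,
                       marker_fc = 8,
                       seed = 1L) {
  cfg <- as.list(environment())
  fr <- c(frac_sets_shifted, ddc_frac_dkd, ddc_frac_ctrl, doublet_fraction)
  if (any(fr < 0 | fr > 1)) stop("validation error: fractions must be in [0,1]")
  if (length(groups) != 2L) stop("validation error: exactly two groups")
  if (round(frac_sets_shifted * n_sets) > n_sets)
    stop("validation error: more shifted sets than sets")
  if (!all(is.finite(c(shift_log2fc, traj_log2fc, cascade_log2fc, lr_fc))))
    stop("validation error: effect sizes must be finite")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a full synthetic dataset with ground truth
#'
#' Produces a UMI [count_matrix()], a [gene_set_collection()] of planted
#' pathway sets, a gene catalog (mito-mRNA, MANG and TF flags), a small
#' ligand-receptor database containing the planted pair, and a ground-truth
#' record for every downstream recovery test: per-cell state (HDC/DDC),
#' doublet flags, latent severity (the true pseudotime order), shifted set
#' names, planted cascade edges and per-type mean profiles for bulk mixing.
#'
#' DDC cells have the configured log2 fold shift applied to the genes of the
#' shifted pathway sets; trajectory genes scale continuously with a latent
#' severity that is low in HDC and high in DDC cells; in the cascade target
#' type, receptor, TF and target-gene means all increase monotonically with
#' severity so that the receptor->TF->target chain is causally planted;
#' doublets are count sums of two distinct same-sample cells.
#'
#' @param config a [sim_config()].
#' @return list with elements `counts`, `sets`, `catalog`, `lr`, `truth`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config

  ## gene universe -----------------------------------------------------------
  mito_mrna <- c("mt-Nd1", "mt-Nd2", "mt-Co1", "mt-Co2", "mt-Atp8", "mt-Atp6",
                 "mt-Co3", "mt-Nd3", "mt-Nd4l", "mt-Nd4", "mt-Nd5", "mt-Nd6",
                 "mt-Cytb")
  n_mang <- max(cfg$n_sets * cfg$set_size %/% 2L, cfg$set_size * 2L)
  mang <- sprintf("Mang%04d", seq_len(n_mang))
  traj <- sprintf("Esd%03d", seq_len(cfg$n_traj_genes))
  tfs <- sprintf("Tf%02d", seq_len(cfg$n_tfs))
  targets <- sprintf("Tg%03d", seq_len(cfg$n_tfs * cfg$targets_per_tf))
  lig <- "LigA"; rcp <- "RcpA"
  markers <- sprintf("Mk%03d", seq_len(cfg$n_markers_per_type * cfg$n_cell_types))
  named <- c(mito_mrna, mang, traj, tfs, targets, lig, rcp, markers)
  n_fill <- max(cfg$n_genes - length(named), 10L)
  fill <- sprintf("Gene%04d", seq_len(n_fill))
  genes <- c(named, fill)
  n_genes <- length(genes)

  ## pathway sets over the MANG pool ----------------------------------------
  sets <- lapply(seq_len(cfg$n_sets), function(i)
    sample(mang, cfg$set_size))
  names(sets) <- sprintf("MitoPath%03d", seq_len(cfg$n_sets))
  sets <- gene_set_collection(sets)
  n_shift <- round(cfg$frac_sets_shifted * cfg$n_sets)
  shifted_sets <- names(sets)[seq_len(n_shift)]
  shifted_genes <- unique(unlist(sets[shifted_sets], use.names = FALSE))

  ## cell design -------------------------------------------------------------
  types <- sprintf("Type%d", seq_len(cfg$n_cell_types))
  samples <- c(paste0(cfg$groups[1L], "_", seq_len(cfg$samples_per_group)),
               paste0(cfg$groups[2L], "_", seq_len(cfg$samples_per_group)))
  group_of <- rep(cfg$groups, each = cfg$samples_per_group)
  design <- expand.grid(sample_id = samples, cell_type = types,
                        stringsAsFactors = FALSE)
  design <- design[rep(seq_len(nrow(design)), each = cfg$cells_per_type_per_sample), ]
  n_cells <- nrow(design)
  design$group <- group_of[match(design$sample_id, samples)]
  p_ddc <- ifelse(design$group == cfg$groups[2L], cfg$ddc_frac_dkd, cfg$ddc_frac_ctrl)
  state <- ifelse(runif(n_cells) < p_ddc, "DDC", "HDC")
  severity <- ifelse(state == "DDC", runif(n_cells, 0.55, 1), runif(n_cells, 0, 0.45))

  ## per-gene NB law ---------------------------------------------------------
  mu0 <- rlnorm(n_genes, cfg$baseline_meanlog, cfg$baseline_sdlog)
  names(mu0) <- genes
  mu0[mito_mrna] <- rlnorm(length(mito_mrna), log(3), 0.3)  # mito mRNAs are abundant
  size_g <- rlnorm(n_genes, cfg$dispersion_meanlog, cfg$dispersion_sdlog)
  names(size_g) <- genes
  sf <- rlnorm(n_cells, 0, cfg$size_factor_sdlog)

  ## mean model: baseline x markers x state shift x trajectory x cascade -----
  logfc <- matrix(0, n_genes, n_cells, dimnames = list(genes, NULL))
  for (i in seq_along(types)) {
    mk <- markers[seq_len(cfg$n_markers_per_type) + (i - 1L) * cfg$n_markers_per_type]
    logfc[mk, design$cell_type == types[i]] <- log2(cfg$marker_fc)
  }
  ddc <- state == "DDC"
  logfc[shifted_genes, ddc] <- logfc[shifted_genes, ddc] + cfg$shift_log2fc
  logfc[traj, ] <- logfc[traj, ] +
    matrix(cfg$traj_log2fc, length(traj), 1) %*% matrix(severity, 1, n_cells)
  ## cascade planted in the last cell type; ligand from the first cell type
  src <- design$cell_type == types[1L]
  tgt <- design$cell_type == types[length(types)]
  logfc[lig, src] <- log2(cfg$lr_fc)
  logfc[rcp, tgt] <- log2(cfg$lr_fc) * severity[tgt] + log2(2)
  for (k in seq_along(tfs)) {
    tg_k <- targets[seq_len(cfg$targets_per_tf) + (k - 1L) * cfg$targets_per_tf]
    logfc[tfs[k], tgt] <- cfg$cascade_log2fc * severity[tgt]
    logfc[tg_k, tgt] <- rep(cfg$cascade_log2fc * severity[tgt],
                            each = length(tg_k))
  }
  mu <- mu0 * (2^logfc) * rep(sf, each = n_genes)
  counts <- matrix(rnbinom(n_genes * n_cells, size = size_g, mu = mu),
                   n_genes, n_cells)
  rownames(counts) <- genes

  barcodes <- sprintf("cell_%05d", seq_len(n_cells))
  colnames(counts) <- barcodes
  meta <- data.frame(barcode = barcodes, sample_id = design$sample_id,
                     group = design$group, cell_type = design$cell_type,
                     stringsAsFactors = FALSE)
  doublet_flag <- rep(FALSE, n_cells)

  ## doublets: sums of two distinct same-sample cells ------------------------
  if (cfg$doublet_fraction > 0) {
    n_doub <- round(cfg$doublet_fraction * n_cells / (1 - cfg$doublet_fraction))
    dsample <- sample(samples, n_doub, replace = TRUE)
    dmat <- matrix(0, n_genes, n_doub)
    dtype <- character(n_doub)
    for (j in seq_len(n_doub)) {
      idx <- sample(which(design$sample_id == dsample[j]), 2L)
      dmat[, j] <- counts[, idx[1L]] + counts[, idx[2L]]
      dtype[j] <- design$cell_type[idx[1L]]
    }
    dbar <- sprintf("doublet_%04d", seq_len(n_doub))
    colnames(dmat) <- dbar
    rownames(dmat) <- genes
    counts <- cbind(counts, dmat)
    meta <- rbind(meta, data.frame(barcode = dbar, sample_id = dsample,
                                   group = group_of[match(dsample, samples)],
                                   cell_type = dtype, stringsAsFactors = FALSE))
    state <- c(state, rep(NA_character_, n_doub))
    severity <- c(severity, rep(NA_real_, n_doub))
    doublet_flag <- c(doublet_flag, rep(TRUE, n_doub))
  }

  ## catalog and LR database -------------------------------------------------
  catalog <- data.frame(
    symbol = genes,
    is_mito_encoded = genes %in% mito_mrna,
    is_mito_mrna = genes %in% mito_mrna,
    is_mang = genes %in% mang,
    is_tf = genes %in% tfs,
    slc_family = "",
    chromosome = ifelse(genes %in% mito_mrna, "chrM", "chr1"),
    stringsAsFactors = FALSE)
  class(catalog) <- c("gene_catalog", "data.frame")

  decoys <- data.frame(
    pathway = sprintf("ToyPath%02d", 2:6),
    ligand = sprintf("Gene%04d", 1:5),
    receptor = sprintf("Gene%04d", 6:10),
    category = "secreted", stringsAsFactors = FALSE)
  lr <- lr_database(rbind(
    data.frame(pathway = "PlantedPath", ligand = lig, receptor = rcp,
               category = "secreted", stringsAsFactors = FALSE),
    decoys))

  ## per-type mean profiles for bulk mixing (singlet expectation) ------------
  type_profiles <- sapply(types, function(tp) {
    cols <- which(design$cell_type == tp)
    rowMeans(mu[, cols, drop = FALSE])
  })

  cm <- count_matrix(counts, meta, catalog[, c("symbol", "chromosome")])
  truth <- list(
    state = setNames(state, colnames(counts)),
    severity = setNames(severity, colnames(counts)),
    doublet = setNames(doublet_flag, colnames(counts)),
    shifted_sets = shifted_sets,
    shifted_genes = shifted_genes,
    traj_genes = traj,
    markers = split(markers, rep(types, each = cfg$n_markers_per_type)),
    cascade = list(ligand = lig, receptor = rcp, tfs = tfs,
                   targets = split(targets, rep(tfs, each = cfg$targets_per_tf)),
                   source_type = types[1L], target_type = types[length(types)]),
    type_profiles = type_profiles)
  list(counts = cm, sets = sets, catalog = catalog, lr = lr, truth = truth)
}

#' Simulate bulk expression profiles as mixtures of cell-type signatures
#'
#' @param signature genes x cell-type matrix of mean expression profiles
#'   (e.g. `truth$type_profiles` from [simulate_dataset()]).
#' @param proportions numeric vector (one mixture) or cell-types x samples
#'   matrix of mixing proportions; each column must be non-negative and sum
#'   to 1.
#' @param noise_sd sd of Gaussian noise applied on the log scale (0 = exact
#'   mixture).
#' @param seed RNG seed used when `noise_sd > 0`.
#' @return genes x samples matrix of bulk profiles.
#' @export
simulate_bulk <- function(signature, proportions, noise_sd = 0, seed = 1L) {
  if (is.null(dim(proportions)))
    proportions <- matrix(proportions, ncol = 1L,
                          dimnames = list(colnames(signature), "bulk_1"))
  if (any(proportions < 0)) stop("validation error: negative proportions")
  cs <- colSums(proportions)
  if (any(abs(cs - 1) > 1e-8)) stop("validation error: proportions must sum to 1")
  if (nrow(proportions) != ncol(signature))
    stop("validation error: proportions rows must match signature columns")
  bulk <- signature %*% proportions
  if (noise_sd > 0) {
    set.seed(seed)
    bulk <- bulk * exp(matrix(rnorm(length(bulk), 0, noise_sd), nrow(bulk)))
  }
  rownames(bulk) <- rownames(signature)
  bulk
}

#' Simulate a noiseless (or noisy) one-dimensional expression gradient
#'
#' Emits a normalized-expression matrix whose cells lie on a single latent
#' severity axis, together with the planted ordering; used to exercise
#' pseudotime recovery where the true ordering is known exactly.
#'
#' @param n_cells,n_genes matrix dimensions.
#' @param noise_sd Gaussian noise added to each entry (0 = noiseless).
#' @param seed RNG seed for loadings/noise.
#' @return list with `expr` (genes x cells), `order` (latent position per
#'   cell in \[0,1\]) and `state` ("HDC" below the midpoint, "DDC" above).
#' @export
simulate_gradient <- function(n_cells = 100, n_genes = 20, noise_sd = 0,
                              seed = 1L) {
  set.seed(seed)
  t <- runif(n_cells)
  load <- runif(n_genes, 0.5, 2) * sample(c(-1, 1), n_genes, replace = TRUE)
  expr <- outer(load, t) + matrix(rnorm(n_genes * n_cells, 0, noise_sd),
                                  n_genes, n_cells)
  dimnames(expr) <- list(sprintf("Esd%03d", seq_len(n_genes)),
                         sprintf("cell_%04d", seq_len(n_cells)))
  list(expr = expr, order = setNames(t, colnames(expr)),
       state = setNames(ifelse(t > 0.5, "DDC", "HDC"), colnames(expr)))
}
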