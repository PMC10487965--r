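## Cluster-to-cluster ligand-receptor communication probabilities with a
## permutation null, and selection of ESDEG-bearing pathways (DCCPs).

#' Trimmed-mean ensemble expression per cluster
#'
#' @param norm genes x cells normalized matrix.
#' @param labels per-cell cluster labels (every cluster >= 1 cell).
#' @param trim trimming fraction per tail (default 0.25; must be < 0.5).
#' @return genes x clusters matrix of trimmed means.
#' @export
cluster_expression <- function(norm, labels, trim = 0.25) {
  if (trim >= 0.5) stop("validation error: trim must be < 0.5")
  labels <- as.character(labels)
  cl <- sort(unique(labels))
  out <- vapply(cl, function(c1)
    apply(norm[, labels == c1, drop = FALSE], 1L, mean, trim = trim),
    numeric(nrow(norm)))
  out <- matrix(out, nrow = nrow(norm),
                dimnames = list(rownames(norm), cl))
  out
}

## geometric mean of the trimmed means of "+"-separated subunits;
## NA if any subunit is missing from the table
ensemble_level <- function(expr_cl, genes_str) {
  genes <- strsplit(genes_str, "+", fixed = TRUE)[[1L]]
  if (!all(genes %in% rownames(expr_cl))) return(rep(NA_real_, ncol(expr_cl)))
  if (length(genes) == 1L) return(expr_cl[genes, ])
  exp(colMeans(log(expr_cl[genes, , drop = FALSE] + .Machine$double.eps)))
}

#' Ligand-receptor communication probabilities between clusters
#'
#' For each (source, target, pathway) row the ligand level `l` is the
#' trimmed mean of the ligand gene(s) in the source cluster and the
#' receptor level `r` that of the receptor gene(s) in the target cluster
#' (multi-subunit complexes: geometric mean); the communication
#' probability is the Hill-type saturation `l*r / (Kh + l*r)` with
#' half-saturation `Kh` (default 0.5), bounded in \[0, 1).
#'
#' @param cluster_expr genes x clusters matrix from [cluster_expression()].
#' @param lr an [lr_database()]; rows whose genes are absent from the
#'   matrix are dropped with a warning.
#' @param Kh half-saturation constant.
#' @return data.frame with source, target, pathway, ligand, receptor,
#'   `prob`.
#' @export
communication_prob <- function(cluster_expr, lr, Kh = 0.5) {
  cl <- colnames(cluster_expr)
  keep <- logical(nrow(lr))
  lvl_l <- list(); lvl_r <- list()
  for (i in seq_len(nrow(lr))) {
    li <- ensemble_level(cluster_expr, lr$ligand[i])
    ri <- ensemble_level(cluster_expr, lr$receptor[i])
    keep[i] <- !anyNA(li) && !anyNA(ri)
    lvl_l[[i]] <- li; lvl_r[[i]] <- ri
  }
  if (any(!keep))
    warning("LR rows dropped (genes missing): ",
            paste(lr$pathway[!keep], collapse = ", "))
  rows <- list()
  for (i in which(keep)) {
    for (s in seq_along(cl)) for (t in seq_along(cl)) {
      lrp <- lvl_l[[i]][s] * lvl_r[[i]][t]
      rows[[length(rows) + 1L]] <- data.frame(
        source = cl[s], target = cl[t], pathway = lr$pathway[i],
        ligand = lr$ligand[i], receptor = lr$receptor[i],
        prob = lrp / (Kh + lrp), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Permutation test of communication probabilities
#'
#' Cluster labels are permuted `n_perm` times and each observed probability
#' is compared with its permutation distribution:
#' `p = (1 + #[perm prob >= observed]) / (1 + n_perm)`. Rows with p < alpha
#' are flagged retained; per-cluster incoming/outgoing strengths are the
#' sums of retained probabilities.
#'
#' @param norm genes x cells normalized matrix.
#' @param labels per-cell cluster labels.
#' @param lr an [lr_database()].
#' @param n_perm number of permutations (>= 20; default 100).
#' @param seed permutation seed.
#' @param trim,Kh model parameters (see [cluster_expression()],
#'   [communication_prob()]).
#' @param alpha retention threshold (default 0.05).
#' @return data.frame (class `communication_result`) with `prob`, `p`,
#'   `retained`; per-cluster strength summary as attribute `strength`.
#' @export
permutation_test <- function(norm, labels, lr, n_perm = 100L, seed = 42L,
                             trim = 0.25, Kh = 0.5, alpha = 0.05) {
  if (n_perm < 20L) stop("validation error: n_perm must be >= 20")
  labels <- as.character(labels)
  obs <- communication_prob(cluster_expression(norm, labels, trim), lr, Kh)
  exceed <- numeric(nrow(obs))
  set.seed(seed)
  ## restrict the matrix to LR genes once; permutations only need those rows
  lr_genes <- unique(unlist(strsplit(c(obs$ligand, obs$receptor), "+",
                                     fixed = TRUE)))
  sub <- norm[intersect(rownames(norm), lr_genes), , drop = FALSE]
  for (b in seq_len(n_perm)) {
    perm <- sample(labels)
    pb <- communication_prob(cluster_expression(sub, perm, trim), lr, Kh)
    exceed <- exceed + (pb$prob >= obs$prob)
  }
  obs$p <- (1 + exceed) / (1 + n_perm)
  obs$retained <- obs$p < alpha
  kept <- obs[obs$retained, , drop = FALSE]
  cl <- sort(unique(labels))
  strength <- data.frame(
    cluster = cl,
    outgoing = vapply(cl, function(c1) sum(kept$prob[kept$source == c1]), 1),
    incoming = vapply(cl, function(c1) sum(kept$prob[kept$target == c1]), 1),
    stringsAsFactors = FALSE)
  attr(obs, "strength") <- strength
  class(obs) <- c("communication_result", "data.frame")
  obs
}

#' Flag communication rows whose genes are ESDEGs (DCCPs)
#'
#' A retained row is an incoming different-communication pathway (DCCP)
#' when its receptor gene is an ESDEG of the target's cell type, and an
#' outgoing DCCP when its ligand gene is an ESDEG of the source's cell
#' type. Communication must have been computed over HDC/DDC-split
#' clusters; `cluster_celltype` maps each split cluster back to its cell
#' type.
#'
#' @param result a `communication_result`.
#' @param esdegs named list: cell type -> ESDEG gene vector.
#' @param cluster_celltype named character: cluster -> cell type.
#' @return the retained rows annotated with `incoming_dccp` and
#'   `outgoing_dccp` flags (possibly zero rows, mirroring cell types with
#'   no ESDEG-bearing pathway).
#' @export
select_dccp <- function(result, esdegs, cluster_celltype) {
  need <- unique(c(result$source, result$target))
  if (!all(need %in% names(cluster_celltype)))
    stop("validation error: missing subcluster labels: ",
         paste(setdiff(need, names(cluster_celltype)), collapse = ", "))
  rows <- result[result$retained, , drop = FALSE]
  gene_in <- function(genes_str, ct) {
    genes <- strsplit(genes_str, "+", fixed = TRUE)[[1L]]
    es <- esdegs[[ct]]
    !is.null(es) && any(genes %in% es)
  }
  rows$incoming_dccp <- vapply(seq_len(nrow(rows)), function(i)
    gene_in(rows$receptor[i], cluster_celltype[[rows$target[i]]]), TRUE)
  rows$outgoing_dccp <- vapply(seq_len(nrow(rows)), function(i)
    gene_in(rows$ligand[i], cluster_celltype[[rows$source[i]]]), TRUE)
  rows <- rows[rows$incoming_dccp | rows$outgoing_dccp, , drop = FALSE]
  rownames(rows) <- NULL
  rows
}
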