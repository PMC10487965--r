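## Regulon inference by regression-forest importance, AUC-based regulon
## activity, differential regulon testing, and receptor->TF->target
## cascade assembly.

#' Infer regulons from TF-to-target co-expression importance
#'
#' For every non-TF gene a regression forest predicts its UMI counts from
#' the expression of all transcription factors; per TF, the
#' `top_k_targets` genes by importance form the candidate regulon. An
#' optional prior (data.frame `tf`, `target`, `nes` from a motif-enrichment
#' resource) prunes candidates to prior-supported targets and applies the
#' NES > 3.0 qualification rule; without a prior, regulons are
#' co-expression-only and labelled as such. Cells are ordered by barcode
#' internally so results do not depend on cell order.
#'
#' @param counts a [count_matrix()] or genes x cells count matrix (>= 50
#'   cells).
#' @param tf_list character vector of TF symbols (>= 2 present in the
#'   matrix).
#' @param n_trees trees per forest (default 100).
#' @param top_k_targets candidate targets per TF (default 20).
#' @param prior optional data.frame with columns `tf`, `target`, `nes`.
#' @param nes_min qualification threshold on prior NES (default 3.0).
#' @param seed forest seed.
#' @return list of regulons (class `regulon_set`); each has `tf`,
#'   `targets`, `importance`, `provenance`.
#' @export
infer_regulons <- function(counts, tf_list, n_trees = 100L,
                           top_k_targets = 20L, prior = NULL, nes_min = 3.0,
                           seed = 42L) {
  m <- as_counts(counts)
  if (!length(tf_list)) stop("validation error: empty TF list")
  tfs <- intersect(tf_list, rownames(m))
  if (length(tfs) < 2L)
    stop("validation error: need >= 2 TFs present in the matrix")
  if (ncol(m) < 50L) stop("validation error: need >= 50 cells")
  m <- m[, order(colnames(m)), drop = FALSE]   # cell-order invariance
  X <- t(m[tfs, , drop = FALSE])
  colnames(X) <- make.names(tfs)
  other <- setdiff(rownames(m), tfs)
  imp <- matrix(0, length(tfs), length(other),
                dimnames = list(tfs, other))
  for (g in other) {
    y <- m[g, ]
    if (stats::var(y) == 0) next
    fit <- ranger::ranger(x = as.data.frame(X), y = y,
                          num.trees = n_trees, importance = "impurity",
                          seed = seed, num.threads = 1L)
    iv <- fit$variable.importance[make.names(tfs)]
    iv[is.na(iv)] <- 0
    imp[, g] <- iv
  }
  regs <- lapply(tfs, function(tf) {
    w <- imp[tf, ]
    w <- sort(w[w > 0], decreasing = TRUE)
    targets <- utils::head(names(w), top_k_targets)
    prov <- "coexpression"
    if (!is.null(prior)) {
      pr <- prior[prior$tf == tf, , drop = FALSE]
      if (nrow(pr)) {
        pr <- pr[pr$nes > nes_min, , drop = FALSE]
        targets <- intersect(targets, pr$target)
        prov <- "coexpression+prior"
      }
    }
    targets <- setdiff(targets, tf)
    if (!length(targets)) return(NULL)
    list(tf = tf, targets = targets,
         importance = imp[tf, targets], provenance = prov)
  })
  regs <- regs[!vapply(regs, is.null, TRUE)]
  names(regs) <- vapply(regs, `[[`, "", "tf")
  structure(regs, class = c("regulon_set", "list"))
}

#' @export
print.regulon_set <- function(x, ...) {
  cat(sprintf("regulon_set: %d regulons (%s)\n", length(x),
              paste(sprintf("%s:%d", names(x),
                            vapply(x, function(r) length(r$targets), 1L)),
                    collapse = ", ")))
  invisible(x)
}

#' Regulon activity as area under the recovery curve (AUCell-style)
#'
#' Per cell, genes are ranked by decreasing expression (random seeded
#' tie-break) and the regulon's activity is the trapezoidal area under the
#' curve recovering regulon genes within the top
#' `ceiling(top_fraction * n_genes)` ranks, normalized by the maximal
#' achievable area. Invariant under strictly monotone transforms of a
#' cell's expression vector.
#'
#' @param norm genes x cells normalized matrix.
#' @param regulons a `regulon_set` (or named list with `targets`).
#' @param top_fraction fraction of the ranking considered (in (0, 0.5\];
#'   default 0.05).
#' @param seed tie-break seed.
#' @return regulons x cells activity matrix in \[0, 1\].
#' @export
aucell_scores <- function(norm, regulons, top_fraction = 0.05, seed = 42L) {
  if (top_fraction <= 0 || top_fraction > 0.5)
    stop("validation error: top_fraction must be in (0, 0.5]")
  p <- nrow(norm)
  top <- ceiling(top_fraction * p)
  gene_sets <- lapply(regulons, function(r)
    intersect(if (is.list(r)) r$targets else r, rownames(norm)))
  empty <- lengths(gene_sets) == 0L
  if (any(empty))
    warning("regulons with no genes in matrix score 0: ",
            paste(names(regulons)[empty], collapse = ", "))
  max_auc <- function(m) {  # recovery curve y(k) = min(k, m), trapezoid
    y <- pmin(seq_len(top), m)
    sum((c(0, y[-top]) + y) / 2)
  }
  act <- matrix(0, length(regulons), ncol(norm),
                dimnames = list(names(regulons), colnames(norm)))
  set.seed(seed)
  tie_break <- stats::runif(p)
  for (j in seq_len(ncol(norm))) {
    ord <- order(-norm[, j], tie_break)
    top_genes <- rownames(norm)[ord[seq_len(top)]]
    for (s in seq_along(gene_sets)) {
      gs <- gene_sets[[s]]
      if (!length(gs)) next
      hit <- cumsum(top_genes %in% gs)
      auc <- sum((c(0, hit[-top]) + hit) / 2)
      act[s, j] <- auc / max_auc(min(length(gs), top))
    }
  }
  act
}

#' Differential regulon activity between HDC and DDC cells
#'
#' Applies the moderated two-group test ([moderated_diff()]) to the
#' activity rows and keeps the rows with p < `p_cut` (default 0.01), the
#' `top_n` most significant (all of them when fewer are significant).
#'
#' @param activity regulons x cells matrix from [aucell_scores()].
#' @param labels per-cell HDC/DDC labels (>= 3 cells each).
#' @param top_n rows retained (default 50).
#' @param p_cut significance threshold on the unadjusted p (default 0.01).
#' @return `moderated_diff_result` rows sorted by p.
#' @export
regulon_diff <- function(activity, labels, top_n = 50L, p_cut = 0.01) {
  labels <- as.factor(labels)
  if (min(table(labels)) < 3L)
    stop("validation error: both labels need >= 3 cells")
  res <- moderated_diff(activity, labels)
  res <- res[res$p < p_cut, , drop = FALSE]
  res <- res[order(res$p), , drop = FALSE]
  utils::head(res, top_n)
}

#' Assemble the receptor -> TF -> target cascade network
#'
#' Receptor-TF edges are created where the absolute Spearman correlation
#' of normalized expression reaches `rho_min` and the BH-adjusted
#' correlation p across all candidate pairs is < `alpha`; TF-target edges
#' come from regulon membership with the Spearman coefficient annotated.
#' TFs without a receptor edge, and TFs left without targets, are pruned
#' so that every TF in the network lies on a complete
#' receptor->TF->target chain.
#'
#' @param receptors character vector of ESDEG receptor genes (>= 1).
#' @param regulons a `regulon_set` inferred on the same cells.
#' @param norm genes x cells normalized matrix.
#' @param rho_min minimum |Spearman| for receptor-TF edges (default 0.3).
#' @param alpha BH-adjusted p threshold (default 0.05).
#' @return data.frame (class `cascade_network`) with `source`, `target`,
#'   `layer` (receptor-tf / tf-target), `rho`, `p_adj`; empty with a
#'   warning when no edge survives.
#' @export
build_cascade <- function(receptors, regulons, norm, rho_min = 0.3,
                          alpha = 0.05) {
  receptors <- intersect(receptors, rownames(norm))
  if (!length(receptors)) stop("validation error: no receptor present")
  tfs <- intersect(names(regulons), rownames(norm))
  pairs <- expand.grid(receptor = receptors, tf = tfs,
                       stringsAsFactors = FALSE)
  if (!nrow(pairs)) {
    warning("no candidate receptor-TF pair")
    return(structure(data.frame(), class = c("cascade_network", "data.frame")))
  }
  ct <- lapply(seq_len(nrow(pairs)), function(i)
    suppressWarnings(stats::cor.test(norm[pairs$receptor[i], ],
                                     norm[pairs$tf[i], ],
                                     method = "spearman", exact = FALSE)))
  pairs$rho <- vapply(ct, function(x) unname(x$estimate), 1)
  pairs$p_adj <- stats::p.adjust(vapply(ct, function(x) x$p.value, 1), "BH")
  pairs$rho[is.na(pairs$rho)] <- 0
  keep <- abs(pairs$rho) >= rho_min & pairs$p_adj < alpha
  keep[is.na(keep)] <- FALSE
  rt <- pairs[keep, , drop = FALSE]
  if (!nrow(rt)) {
    warning("no surviving receptor-TF edge")
    return(structure(data.frame(), class = c("cascade_network", "data.frame")))
  }
  edges <- data.frame(source = rt$receptor, target = rt$tf,
                      layer = "receptor-tf", rho = rt$rho, p_adj = rt$p_adj,
                      stringsAsFactors = FALSE)
  tt <- do.call(rbind, lapply(unique(rt$tf), function(tf) {
    targets <- intersect(regulons[[tf]]$targets, rownames(norm))
    if (!length(targets)) return(NULL)
    rho <- vapply(targets, function(g)
      stats::cor(norm[tf, ], norm[g, ], method = "spearman"), 1)
    data.frame(source = tf, target = targets, layer = "tf-target",
               rho = rho, p_adj = NA_real_, stringsAsFactors = FALSE)
  }))
  if (is.null(tt)) {
    warning("no surviving TF-target edge")
    return(structure(data.frame(), class = c("cascade_network", "data.frame")))
  }
  ## prune TFs without any surviving target edge
  with_targets <- unique(tt$source)
  edges <- edges[edges$target %in% with_targets, , drop = FALSE]
  out <- rbind(edges, tt[tt$source %in% edges$target, , drop = FALSE])
  rownames(out) <- NULL
  class(out) <- c("cascade_network", "data.frame")
  out
}

#' @export
print.cascade_network <- function(x, ...) {
  if (!nrow(x)) { cat("cascade_network: empty\n"); return(invisible(x)) }
  cat(sprintf("cascade_network: %d receptor-TF edges, %d TF-target edges\n",
              sum(x$layer == "receptor-tf"), sum(x$layer == "tf-target")))
  invisible(x)
}
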