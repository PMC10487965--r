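## Moderated differential scoring of pathways, re-clustering in pathway-
## score space, and health-dominant vs disease-dominant classification.

## Newton inversion of the trigamma function (solve trigamma(x) = y, y > 0)
trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (!is.finite(yi) || yi <= 0) return(Inf)
    if (yi > 1e7) return(1 / sqrt(yi))
    if (yi < 1e-6) return(1 / yi)
    x <- 0.5 + 1 / yi
    for (it in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, 2L)
      x <- x + dif
      if (abs(dif) / x < 1e-10) break
    }
    x
  }, 1)
}

#' Empirical-Bayes moderated two-group differential test
#'
#' Fits a per-feature two-group linear model and shrinks the residual
#' variances towards a common prior: the sample variances are modelled as
#' scaled F (equivalently, log variances as shifted log-chi-square), and the
#' prior degrees of freedom d0 and prior variance s0^2 are estimated by
#' moment matching on the log scale (trigamma inversion). The posterior
#' variance is `(d0*s0^2 + d*s^2) / (d0 + d)` and the moderated t-statistic
#' is referred to a t distribution on `d0 + d` degrees of freedom. As
#' `d0 -> 0` the statistic reduces to the ordinary pooled two-sample t.
#'
#' The significance rule mirrors the pathway-level convention: BH-adjusted
#' p < 0.05 and |log2FC| > 0.5, where log2FC is the difference of group
#' means (scores are already on an additive scale).
#'
#' @param scores features x samples matrix (e.g. pathway scores x cells).
#' @param groups two-level factor/character vector (reference level first);
#'   each group needs >= 2 samples.
#' @param prior_df optional fixed prior degrees of freedom overriding the
#'   empirical estimate (0 gives the ordinary pooled t).
#' @param p_cut,lfc_cut thresholds of the significance flag.
#' @return data.frame (class `moderated_diff_result`) with per-feature
#'   `log2fc`, group means, `t`, `p`, `p_adj`, `s2_post`, `significant`;
#'   the estimated `d0` and `s0_sq` are attributes.
#' @export
moderated_diff <- function(scores, groups, prior_df = NULL, p_cut = 0.05,
                           lfc_cut = 0.5) {
  scores <- as.matrix(scores)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("validation error: groups must have 2 levels")
  g1 <- which(groups == levels(groups)[1L])
  g2 <- which(groups == levels(groups)[2L])
  if (length(g1) < 2L || length(g2) < 2L)
    stop("validation error: each group needs >= 2 samples")
  n1 <- length(g1); n2 <- length(g2)
  d <- n1 + n2 - 2L
  m1 <- rowMeans(scores[, g1, drop = FALSE])
  m2 <- rowMeans(scores[, g2, drop = FALSE])
  v1 <- apply(scores[, g1, drop = FALSE], 1L, stats::var)
  v2 <- apply(scores[, g2, drop = FALSE], 1L, stats::var)
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d
  ok <- s2 > 0
  if (is.null(prior_df)) {
    if (sum(ok) >= 2L) {
      e <- log(s2[ok]) - digamma(d / 2) + log(d / 2)
      evar <- stats::var(e)
      t2 <- evar - trigamma(d / 2)
      if (is.finite(t2) && t2 > 0) {
        d0 <- 2 * trigamma_inverse(t2)
        s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
      } else {
        ## variances no more spread than chi-square sampling alone:
        ## the prior absorbs everything
        d0 <- Inf
        s0_sq <- mean(s2[ok])
      }
    } else {
      d0 <- 0; s0_sq <- mean(s2)
    }
  } else {
    d0 <- prior_df
    s0_sq <- if (sum(ok)) mean(s2[ok]) else 1
  }
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else
    (d0 * s0_sq + d * s2) / (d0 + d)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- ifelse(se > 0, (m2 - m1) / se, 0)
  df_total <- d0 + d
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  lfc <- m2 - m1
  ## constant features in both groups: no evidence, flat call
  const <- !ok & (m1 == m2)
  p[const] <- 1; tstat[const] <- 0; lfc[const] <- 0
  p_adj <- stats::p.adjust(p, "BH")
  if (is.null(rownames(scores)))
    rownames(scores) <- sprintf("feature_%d", seq_len(nrow(scores)))
  out <- data.frame(feature = rownames(scores), log2fc = lfc, mean_1 = m1,
                    mean_2 = m2, t = tstat, p = p, p_adj = p_adj,
                    s2_post = s2_post,
                    significant = p_adj < p_cut & abs(lfc) > lfc_cut,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  attr(out, "df_residual") <- d
  class(out) <- c("moderated_diff_result", "data.frame")
  out
}

#' @export
print.moderated_diff_result <- function(x, ...) {
  cat(sprintf("moderated_diff_result: %d features, %d significant (d0 = %.3g)\n",
              nrow(x), sum(x$significant), attr(x, "d0")))
  invisible(x)
}

#' Re-cluster cells in pathway-score space
#'
#' Feature-wise standardisation, PCA to `dims` components, a shared-
#' nearest-neighbour graph (k = 20, Jaccard-weighted, pruned below 1/15)
#' and modularity community detection at the given resolution with a fixed
#' seed. Cluster ids are 0..K-1 by decreasing size.
#'
#' @param scores features x cells matrix restricted to significant pathways
#'   (>= 2 features).
#' @param dims number of principal components (<= feature count, else a
#'   validation error — mirroring cell types with too few significant
#'   pathways to cluster).
#' @param resolution modularity resolution.
#' @param snn_k neighbourhood size (default 20).
#' @param prune Jaccard threshold below which SNN edges are dropped.
#' @param seed community-detection seed.
#' @return integer vector of cluster ids (0-based), named by cell.
#' @export
recluster_on_scores <- function(scores, dims, resolution, snn_k = 20L,
                                prune = 1 / 15, seed = 42L) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2L) stop("validation error: need >= 2 significant pathways")
  if (dims > nrow(scores))
    stop("validation error: dims exceeds significant-pathway count")
  n <- ncol(scores)
  z <- t(apply(scores, 1L, function(x) {
    s <- stats::sd(x); if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
  if (all(z == 0))  # all cells identical in score space
    return(setNames(rep(0L, n), colnames(scores)))
  dims <- min(dims, n - 1L)
  pcs <- stats::prcomp(t(z), center = TRUE, scale. = FALSE)$x
  pcs <- pcs[, seq_len(min(dims, ncol(pcs))), drop = FALSE]
  k <- min(snn_k, n - 1L)
  d <- as.matrix(stats::dist(pcs))
  nn <- lapply(seq_len(n), function(i) order(d[i, ])[seq_len(k + 1L)])  # incl self
  adj <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ni <- nn[[i]]
    for (j in ni[ni > i]) {
      jac <- length(intersect(ni, nn[[j]])) / length(union(ni, nn[[j]]))
      if (jac >= prune) adj[i, j] <- adj[j, i] <- jac
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  mem <- igraph::membership(cl)
  ## cells isolated by SNN pruning end up as singleton communities; group
  ## them with the cluster of their nearest non-singleton cell (the cited
  ## toolchain's group-singletons convention)
  sizes0 <- table(mem)
  singletons <- which(mem %in% as.integer(names(sizes0)[sizes0 == 1L]))
  if (length(singletons) && length(singletons) < n) {
    keepers <- setdiff(seq_len(n), singletons)
    for (i in singletons)
      mem[i] <- mem[keepers[which.min(d[i, keepers])]]
  }
  sizes <- sort(table(mem), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes) - 1L, names(sizes))
  setNames(as.integer(relabel[as.character(mem)]), colnames(scores))
}

#' Classify clusters as health-dominant (HDC) or disease-dominant (DDC)
#'
#' For each cluster the per-sample fraction of that sample's cells falling
#' in the cluster is computed; Ctrl and DKD sample fractions are compared
#' with an unpaired two-sided t-test. Clusters with a higher DKD mean and
#' p < alpha are labelled DDC (all such clusters pooled); the remaining
#' clusters are HDC. With no significant cluster the cell type is marked
#' unclassified and labels are NA.
#'
#' @param clusters named (by barcode) cluster ids from
#'   [recluster_on_scores()].
#' @param cell_meta data.frame with `barcode`, `sample_id`, `group`
#'   (two groups, >= 2 samples each).
#' @param groups the two group labels, reference (Ctrl-like) first.
#' @param alpha significance level of the dominance test (default 0.05).
#' @return list (class `subcluster_assignment`): `label` named per-cell
#'   HDC/DDC vector, `cluster_table` per-cluster stats, `classified` flag.
#' @export
classify_dominance <- function(clusters, cell_meta,
                               groups = c("Ctrl", "DKD"), alpha = 0.05) {
  meta <- cell_meta[match(names(clusters), cell_meta$barcode), ]
  if (!all(groups %in% meta$group))
    stop("validation error: both groups must be present")
  samples <- unique(meta$sample_id)
  grp_of <- meta$group[match(samples, meta$sample_id)]
  if (min(table(grp_of)) < 2L)
    stop("validation error: need >= 2 samples per group")
  ids <- sort(unique(clusters))
  tab <- do.call(rbind, lapply(ids, function(cl) {
    frac <- vapply(samples, function(s) {
      in_s <- meta$sample_id == s
      mean(clusters[in_s] == cl)
    }, 1)
    f1 <- frac[grp_of == groups[1L]]   # Ctrl-like
    f2 <- frac[grp_of == groups[2L]]   # DKD-like
    p <- tryCatch(stats::t.test(f1, f2)$p.value, error = function(e) {
      if (isTRUE(all.equal(mean(f1), mean(f2)))) 1 else 0  # degenerate: constant fractions
    })
    data.frame(cluster = cl, mean_frac_1 = mean(f1), mean_frac_2 = mean(f2),
               p = p, stringsAsFactors = FALSE)
  }))
  tab$ddc <- tab$p < alpha & tab$mean_frac_2 > tab$mean_frac_1
  classified <- any(tab$ddc)
  label <- if (classified) {
    ifelse(clusters %in% tab$cluster[tab$ddc], "DDC", "HDC")
  } else rep(NA_character_, length(clusters))
  names(label) <- names(clusters)
  structure(list(label = label, cluster_table = tab, classified = classified,
                 groups = groups),
            class = "subcluster_assignment")
}

#' @export
print.subcluster_assignment <- function(x, ...) {
  if (x$classified) {
    cat(sprintf("subcluster_assignment: %d DDC / %d HDC cells\n",
                sum(x$label == "DDC"), sum(x$label == "HDC")))
  } else cat("subcluster_assignment: unclassified (no significant cluster)\n")
  print(x$cluster_table)
  invisible(x)
}
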