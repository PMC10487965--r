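## Per-cell gene-set scoring: kernel-CDF random-walk scores (GSVA-style),
## single-sample enrichment (ssGSEA-style), additive module scores and
## cell-cycle phase calls.

## intersect a collection with the measured genes; drop sets that keep <2
prepare_sets <- function(sets, genes) {
  kept <- lapply(sets, function(s) intersect(s, genes))
  drop <- lengths(kept) < 2L
  if (any(drop))
    warning("sets dropped (<2 genes in matrix): ",
            paste(names(kept)[drop], collapse = ", "))
  kept <- kept[!drop]
  if (!length(kept)) stop("validation error: no gene set survives intersection")
  kept
}

## gene-wise kernel CDF statistic across cells
kcdf_stat <- function(expr, kcdf = c("gaussian", "poisson")) {
  kcdf <- match.arg(kcdf)
  n <- ncol(expr)
  z <- matrix(0, nrow(expr), n, dimnames = dimnames(expr))
  for (i in seq_len(nrow(expr))) {
    x <- expr[i, ]
    if (kcdf == "gaussian") {
      h <- stats::sd(x) / 4
      if (!is.finite(h) || h == 0) next  # zero-variance gene: statistic 0
      z[i, ] <- rowMeans(stats::pnorm(outer(x, x, "-") / h))
    } else {
      z[i, ] <- rowMeans(stats::ppois(matrix(x, n, n),
                                      lambda = matrix(x + 0.5, n, n, byrow = TRUE)))
    }
  }
  z
}

## per-cell weighted KS-like random walk over an ordering; returns one score
## per set. inc: sets x genes 0/1 membership (columns in walk order),
## w: per-position weights.
ks_walk <- function(member_ord, w_ord, max_diff) {
  p <- ncol(member_ord)
  set_sizes <- rowSums(member_ord)
  in_w <- member_ord * rep(w_ord, each = nrow(member_ord))
  sum_in <- rowSums(in_w)
  cum_in <- t(apply(in_w, 1L, cumsum)) / pmax(sum_in, .Machine$double.eps)
  cum_out <- t(apply(1 - member_ord, 1L, cumsum)) / pmax(p - set_sizes, 1L)
  nu <- cum_in - cum_out
  if (max_diff) {
    apply(nu, 1L, function(v) max(c(v, 0))) + apply(nu, 1L, function(v) min(c(v, 0)))
  } else {
    apply(nu, 1L, function(v) v[which.max(abs(v))])
  }
}

#' Kernel-CDF random-walk pathway scores per cell (GSVA-style)
#'
#' Per gene, a kernel estimate of the expression CDF across cells (Gaussian
#' kernel, bandwidth = gene sd / 4; a Poisson kernel is available for raw
#' counts). Per cell, genes are ranked by this statistic (ties broken by
#' gene identifier), rank scores are symmetrised around zero, and a
#' weighted Kolmogorov-Smirnov-like random walk with weight `|rank|^tau` is
#' evaluated over each set. With `max_diff` the score is the maximum
#' positive deviation plus the minimum negative deviation of the walk,
#' otherwise the maximum-magnitude deviation. A set containing every
#' measured gene carries no discriminative information and scores 0.
#'
#' @param expr genes x cells normalized expression matrix (>= 2 cells).
#' @param sets a [gene_set_collection()]; sets are intersected with the
#'   matrix genes and sets keeping < 2 genes dropped with a warning.
#' @param kcdf kernel for the CDF statistic: `"gaussian"` (default, for
#'   log-normalized input) or `"poisson"` (for counts).
#' @param tau rank-weight exponent (default 1).
#' @param max_diff use the two-sided deviation sum (default TRUE).
#' @return sets x cells score matrix (class `pathway_scores`), bounded in
#'   \[-1, 1\].
#' @export
gsva_scores <- function(expr, sets, kcdf = "gaussian", tau = 1, max_diff = TRUE) {
  if (ncol(expr) < 2L) stop("validation error: need >= 2 cells")
  kept <- prepare_sets(sets, rownames(expr))
  z <- kcdf_stat(expr, kcdf)
  p <- nrow(expr)
  member <- do.call(rbind, lapply(kept, function(s) rownames(expr) %in% s))
  sym <- abs(seq_len(p) - (p + 1) / 2)   # symmetric rank value by position
  w <- sym^tau
  scores <- matrix(0, length(kept), ncol(expr),
                   dimnames = list(names(kept), colnames(expr)))
  full <- rowSums(member) == p           # degenerate whole-universe sets
  for (j in seq_len(ncol(expr))) {
    ord <- order(-z[, j], rownames(expr))
    scores[, j] <- ks_walk(member[, ord, drop = FALSE], w, max_diff)
  }
  scores[full, ] <- 0
  structure(scores, method = "gsva",
            params = list(kcdf = kcdf, tau = tau, max_diff = max_diff),
            class = c("pathway_scores", class(scores)))
}

#' Single-sample enrichment scores per cell (ssGSEA-style)
#'
#' Per cell, genes are ranked by expression (descending; ties broken by
#' gene identifier) with rank value p for the most expressed gene. The
#' score of a set is the sum over all positions of the difference between
#' the weighted in-set ECDF (weight `rank^alpha`) and the uniform out-set
#' ECDF. With `normalize` the whole matrix is divided by its range.
#'
#' @param expr genes x cells normalized expression matrix (>= 2 cells).
#' @param sets a [gene_set_collection()].
#' @param alpha rank-weight exponent (default 0.25).
#' @param normalize divide scores by (max - min) over all cells and sets
#'   (default TRUE).
#' @return sets x cells score matrix (class `pathway_scores`).
#' @export
ssgsea_scores <- function(expr, sets, alpha = 0.25, normalize = TRUE) {
  if (ncol(expr) < 2L) stop("validation error: need >= 2 cells")
  kept <- prepare_sets(sets, rownames(expr))
  p <- nrow(expr)
  member <- do.call(rbind, lapply(kept, function(s) rownames(expr) %in% s))
  full <- rowSums(member) == p
  scores <- matrix(0, length(kept), ncol(expr),
                   dimnames = list(names(kept), colnames(expr)))
  w_pos <- (p:1)^alpha                   # rank value p at the top position
  for (j in seq_len(ncol(expr))) {
    ord <- order(-expr[, j], rownames(expr))
    mo <- member[, ord, drop = FALSE]
    in_w <- mo * rep(w_pos, each = nrow(mo))
    cum_in <- t(apply(in_w, 1L, cumsum)) /
      pmax(rowSums(in_w), .Machine$double.eps)
    cum_out <- t(apply(1 - mo, 1L, cumsum)) / pmax(p - rowSums(mo), 1L)
    scores[, j] <- rowSums(cum_in - cum_out)
  }
  scores[full, ] <- 0
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  structure(scores, method = "ssgsea",
            params = list(alpha = alpha, normalize = normalize),
            class = c("pathway_scores", class(scores)))
}

#' Additive module score against expression-matched controls
#'
#' Score = mean(signature genes) - mean(control genes), where controls are
#' drawn per expression bin (`n_ctrl` per signature gene, bins by average
#' expression across cells).
#'
#' @param expr genes x cells normalized matrix.
#' @param signature character vector of signature genes.
#' @param n_bins,n_ctrl binning and control-pool parameters.
#' @param seed seed for the control draw.
#' @return named per-cell score vector.
#' @export
module_score <- function(expr, signature, n_bins = 25L, n_ctrl = 100L,
                         seed = 42L) {
  sig <- intersect(signature, rownames(expr))
  if (!length(sig))
    stop("validation error: signature entirely absent from matrix")
  set.seed(seed)
  mu <- rowMeans(expr)
  bins <- cut(rank(mu, ties.method = "first"),
              breaks = min(n_bins, nrow(expr)), labels = FALSE)
  names(bins) <- rownames(expr)
  ctrl <- unique(unlist(lapply(sig, function(g) {
    pool <- setdiff(names(bins)[bins == bins[g]], sig)
    if (!length(pool)) return(character())
    sample(pool, min(n_ctrl, length(pool)))
  })))
  s <- colMeans(expr[sig, , drop = FALSE])
  ctrl_mean <- if (length(ctrl)) colMeans(expr[ctrl, , drop = FALSE]) else 0
  s - ctrl_mean
}

#' Cell-cycle phase scores and calls
#'
#' Computes S and G2M module scores ([module_score()]) and assigns each
#' cell the phase of the larger score when either is positive, else G1.
#'
#' @param expr genes x cells normalized matrix.
#' @param s_genes,g2m_genes phase signatures.
#' @param n_bins,n_ctrl,seed passed to [module_score()].
#' @return data.frame (class `cell_cycle_call`) with `barcode`, `s_score`,
#'   `g2m_score`, `phase`.
#' @export
cell_cycle_score <- function(expr, s_genes, g2m_genes, n_bins = 25L,
                             n_ctrl = 100L, seed = 42L) {
  s <- module_score(expr, s_genes, n_bins, n_ctrl, seed)
  g2m <- module_score(expr, g2m_genes, n_bins, n_ctrl, seed)
  phase <- ifelse(s <= 0 & g2m <= 0, "G1", ifelse(g2m > s, "G2M", "S"))
  out <- data.frame(barcode = colnames(expr), s_score = s, g2m_score = g2m,
                    phase = phase, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("cell_cycle_call", "data.frame")
  out
}
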