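## Normalisation, mitochondrial content, doublet scoring and marker finding.

as_counts <- function(x) {
  if (inherits(x, "count_matrix")) as.matrix(x$counts) else as.matrix(x)
}

#' Library-size log-normalisation
#'
#' `value = ln(1 + count / cell_total * scale)` — the standard counts-per-
#' ten-thousand log transform used throughout the pipeline.
#'
#' @param x a [count_matrix()] or genes x cells count matrix.
#' @param scale counts-per-cell target (default 1e4).
#' @return dense genes x cells matrix of normalized expression.
#' @export
normalize_log <- function(x, scale = 1e4) {
  m <- as_counts(x)
  totals <- colSums(m)
  if (any(totals == 0))
    stop("validation error: all-zero cells: ",
         paste(utils::head(colnames(m)[totals == 0], 5L), collapse = ", "))
  log1p(sweep(m, 2L, totals, "/") * scale)
}

#' Percentage of mitochondrially encoded mRNA (PMEM) per cell
#'
#' 100 x (UMI counts on the 13 mitochondrially encoded mRNA genes) / (total
#' UMI counts of the cell).
#'
#' @param x a [count_matrix()].
#' @param catalog a `gene_catalog` with `is_mito_mrna` flags.
#' @return named numeric vector of per-cell percentages in \[0, 100\].
#' @export
compute_pmem <- function(x, catalog) {
  m <- as_counts(x)
  mito <- intersect(catalog$symbol[catalog$is_mito_mrna], rownames(m))
  if (!length(mito))
    stop("validation error: no mitochondrial mRNA gene present in the matrix")
  totals <- colSums(m)
  if (any(totals == 0)) stop("validation error: zero-total cell")
  100 * colSums(m[mito, , drop = FALSE]) / totals
}

#' Summarise PMEM by cell type with rank-sum comparisons
#'
#' For each cell type, the mean/median PMEM and a two-sided rank-sum
#' (Mann-Whitney) p-value of that type's cells against all remaining cells.
#'
#' @param pmem per-cell percentages from [compute_pmem()].
#' @param cell_type per-cell type labels (parallel to `pmem`).
#' @return data.frame with one row per cell type.
#' @export
pmem_summary <- function(pmem, cell_type) {
  stopifnot(length(pmem) == length(cell_type))
  types <- sort(unique(cell_type))
  out <- do.call(rbind, lapply(types, function(tp) {
    a <- pmem[cell_type == tp]; b <- pmem[cell_type != tp]
    p <- if (length(b)) stats::wilcox.test(a, b)$p.value else NA_real_
    data.frame(cell_type = tp, n = length(a), mean = mean(a),
               median = stats::median(a), p_vs_rest = p,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

## variable-gene selection: dispersion standardized within mean bins
variable_genes <- function(norm, n = 2000L, n_bins = 20L) {
  mu <- rowMeans(norm)
  v <- apply(norm, 1L, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  bins <- cut(rank(mu, ties.method = "first"), breaks = n_bins, labels = FALSE)
  z <- disp
  for (b in unique(bins)) {
    i <- bins == b
    s <- stats::sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  names(sort(z, decreasing = TRUE))[seq_len(min(n, nrow(norm)))]
}

#' Doublet scoring by artificial nearest neighbours (pANN)
#'
#' Simulates artificial doublets as averaged normalized profiles of random
#' cell pairs, embeds real and artificial cells together by PCA, and scores
#' each real cell by the fraction of its k nearest neighbours (Euclidean,
#' principal-component space) that are artificial. Cells in the top
#' `expected_rate` quantile of pANN are called doublets.
#'
#' @param x a [count_matrix()] or count matrix (>= 20 cells).
#' @param pN artificial doublets generated as a fraction of the real cell
#'   count (default 0.25).
#' @param pK neighbourhood size as a fraction of the merged (real +
#'   artificial) cell count; `k = max(1, round(pK * merged_n))`.
#' @param dims number of principal components (must not exceed the feasible
#'   rank).
#' @param expected_rate expected doublet rate used for calling (default
#'   0.075, the usual droplet-loading convention).
#' @param n_var_genes number of variable genes for the PCA.
#' @param seed RNG seed for pair sampling.
#' @return data.frame (class `doublet_result`) with `barcode`, `pANN` in
#'   \[0,1\] and `call` (singlet/doublet); parameters kept as attributes.
#' @export
detect_doublets <- function(x, pN = 0.25, pK = 0.1, dims = 10,
                            expected_rate = 0.075, n_var_genes = 2000L,
                            seed = 42L) {
  m <- as_counts(x)
  n <- ncol(m)
  if (n < 20L) stop("validation error: need at least 20 cells")
  if (dims > min(n_var_genes, nrow(m), n) - 1L)
    stop("validation error: dims exceeds feasible rank")
  set.seed(seed)
  ## artificial doublets: averaged raw profiles of random cell pairs, so
  ## that after library-size normalisation they coincide with the profile
  ## of a droplet pooling both cells' transcripts
  n_art <- max(2L, round(pN * n))
  i1 <- sample.int(n, n_art, replace = TRUE)
  i2 <- vapply(i1, function(i) sample(setdiff(seq_len(n), i), 1L), 1L)
  art <- (m[, i1, drop = FALSE] + m[, i2, drop = FALSE]) / 2
  colnames(art) <- sprintf(".art_%d", seq_len(n_art))
  merged <- normalize_log(cbind(m, art))
  vg <- variable_genes(merged[, seq_len(n), drop = FALSE], n_var_genes)
  merged <- merged[vg, , drop = FALSE]
  pcs <- stats::prcomp(t(merged), center = TRUE, scale. = FALSE)$x[, seq_len(dims), drop = FALSE]
  k <- max(1L, round(pK * ncol(merged)))
  d <- as.matrix(stats::dist(pcs))
  is_art <- c(rep(FALSE, n), rep(TRUE, n_art))
  pann <- vapply(seq_len(n), function(i) {
    nn <- order(d[i, -i])[seq_len(k)]
    mean(is_art[-i][nn])
  }, 1)
  n_call <- round(expected_rate * n)
  call <- rep("singlet", n)
  if (n_call > 0) call[order(-pann)[seq_len(n_call)]] <- "doublet"
  out <- data.frame(barcode = colnames(m), pANN = pann, call = call,
                    stringsAsFactors = FALSE)
  attr(out, "params") <- list(pN = pN, pK = pK, dims = dims,
                              expected_rate = expected_rate, k = k)
  class(out) <- c("doublet_result", "data.frame")
  out
}

## vectorized one-vs-rest rank-sum p (normal approximation, tie-corrected,
## continuity-corrected) applied row-wise
rank_sum_p <- function(norm, in_idx) {
  n1 <- length(in_idx); n2 <- ncol(norm) - n1; N <- n1 + n2
  r <- t(apply(norm, 1L, rank))
  W <- rowSums(r[, in_idx, drop = FALSE]) - n1 * (n1 + 1) / 2
  tie_term <- apply(norm, 1L, function(x) {
    tt <- table(x); sum(tt^3 - tt)
  })
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  z <- W - n1 * n2 / 2
  z <- sign(z) * pmax(abs(z) - 0.5, 0) / sqrt(pmax(sigma2, .Machine$double.eps))
  p <- 2 * stats::pnorm(-abs(z))
  p[sigma2 == 0] <- 1
  pmin(p, 1)
}

## log2 fold change of de-logged means with pseudocount 1
log2fc_delogged <- function(norm, in_idx, out_idx) {
  a <- rowMeans(expm1(norm[, in_idx, drop = FALSE]))
  b <- rowMeans(expm1(norm[, out_idx, drop = FALSE]))
  log2((a + 1) / (b + 1))
}

#' One-vs-rest marker genes per label
#'
#' For every label, each gene is tested against all remaining cells with a
#' two-sided rank-sum test; the log2 fold change is computed on de-logged
#' mean normalized expression with a pseudocount of 1. Rows are sorted by
#' ascending p and the `top_k` genes per label retained.
#'
#' @param norm genes x cells normalized matrix ([normalize_log()]).
#' @param labels per-cell labels (>= 2 labels, each with >= 3 cells; smaller
#'   labels are skipped with a warning).
#' @param top_k markers retained per label (default 10, feeding the
#'   deconvolution signature).
#' @return data.frame with `label`, `gene`, `log2fc`, `p`, `p_adj`, `rank`.
#' @export
find_markers <- function(norm, labels, top_k = 10L) {
  labels <- as.character(labels)
  stopifnot(ncol(norm) == length(labels))
  tab <- table(labels)
  if (length(tab) < 2L) stop("validation error: need at least 2 labels")
  use <- names(tab)[tab >= 3L]
  if (length(use) < length(tab))
    warning("labels skipped (<3 cells): ",
            paste(setdiff(names(tab), use), collapse = ", "))
  out <- do.call(rbind, lapply(use, function(lb) {
    in_idx <- which(labels == lb)
    out_idx <- which(labels != lb)
    p <- rank_sum_p(norm, in_idx)
    fc <- log2fc_delogged(norm, in_idx, out_idx)
    d <- data.frame(label = lb, gene = rownames(norm), log2fc = fc, p = p,
                    p_adj = stats::p.adjust(p, "BH"), stringsAsFactors = FALSE)
    d <- d[order(d$p, -abs(d$log2fc)), ]
    d <- utils::head(d, top_k)
    d$rank <- seq_len(nrow(d))
    d
  }))
  rownames(out) <- NULL
  out
}
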