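## TPM computation, signature-based deconvolution of bulk profiles, and
## reference-based HDC/DDC label transfer.

#' Transcripts per million from bulk counts and gene lengths
#'
#' `rate = count / length`; `TPM = rate / sum(rate) * 1e6` per sample, so
#' every column sums to one million.
#'
#' @param counts genes x samples count matrix.
#' @param lengths per-gene lengths (same order; all > 0), any length unit.
#' @return genes x samples TPM matrix.
#' @export
compute_tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (length(lengths) != nrow(counts))
    stop("validation error: one length per gene required")
  if (any(lengths <= 0)) stop("validation error: lengths must be positive")
  rate <- counts / lengths
  sweep(rate, 2L, colSums(rate), "/") * 1e6
}

#' Build a subcluster signature matrix from top markers
#'
#' Mean de-logged normalized expression per subcluster over the union of
#' the top `top_k` one-vs-rest markers of every subcluster.
#'
#' @param norm genes x cells normalized matrix.
#' @param labels per-cell subcluster labels (e.g. "CDPC_HDC").
#' @param top_k markers per subcluster (default 10).
#' @return genes x subclusters signature matrix.
#' @export
build_signature <- function(norm, labels, top_k = 10L) {
  mk <- find_markers(norm, labels, top_k)
  genes <- unique(mk$gene)
  labs <- sort(unique(as.character(labels)))
  sig <- vapply(labs, function(l)
    rowMeans(expm1(norm[genes, labels == l, drop = FALSE])),
    numeric(length(genes)))
  rownames(sig) <- genes
  sig
}

#' Deconvolve bulk profiles against a subcluster signature
#'
#' Non-negative least squares on the shared-gene submatrix followed by
#' renormalisation onto the proportion simplex; the simplex step also makes
#' the estimates invariant to positive rescaling of the bulk profile. A
#' rank-deficient signature triggers a warning and a pseudo-inverse
#' fallback (negative coefficients clamped), flagged in the result.
#'
#' @param bulk genes x samples matrix (e.g. TPM).
#' @param signature genes x subclusters matrix from [build_signature()].
#' @param method `"nnls"` (default) or `"pinv"`.
#' @return list (class `deconvolution_result`): `proportions`
#'   (samples x subclusters, rows on the simplex), `residual` per sample,
#'   `fallback` flag.
#' @export
deconvolve <- function(bulk, signature, method = c("nnls", "pinv")) {
  method <- match.arg(method)
  bulk <- as.matrix(bulk)
  shared <- intersect(rownames(bulk), rownames(signature))
  if (length(shared) < ncol(signature))
    stop("validation error: need at least as many shared genes as subclusters")
  S <- signature[shared, , drop = FALSE]
  B <- bulk[shared, , drop = FALSE]
  fallback <- FALSE
  if (qr(S)$rank < ncol(S) && method == "nnls") {
    warning("rank-deficient signature; falling back to pseudo-inverse")
    method <- "pinv"; fallback <- TRUE
  }
  props <- matrix(0, ncol(B), ncol(S),
                  dimnames = list(colnames(B), colnames(S)))
  resid <- numeric(ncol(B))
  for (j in seq_len(ncol(B))) {
    b <- B[, j] / mean(B[, j])   # unit scale; proportions are scale-free
    x <- if (method == "nnls") pracma::lsqnonneg(S, b)$x else
      pmax(pracma::pinv(S) %*% b, 0)
    resid[j] <- sqrt(sum((b - S %*% x)^2))
    props[j, ] <- if (sum(x) > 0) x / sum(x) else rep(1 / ncol(S), ncol(S))
  }
  structure(list(proportions = props, residual = resid, fallback = fallback,
                 method = method),
            class = "deconvolution_result")
}

#' @export
print.deconvolution_result <- function(x, ...) {
  cat(sprintf("deconvolution_result (%s%s):\n", x$method,
              if (x$fallback) ", fallback" else ""))
  print(round(x$proportions, 3))
  invisible(x)
}

#' Transfer HDC/DDC labels from a reference to a query by rank correlation
#'
#' Variable genes are the union of top pairwise one-vs-rest markers
#' between the reference labels; each query cell is Spearman-correlated
#' with every reference cell over those genes, the per-label score is the
#' 0.8 quantile of the correlations to that label's cells, and the label
#' with the highest score is assigned. Assignments whose score gap to the
#' runner-up is below `gap_min` are flagged low-confidence.
#'
#' @param ref_norm,query_norm genes x cells normalized matrices; shared
#'   genes must number at least `n_top_genes / 2`.
#' @param ref_labels per-reference-cell labels (each >= 3 cells).
#' @param n_top_genes markers per label for the variable-gene union
#'   (default 50).
#' @param gap_min low-confidence threshold on the score gap (default
#'   0.05).
#' @return data.frame with `barcode`, `label`, `score`, `gap`,
#'   `low_confidence`; per-label score matrix as attribute `scores`.
#' @export
transfer_labels <- function(ref_norm, ref_labels, query_norm,
                            n_top_genes = 50L, gap_min = 0.05) {
  ref_labels <- as.character(ref_labels)
  if (min(table(ref_labels)) < 3L)
    stop("validation error: every reference label needs >= 3 cells")
  shared <- intersect(rownames(ref_norm), rownames(query_norm))
  if (length(shared) < n_top_genes / 2)
    stop("validation error: too few shared genes")
  mk <- find_markers(ref_norm[shared, , drop = FALSE], ref_labels,
                     top_k = n_top_genes)
  genes <- unique(mk$gene)
  R <- ref_norm[genes, , drop = FALSE]
  Q <- query_norm[genes, , drop = FALSE]
  cors <- stats::cor(Q, R, method = "spearman")
  cors[is.na(cors)] <- 0
  labs <- sort(unique(ref_labels))
  scores <- vapply(labs, function(l)
    apply(cors[, ref_labels == l, drop = FALSE], 1L, stats::quantile,
          probs = 0.8), numeric(ncol(Q)))
  scores <- matrix(scores, ncol = length(labs),
                   dimnames = list(colnames(Q), labs))
  best <- max.col(scores, ties.method = "first")
  sorted <- t(apply(scores, 1L, sort, decreasing = TRUE))
  gap <- sorted[, 1L] - if (ncol(sorted) > 1L) sorted[, 2L] else 0
  out <- data.frame(barcode = colnames(Q), label = labs[best],
                    score = sorted[, 1L], gap = gap,
                    low_confidence = gap < gap_min,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "scores") <- scores
  out
}
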