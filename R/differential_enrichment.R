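## Gene-level rank-sum differential tests, exclusive-gene (ESDEG)
## partitioning with MANG exclusion, fold-change correlation, and
## hypergeometric over-representation.

#' Per-gene two-group rank-sum differential expression
#'
#' Two-sided Mann-Whitney test per gene (exact enumeration when both groups
#' have <= 8 cells and no ties, normal approximation with tie and
#' continuity correction otherwise) with log2 fold change of de-logged
#' means (pseudocount 1). Significance follows the gene-level rule: raw
#' p < 0.05 and |log2FC| > 0.5; the BH-adjusted column is always emitted so
#' the FDR-based rule is equally reproducible.
#'
#' @param norm genes x cells normalized matrix.
#' @param cells_a,cells_b index/barcode vectors of the two groups (>= 3
#'   cells each; `log2fc` is A relative to B, so swapping groups negates
#'   it).
#' @param p_cut,lfc_cut thresholds of the significance flag.
#' @return data.frame (class `differential_result`) with `gene`, `log2fc`,
#'   `p`, `p_adj`, `significant`.
#' @export
wilcoxon_de <- function(norm, cells_a, cells_b, p_cut = 0.05, lfc_cut = 0.5) {
  a <- norm[, cells_a, drop = FALSE]
  b <- norm[, cells_b, drop = FALSE]
  if (ncol(a) == 0L || ncol(b) == 0L) stop("validation error: empty group")
  if (ncol(a) < 3L || ncol(b) < 3L)
    stop("validation error: both groups need >= 3 cells")
  if (max(ncol(a), ncol(b)) <= 8L) {
    p <- vapply(seq_len(nrow(norm)), function(i)
      suppressWarnings(stats::wilcox.test(a[i, ], b[i, ])$p.value), 1)
  } else {
    p <- rank_sum_p(cbind(a, b), seq_len(ncol(a)))
  }
  p[!is.finite(p)] <- 1
  fc <- log2((rowMeans(expm1(a)) + 1) / (rowMeans(expm1(b)) + 1))
  out <- data.frame(gene = rownames(norm), log2fc = fc, p = p,
                    p_adj = stats::p.adjust(p, "BH"),
                    significant = p < p_cut & abs(fc) > lfc_cut,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("differential_result", "data.frame")
  out
}

#' Partition differential genes into intersection and exclusive sets
#'
#' Removes mitochondria-associated nuclear genes (MANGs) first, then splits
#' the significant genes of the two comparisons (DA1: reference-group HDC
#' vs disease-group DDC; DA2: within-disease HDC vs DDC) into the
#' intersection, DA1-exclusive and DA2-exclusive (= ESDEG) sets. Cell
#' types whose exclusive sets fall below `min_exclusive` genes are flagged
#' discarded.
#'
#' @param da1,da2 `differential_result` objects over the same gene universe.
#' @param catalog a `gene_catalog` with `is_mang` flags.
#' @param min_exclusive minimum exclusive-gene count (default 100).
#' @return list (class `esdeg_partition`) with `intersection`,
#'   `da1_exclusive`, `esdeg` (DA2-exclusive), `counts`, `mang_excluded`,
#'   `discarded`.
#' @export
build_esdeg <- function(da1, da2, catalog, min_exclusive = 100L) {
  if (!setequal(da1$gene, da2$gene))
    stop("validation error: mismatched gene universes")
  mang <- catalog$symbol[catalog$is_mang]
  keep1 <- da1[!da1$gene %in% mang, ]
  keep2 <- da2[!da2$gene %in% mang, ]
  sig1 <- keep1$gene[keep1$significant]
  sig2 <- keep2$gene[keep2$significant]
  inter <- intersect(sig1, sig2)
  ex1 <- setdiff(sig1, sig2)
  ex2 <- setdiff(sig2, sig1)
  counts <- c(intersection = length(inter), da1_exclusive = length(ex1),
              esdeg = length(ex2))
  structure(list(intersection = inter, da1_exclusive = ex1, esdeg = ex2,
                 counts = counts,
                 mang_excluded = intersect(union(da1$gene, da2$gene), mang),
                 discarded = min(length(ex1), length(ex2)) < min_exclusive),
            class = "esdeg_partition")
}

#' @export
print.esdeg_partition <- function(x, ...) {
  cat(sprintf("esdeg_partition: %d intersection, %d DA1-exclusive, %d ESDEG%s\n",
              x$counts["intersection"], x$counts["da1_exclusive"],
              x$counts["esdeg"], if (x$discarded) " [discarded]" else ""))
  invisible(x)
}

#' Correlate fold changes of the intersection genes across two comparisons
#'
#' Pearson correlation with its t-test p-value and a least-squares line
#' fitted by orthogonal-triangular (QR) decomposition.
#'
#' @param fc1,fc2 numeric fold-change vectors over the same >= 3 genes.
#' @return list with `r`, `p`, `slope`, `intercept`, `degenerate` (TRUE
#'   when either vector has zero variance, in which case `r` is NA).
#' @export
correlate_fc <- function(fc1, fc2) {
  stopifnot(length(fc1) == length(fc2))
  if (length(fc1) < 3L) stop("validation error: need >= 3 genes")
  if (stats::sd(fc1) == 0 || stats::sd(fc2) == 0)
    return(list(r = NA_real_, p = NA_real_, slope = NA_real_,
                intercept = NA_real_, degenerate = TRUE))
  ct <- suppressWarnings(stats::cor.test(fc1, fc2))
  fit <- stats::lm(fc2 ~ fc1, method = "qr")
  list(r = unname(ct$estimate), p = ct$p.value,
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]), degenerate = FALSE)
}

#' Hypergeometric over-representation of a query gene list
#'
#' Upper-tail hypergeometric probability of the observed overlap per set,
#' BH adjustment across sets, rows sorted by ascending p with the `top_n`
#' most significant retained.
#'
#' @param query character vector of query genes (must lie in `universe`).
#' @param universe character vector of background genes.
#' @param collection a [gene_set_collection()]; sets are intersected with
#'   the universe.
#' @param top_n rows retained (default 20).
#' @return data.frame (class `enrichment_table`) with set name, `k`
#'   (overlap), `n` (query), `K` (set), `N` (universe), `p`, `p_adj`,
#'   `genes` (comma-separated overlap).
#' @export
hypergeom_enrich <- function(query, universe, collection, top_n = 20L) {
  if (!all(query %in% universe))
    stop("validation error: query must be a subset of the universe")
  query <- unique(query)
  universe <- unique(universe)
  if (!length(query)) {
    warning("empty query after intersection with universe")
    return(structure(data.frame(), class = c("enrichment_table", "data.frame")))
  }
  N <- length(universe)
  rows <- do.call(rbind, lapply(names(collection), function(nm) {
    set <- intersect(collection[[nm]], universe)
    k <- length(intersect(set, query))
    K <- length(set)
    if (!K) return(NULL)
    p <- stats::phyper(k - 1L, K, N - K, length(query), lower.tail = FALSE)
    data.frame(set = nm, k = k, n = length(query), K = K, N = N, p = p,
               genes = paste(intersect(set, query), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    warning("no set overlaps the universe")
    return(structure(data.frame(), class = c("enrichment_table", "data.frame")))
  }
  rows$p_adj <- stats::p.adjust(rows$p, "BH")
  rows <- rows[order(rows$p), ]
  rows <- utils::head(rows, top_n)
  rownames(rows) <- NULL
  class(rows) <- c("enrichment_table", "data.frame")
  rows
}
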