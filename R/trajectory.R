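## Semi-supervised principal-tree pseudotime over exclusive-gene (ESDEG)
## expression, and the HDC/DDC pseudotime-distribution test.

#' Principal-tree pseudotime over ESDEG expression
#'
#' Standardised ESDEG expression is reduced to two principal components,
#' `n_centroids` k-means centroids are fitted (seeded) and joined by their
#' Euclidean minimum spanning tree; every cell is projected to the nearest
#' tree edge and its pseudotime is the geodesic distance from the root
#' along the tree. The root encodes the semi-supervision: with
#' `root_rule = "hdc_max"` it is the leaf whose projected cells have the
#' highest HDC fraction, so pseudotime runs from health towards disease.
#'
#' @param expr genes x cells normalized matrix restricted to ESDEGs (>= 5
#'   genes; >= `n_centroids` x 3 cells).
#' @param labels optional per-cell HDC/DDC labels (required for
#'   `root_rule = "hdc_max"`).
#' @param n_centroids number of principal-tree nodes (default 5).
#' @param root_rule `"hdc_max"` (default) or `"first_leaf"`.
#' @param seed k-means seed.
#' @return list (class `pseudotime_result`): `pseudotime` (named, >= 0,
#'   root extreme at 0), `node` nearest-centroid id per cell, `edges`
#'   (tree edge list with lengths), `centroids`, `root`.
#' @export
fit_pseudotime <- function(expr, labels = NULL, n_centroids = 5L,
                           root_rule = c("hdc_max", "first_leaf"),
                           seed = 42L) {
  root_rule <- match.arg(root_rule)
  expr <- as.matrix(expr)
  if (nrow(expr) < 5L) stop("validation error: need >= 5 ESDEGs")
  if (ncol(expr) < n_centroids * 3L)
    stop("validation error: need >= 3 cells per centroid")
  z <- t(apply(expr, 1L, function(x) {
    s <- stats::sd(x); if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
  emb <- if (all(z == 0)) matrix(0, ncol(expr), 2L) else {
    pc <- stats::prcomp(t(z), center = TRUE, scale. = FALSE)$x
    cbind(pc[, 1L], if (ncol(pc) >= 2L) pc[, 2L] else 0)
  }
  rownames(emb) <- colnames(expr)
  n_distinct <- nrow(unique(emb))
  kk <- min(n_centroids, n_distinct)
  if (kk == 1L) {
    pt <- setNames(rep(0, ncol(expr)), colnames(expr))
    return(structure(list(pseudotime = pt,
                          node = setNames(rep(1L, ncol(expr)), colnames(expr)),
                          edges = data.frame(), centroids = emb[1, , drop = FALSE],
                          root = 1L),
                     class = "pseudotime_result"))
  }
  set.seed(seed)
  km <- stats::kmeans(emb, centers = kk, nstart = 10L, iter.max = 50L)
  cen <- km$centers
  dc <- as.matrix(stats::dist(cen))
  g <- igraph::graph_from_adjacency_matrix(dc, mode = "undirected",
                                           weighted = TRUE)
  tree <- igraph::mst(g)
  el <- igraph::as_edgelist(tree, names = FALSE)
  lens <- igraph::E(tree)$weight
  ## project cells to the nearest tree edge
  proj_edge <- integer(ncol(expr)); proj_t <- numeric(ncol(expr))
  best <- rep(Inf, ncol(expr))
  for (e in seq_len(nrow(el))) {
    a <- cen[el[e, 1L], ]; b <- cen[el[e, 2L], ]
    ab <- b - a; len2 <- sum(ab^2)
    tpar <- if (len2 == 0) rep(0, ncol(expr)) else
      pmin(1, pmax(0, (sweep(emb, 2L, a) %*% ab) / len2))
    px <- outer(as.numeric(tpar), ab) + rep(a, each = nrow(emb))
    dd <- rowSums((emb - px)^2)
    upd <- dd < best
    best[upd] <- dd[upd]; proj_edge[upd] <- e; proj_t[upd] <- tpar[upd]
  }
  ## root selection among leaves
  node <- km$cluster
  deg <- igraph::degree(tree)
  leaves <- which(deg == 1L)
  root <- if (root_rule == "hdc_max" && !is.null(labels)) {
    frac <- vapply(leaves, function(v) {
      cells <- node == v
      if (!any(cells)) return(-1)
      mean(labels[colnames(expr)][cells] == "HDC", na.rm = TRUE)
    }, 1)
    leaves[which.max(frac)]
  } else leaves[1L]
  dist_root <- igraph::distances(tree, v = root)[1L, ]
  pt <- vapply(seq_len(ncol(expr)), function(i) {
    e <- proj_edge[i]
    u <- el[e, 1L]; v <- el[e, 2L]
    tu <- proj_t[i] * lens[e]
    min(dist_root[u] + tu, dist_root[v] + (lens[e] - tu))
  }, 1)
  names(pt) <- colnames(expr)
  structure(list(pseudotime = pt, node = setNames(node, colnames(expr)),
                 edges = data.frame(from = el[, 1L], to = el[, 2L],
                                    length = lens),
                 centroids = cen, root = root),
            class = "pseudotime_result")
}

#' @export
print.pseudotime_result <- function(x, ...) {
  cat(sprintf("pseudotime_result: %d cells, %d tree nodes, root %d, range [0, %.3g]\n",
              length(x$pseudotime), nrow(x$centroids), x$root,
              max(x$pseudotime)))
  invisible(x)
}

#' Compare pseudotime distributions between HDC and DDC cells
#'
#' Two-sided unpaired t-test on the pseudotime values of the two labels
#' plus kernel-density summaries per label for reporting.
#'
#' @param pseudotime named per-cell pseudotime vector.
#' @param labels per-cell HDC/DDC labels (both present, >= 3 cells each).
#' @return list with `t`, `p`, `means` and per-label `density` summaries.
#' @export
compare_time_distributions <- function(pseudotime, labels) {
  labels <- as.character(labels)
  lv <- sort(unique(labels[!is.na(labels)]))   # deterministic comparison order
  if (length(lv) < 2L) stop("validation error: need both labels present")
  a <- pseudotime[labels == lv[1L]]
  b <- pseudotime[labels == lv[2L]]
  if (length(a) < 3L || length(b) < 3L)
    stop("validation error: both labels need >= 3 cells")
  tt <- tryCatch(stats::t.test(a, b), error = function(e) NULL)
  if (is.null(tt)) {
    t_stat <- 0; p <- 1
  } else {
    t_stat <- unname(tt$statistic); p <- tt$p.value
  }
  dens <- lapply(setNames(lv, lv), function(l) {
    x <- pseudotime[labels == l]
    d <- stats::density(x)
    list(mean = mean(x), median = stats::median(x), bw = d$bw,
         mode = d$x[which.max(d$y)])
  })
  list(t = t_stat, p = p,
       means = c(setNames(mean(a), lv[1L]), setNames(mean(b), lv[2L])),
       density = dens)
}
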