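# Independent brute-force oracles, written against the published
# definitions and kept loop-wise/step-by-step so they share no code path
# with the package implementations they check.

# kernel-CDF random-walk score of one set in every cell, one step at a time
oracle_gsva <- function(expr, set, tau = 1, max_diff = TRUE) {
  p <- nrow(expr); n <- ncol(expr)
  z <- matrix(0, p, n, dimnames = dimnames(expr))
  for (i in seq_len(p)) {
    h <- sd(expr[i, ]) / 4
    if (is.finite(h) && h > 0)
      for (j in seq_len(n))
        z[i, j] <- mean(pnorm((expr[i, j] - expr[i, ]) / h))
  }
  vapply(seq_len(n), function(j) {
    ord <- order(-z[, j], rownames(expr))
    memb <- rownames(expr)[ord] %in% set
    w <- abs(seq_len(p) - (p + 1) / 2)^tau
    sw <- sum(w[memb]); nout <- p - sum(memb)
    nu <- numeric(p); cin <- 0; cout <- 0
    for (k in seq_len(p)) {
      if (memb[k]) cin <- cin + w[k] / sw else cout <- cout + 1 / nout
      nu[k] <- cin - cout
    }
    if (max_diff) max(c(nu, 0)) + min(c(nu, 0)) else nu[which.max(abs(nu))]
  }, 1)
}

# single-sample enrichment running sum for one cell, evaluated directly
oracle_ssgsea <- function(expr_col, genes, set, alpha = 0.25) {
  p <- length(expr_col)
  ord <- order(-expr_col, genes)
  memb <- genes[ord] %in% set
  w <- (p:1)^alpha
  total <- 0; cin <- 0; cout <- 0
  sw <- sum(w[memb]); nout <- p - sum(memb)
  for (k in seq_len(p)) {
    if (memb[k]) cin <- cin + w[k] / sw else cout <- cout + 1 / nout
    total <- total + (cin - cout)
  }
  total
}

# trapezoid area under the recovery curve of `set` genes among the top
# `top` ranks of one cell, normalized by the best achievable curve
oracle_aucell <- function(expr_col, genes, set, top) {
  ord <- order(-expr_col)
  hits <- genes[ord][seq_len(top)] %in% set
  y <- cumsum(hits)
  auc <- 0
  for (k in seq_len(top)) auc <- auc + (if (k == 1) y[1] / 2 else (y[k - 1] + y[k]) / 2)
  m <- min(sum(genes %in% set), top)
  ybest <- pmin(seq_len(top), m)
  best <- 0
  for (k in seq_len(top)) best <- best + (if (k == 1) ybest[1] / 2 else (ybest[k - 1] + ybest[k]) / 2)
  auc / best
}

# Benjamini-Hochberg from the direct formula p * m / rank with
# cumulative-min enforcement from the largest p down
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# AUROC by the rank-sum formula (probability a positive outranks a negative)
oracle_auroc <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
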