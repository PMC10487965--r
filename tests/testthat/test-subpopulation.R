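test_that("moderated t vanishes for equal groups and reduces to pooled t as d0 -> 0", {
  set.seed(1)
  x <- matrix(rnorm(20 * 12), 20, 12,
              dimnames = list(sprintf("f%02d", 1:20), NULL))
  g <- rep(c("A", "B"), each = 6)
  x_eq <- x
  x_eq[1, ] <- rep(c(1, 2, 3, 4, 5, 6), 2)  # identical group samples
  res <- moderated_diff(x_eq, g)
  expect_equal(res$t[1], 0)
  expect_equal(res$p[1], 1)

  # d0 -> 0 limit equals the ordinary pooled two-sample t
  res0 <- moderated_diff(x, g, prior_df = 0)
  pooled <- apply(x, 1, function(r) {
    a <- r[1:6]; b <- r[7:12]
    sp <- sqrt(((5 * var(a) + 5 * var(b)) / 10) * (1 / 6 + 1 / 6))
    (mean(b) - mean(a)) / sp
  })
  expect_equal(res0$t, unname(pooled), tolerance = 1e-8)
  tt <- t.test(x[3, 7:12], x[3, 1:6], var.equal = TRUE)
  expect_equal(res0$p[3], tt$p.value, tolerance = 1e-8)
})

test_that("moderated test matches the established empirical-Bayes fit", {
  skip_if_not_installed("limma")
  # genuinely heterogeneous variances: finite prior df
  set.seed(2)
  scales <- sqrt(1 / rgamma(50, shape = 2, rate = 2))
  x <- matrix(rnorm(50 * 16), 50, 16) * scales
  rownames(x) <- sprintf("f%02d", 1:50)
  g <- rep(c("A", "B"), each = 8)
  mine <- moderated_diff(x, g)
  design <- cbind(1, g == "B")
  fit <- limma::eBayes(limma::lmFit(x, design))
  expect_true(is.finite(attr(mine, "d0")))
  expect_equal(attr(mine, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(mine, "s0_sq"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(mine$t, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(mine$p, unname(fit$p.value[, 2]), tolerance = 1e-8)

  # homogeneous variances: the prior absorbs everything (infinite prior df)
  set.seed(3)
  x2 <- matrix(rnorm(50 * 16), 50, 16,
               dimnames = list(sprintf("f%02d", 1:50), NULL))
  mine2 <- moderated_diff(x2, g)
  fit2 <- limma::eBayes(limma::lmFit(x2, design))
  expect_equal(attr(mine2, "d0"), fit2$df.prior)
  expect_equal(attr(mine2, "s0_sq"), fit2$s2.prior, tolerance = 1e-8)
  expect_equal(mine2$t, unname(fit2$t[, 2]), tolerance = 1e-8)
})

test_that("moderated test attains the planted sensitivity and FDR control", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    x <- matrix(rnorm(200 * 60), 200, 60,
                dimnames = list(sprintf("f%03d", 1:200), NULL))
    g <- rep(c("A", "B"), each = 30)
    x[1:20, g == "B"] <- x[1:20, g == "B"] + 1  # 10% shifted by 1 sd
    res <- moderated_diff(x, g)
    c(sens = mean(res$significant[1:20]),
      fpr = mean(res$significant[21:200]))
  }, c(sens = 1, fpr = 1))
  expect_gte(mean(hits["sens", ]), 0.8)
  expect_lte(mean(hits["fpr", ]), 0.05)
})

test_that("BH adjustment equals the direct formula and preserves order", {
  set.seed(4)
  p <- runif(40)^2
  x <- matrix(rnorm(40 * 8), 40, 8)
  res <- moderated_diff(x, rep(c("A", "B"), each = 4))
  expect_equal(res$p_adj, oracle_bh(res$p))
  expect_true(all(res$p_adj >= res$p))
  expect_true(all(diff(res$p_adj[order(res$p)]) >= -1e-12))
})

test_that("score-space reclustering separates planted states deterministically", {
  sim <- simulate_dataset(sim_config(seed = 42, n_cell_types = 1,
                                     cells_per_type_per_sample = 30,
                                     n_genes = 300))
  norm <- normalize_log(sim$counts)
  sc <- gsva_scores(norm, sim$sets)
  st <- sim$truth$state[colnames(sc)]
  grp <- factor(sim$counts$cell_meta$group, levels = c("Ctrl", "DKD"))
  md <- moderated_diff(sc, grp)
  sig <- md$feature[md$significant]
  expect_gte(length(sig), 2)
  cl <- recluster_on_scores(sc[sig, ], dims = min(8, length(sig)),
                            resolution = 0.1, seed = 42)
  expect_equal(length(unique(cl)), 2L)
  skip_if_not_installed("mclust")
  expect_gte(mclust::adjustedRandIndex(cl, st), 0.9)
  cl2 <- recluster_on_scores(sc[sig, ], dims = min(8, length(sig)),
                             resolution = 0.1, seed = 42)
  expect_identical(cl, cl2)

  # identical cells collapse to one cluster; dims overflow is an error
  flat <- matrix(1, 5, 30, dimnames = list(letters[1:5], sprintf("c%02d", 1:30)))
  expect_equal(length(unique(recluster_on_scores(flat, 2, 0.1))), 1L)
  expect_error(recluster_on_scores(sc[sig, ], dims = length(sig) + 1,
                                   resolution = 0.1), "dims exceeds")
})

test_that("dominance classification follows the per-sample fraction t-test", {
  meta <- data.frame(barcode = sprintf("c%03d", 1:80),
                     sample_id = rep(sprintf("%s_%d", rep(c("Ctrl", "DKD"), each = 4),
                                             1:4), each = 10),
                     group = rep(c("Ctrl", "DKD"), each = 40),
                     cell_type = "T", stringsAsFactors = FALSE)
  # cluster 1 contains only DKD cells in every DKD sample
  cl <- setNames(ifelse(meta$group == "DKD", 1L, 0L), meta$barcode)
  asg <- classify_dominance(cl, meta)
  expect_true(asg$classified)
  expect_true(all(asg$label[cl == 1L] == "DDC"))
  expect_true(all(asg$label[cl == 0L] == "HDC"))

  # perfectly balanced fractions: unclassified
  cl_bal <- setNames(rep(c(0L, 1L), 40), meta$barcode)
  asg2 <- classify_dominance(cl_bal, meta)
  expect_false(asg2$classified)
  expect_true(all(is.na(asg2$label)))

  # invariance to cluster relabeling
  asg3 <- classify_dominance(setNames(1L - cl, names(cl)), meta)
  expect_equal(unname(asg3$label[names(cl)]), unname(asg$label[names(cl)]))

  expect_error(classify_dominance(cl, meta[meta$group == "DKD", ]),
               "both groups")
})

test_that("a planted 70%-DKD/30%-Ctrl state is called DDC in >= 18/20 seeds", {
  # dominance logic exercised on its own contract: cluster ids in, call out
  n_per_sample <- 30L
  meta <- data.frame(
    barcode = sprintf("c%03d", seq_len(8 * n_per_sample)),
    sample_id = rep(sprintf("%s_%d", rep(c("Ctrl", "DKD"), each = 4), 1:4),
                    each = n_per_sample),
    group = rep(c("Ctrl", "DKD"), each = 4 * n_per_sample),
    cell_type = "T", stringsAsFactors = FALSE)
  wins <- vapply(1:20, function(s) {
    set.seed(s)
    p <- ifelse(meta$group == "DKD", 0.7, 0.3)
    cl <- setNames(as.integer(runif(nrow(meta)) < p), meta$barcode)
    asg <- classify_dominance(cl, meta)
    asg$classified && asg$cluster_table$ddc[asg$cluster_table$cluster == 1L]
  }, TRUE)
  expect_gte(sum(wins), 18L)
})
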