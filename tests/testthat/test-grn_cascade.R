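make_cascade_cells <- function(seed, n = 200, n_decoy = 20) {
  # receptor activity drives TF expression drives target expression
  set.seed(seed)
  act <- runif(n)
  rcp <- rpois(n, 2 + 18 * act)
  tf1 <- rpois(n, 2 + 15 * act)
  tf2 <- rpois(n, 6)                     # idle TF
  tg <- t(vapply(1:10, function(i) rpois(n, 1 + 12 * act), numeric(n)))
  decoy <- matrix(rpois(n_decoy * n, 5), n_decoy, n)
  m <- rbind(Rcp = rcp, Tf01 = tf1, Tf02 = tf2, tg, decoy)
  rownames(m) <- c("Rcp", "Tf01", "Tf02", sprintf("Tg%02d", 1:10),
                   sprintf("d%02d", seq_len(n_decoy)))
  colnames(m) <- sprintf("c%03d", seq_len(n))
  m
}

test_that("regulon inference recovers a planted TF-target program", {
  hits <- vapply(1:5, function(s) {
    m <- make_cascade_cells(s)
    regs <- infer_regulons(m, c("Tf01", "Tf02"), n_trees = 100,
                           top_k_targets = 12, seed = 42)
    mean(sprintf("Tg%02d", 1:10) %in% regs$Tf01$targets)
  }, 1)
  expect_gte(mean(hits >= 0.8), 0.8)
})

test_that("regulon inference edge rules: constant TF, priors, cell order", {
  m <- make_cascade_cells(3)
  m["Tf02", ] <- 4                       # constant TF cannot split
  regs <- infer_regulons(m, c("Tf01", "Tf02"), n_trees = 50, seed = 1)
  expect_false("Tf02" %in% names(regs))

  # prior NES <= 3 drops the regulon; NES > 3 prunes to prior targets
  prior <- data.frame(tf = c("Tf01", "Tf01"), target = c("Tg01", "Tg02"),
                      nes = c(2.9, 2.5))
  expect_length(infer_regulons(m, c("Tf01", "Tf02"), n_trees = 50,
                               prior = prior, seed = 1), 0)
  prior2 <- data.frame(tf = "Tf01", target = "Tg01", nes = 5)
  kept <- infer_regulons(m, c("Tf01", "Tf02"), n_trees = 50,
                         prior = prior2, seed = 1)
  expect_equal(kept$Tf01$targets, "Tg01")

  # shuffling cell order leaves the regulons identical
  perm <- sample(ncol(m))
  r1 <- infer_regulons(m, c("Tf01", "Tf02"), n_trees = 50, seed = 7)
  r2 <- infer_regulons(m[, perm], c("Tf01", "Tf02"), n_trees = 50, seed = 7)
  expect_identical(lapply(r1, `[[`, "targets"), lapply(r2, `[[`, "targets"))

  expect_error(infer_regulons(m, character(0)), "empty TF list")
  expect_error(infer_regulons(m[, 1:30], c("Tf01", "Tf02")), ">= 50 cells")
})

test_that("recovery-curve activity matches the trapezoid oracle and its extremes", {
  set.seed(8)
  norm <- toy_norm(10, 6, seed = 8)
  regs <- list(R1 = c("g01", "g03"))
  # brute-force check at top_fraction 0.5
  act <- aucell_scores(norm, regs, top_fraction = 0.5, seed = 1)
  for (j in 1:6)
    expect_equal(act["R1", j],
                 oracle_aucell(norm[, j], rownames(norm), regs$R1, 5),
                 tolerance = 1e-10)

  # all regulon genes on top -> activity 1; none in the top fraction -> 0
  e <- norm
  e[c("g01", "g03"), 1] <- max(norm) + 1:2
  e[c("g01", "g03"), 2] <- min(norm) - 1:2
  a2 <- aucell_scores(e, regs, top_fraction = 0.5, seed = 1)
  expect_equal(a2["R1", 1], 1)
  expect_equal(a2["R1", 2], 0)

  # invariant under strictly monotone transforms
  a3 <- aucell_scores(exp(norm * 2), regs, top_fraction = 0.5, seed = 1)
  expect_equal(a3["R1", ], act["R1", ])

  expect_warning(aucell_scores(norm, list(R2 = "absent"), top_fraction = 0.3),
                 "score 0")
  expect_error(aucell_scores(norm, regs, top_fraction = 0.6), "top_fraction")
})

test_that("differential regulon activity surfaces planted shifts first", {
  set.seed(9)
  act <- matrix(rnorm(20 * 60, 0.5, 0.1), 20, 60,
                dimnames = list(sprintf("R%02d", 1:20), NULL))
  lab <- rep(c("HDC", "DDC"), each = 30)
  act[1:5, lab == "DDC"] <- act[1:5, lab == "DDC"] + 0.2  # 2 sd shift
  res <- regulon_diff(act, lab)
  expect_true(all(sprintf("R%02d", 1:5) %in% res$feature[1:5]))
  expect_true(all(res$p < 0.01))

  # identical activity: empty table; top_n larger than significant: all kept
  flat <- act; flat[, ] <- rep(act[, 1], 60)
  expect_equal(nrow(regulon_diff(flat, lab)), 0L)
  expect_equal(nrow(regulon_diff(act, lab, top_n = 1000)),
               sum(moderated_diff(act, factor(lab))$p < 0.01))
})

test_that("cascade assembly recovers the planted chain and controls false edges", {
  wins <- vapply(1:5, function(s) {
    m <- make_cascade_cells(s)
    norm <- normalize_log(m)
    regs <- infer_regulons(m, c("Tf01", "Tf02"), n_trees = 100,
                           top_k_targets = 12, seed = 42)
    net <- build_cascade("Rcp", regs, norm)
    rt <- net[net$layer == "receptor-tf", ]
    tt <- net[net$layer == "tf-target", ]
    nrow(rt) > 0 && all(rt$source == "Rcp") && "Tf01" %in% rt$target &&
      mean(sprintf("Tg%02d", 1:10) %in% tt$target[tt$source == "Tf01"]) >= 0.5
  }, TRUE)
  expect_gte(sum(wins), 4L)

  # receptor independent of every TF: false-edge rate <= 5% at rho_min 0.3
  false_edges <- vapply(1:20, function(s) {
    set.seed(s + 100)
    n <- 200
    norm <- matrix(rnorm(8 * n), 8, n,
                   dimnames = list(c("Rx", sprintf("Tf%02d", 1:5), "t1", "t2"),
                                   sprintf("c%03d", 1:n)))
    regs <- structure(lapply(sprintf("Tf%02d", 1:5), function(tf)
      list(tf = tf, targets = c("t1", "t2"), importance = c(1, 1),
           provenance = "coexpression")), class = c("regulon_set", "list"))
    names(regs) <- sprintf("Tf%02d", 1:5)
    net <- suppressWarnings(build_cascade("Rx", regs, norm, rho_min = 0.3))
    if (!nrow(net)) 0L else sum(net$layer == "receptor-tf")
  }, 1L)
  expect_lte(mean(false_edges > 0), 0.05)

  # self-correlation sanity on the annotated coefficient
  expect_equal(cor(1:10, 1:10, method = "spearman"), 1)
})

test_that("cascade edge count is monotone non-increasing in rho_min", {
  m <- make_cascade_cells(2)
  norm <- normalize_log(m)
  regs <- infer_regulons(m, c("Tf01", "Tf02"), n_trees = 50, seed = 42)
  n_edges <- vapply(c(0.1, 0.3, 0.5, 0.9), function(r)
    nrow(suppressWarnings(build_cascade("Rcp", regs, norm, rho_min = r))),
    1L)
  expect_true(all(diff(n_edges) <= 0))
})
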