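test_that("trimmed cluster means follow the sorted-slice definition", {
  norm <- rbind(const = rep(5, 10), spike = c(rep(1, 9), 1000))
  colnames(norm) <- sprintf("c%02d", 1:10)
  ce <- cluster_expression(norm, rep("A", 10))
  expect_equal(ce["const", "A"], 5)
  expect_equal(ce["spike", "A"], 1)          # outlier trimmed away

  set.seed(2)
  x <- rnorm(20)
  m <- matrix(x, 1, 20, dimnames = list("g", sprintf("c%02d", 1:20)))
  direct <- mean(sort(x)[6:15])              # 25% trimmed from each end
  expect_equal(cluster_expression(m, rep("A", 20))["g", "A"], direct)
  expect_error(cluster_expression(m, rep("A", 20), trim = 0.5), "trim")
})

test_that("communication probability is the saturating product law", {
  ce <- matrix(c(0, 2, 1, 0.5), 2, 2,
               dimnames = list(c("L", "R"), c("A", "B")))
  lr <- lr_database(data.frame(pathway = "P", ligand = "L", receptor = "R",
                               category = "secreted"))
  probs <- communication_prob(ce, lr)
  # ligand zero in A: all A-sourced rows are zero
  expect_true(all(probs$prob[probs$source == "A"] == 0))
  # l * r = 1 * 0.5 -> exactly half-saturation; l * r = 1 * 2 -> 2/2.5
  expect_equal(probs$prob[probs$source == "B" & probs$target == "B"], 0.5)
  expect_equal(probs$prob[probs$source == "B" & probs$target == "A"], 0.8)
  expect_true(all(probs$prob >= 0 & probs$prob < 1))
  # monotone, bounded limit
  ce2 <- ce; ce2["L", "B"] <- 1e9
  p2 <- communication_prob(ce2, lr)
  expect_gt(p2$prob[p2$source == "B" & p2$target == "B"],
            probs$prob[probs$source == "B" & probs$target == "B"])
  expect_lt(max(p2$prob), 1)
  # missing genes are dropped with a warning
  lr2 <- lr_database(data.frame(pathway = c("P", "Q"), ligand = c("L", "Zz"),
                                receptor = c("R", "R"), category = "s"))
  expect_warning(communication_prob(ce, lr2), "Q")
})

test_that("multi-subunit complexes use the geometric mean", {
  ce <- matrix(c(4, 9, 1, 1, 1, 1), 3, 2,
               dimnames = list(c("L1", "L2", "R"), c("A", "B")))
  lr <- lr_database(data.frame(pathway = "P", ligand = "L1+L2",
                               receptor = "R", category = "s"))
  probs <- communication_prob(ce, lr, Kh = 0.5)
  l <- sqrt(4 * 9)
  expect_equal(probs$prob[probs$source == "A" & probs$target == "B"],
               l / (0.5 + l), tolerance = 1e-6)
})

test_that("permutation p-values: plus-one rule, null calibration, planted pair", {
  set.seed(10)
  # homogeneous cells, random labels: p approximately uniform
  norm <- matrix(abs(rnorm(25 * 120)), 25, 120,
                 dimnames = list(sprintf("g%02d", 1:25),
                                 sprintf("c%03d", 1:120)))
  lab <- rep(c("A", "B"), 60)
  lr_null <- lr_database(data.frame(pathway = sprintf("N%02d", 1:13),
                                    ligand = sprintf("g%02d", 1:13),
                                    receptor = sprintf("g%02d", 13:25),
                                    category = "s"))
  res <- permutation_test(norm, lab, lr_null, n_perm = 100, seed = 1)
  expect_gte(nrow(res), 50)
  expect_true(all(res$p > 0 & res$p <= 1))
  expect_gt(suppressWarnings(ks.test(res$p, "punif")$p.value), 0.01)
  expect_lte(mean(res$retained), 0.1)

  # observed probability 0 has p = 1 under the plus-one rule
  norm0 <- norm; norm0["g01", ] <- 0
  res0 <- permutation_test(norm0, lab, lr_null, n_perm = 50, seed = 1)
  expect_equal(res0$p[res0$ligand == "g01"], rep(1, 4))

  expect_error(permutation_test(norm, lab, lr_null, n_perm = 10), "n_perm")
})

test_that("an 8-fold planted ligand-receptor pair is retained in >= 18/20 seeds", {
  lr <- lr_database(data.frame(pathway = c("Planted", "Decoy"),
                               ligand = c("Lg", "d1"), receptor = c("Rc", "d2"),
                               category = "s"))
  wins <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 60
    norm <- matrix(abs(rnorm(8 * 2 * n, 1, 0.3)), 8, 2 * n,
                   dimnames = list(c("Lg", "Rc", "d1", "d2", "e1", "e2", "e3", "e4"),
                                   sprintf("c%03d", 1:(2 * n))))
    lab <- rep(c("A", "B"), each = n)
    norm["Lg", lab == "A"] <- norm["Lg", lab == "A"] * 8
    norm["Rc", lab == "B"] <- norm["Rc", lab == "B"] * 8
    res <- permutation_test(norm, lab, lr, n_perm = 100, seed = s)
    res$retained[res$source == "A" & res$target == "B" &
                 res$pathway == "Planted"]
  }, TRUE)
  expect_gte(sum(wins), 18L)
})

test_that("DCCP selection flags rows by ESDEG role and yields NULL-like empties", {
  res <- data.frame(source = c("T1_HDC", "T2_DDC", "T1_DDC"),
                    target = c("T2_DDC", "T1_HDC", "T2_HDC"),
                    pathway = c("P1", "P2", "P3"),
                    ligand = c("La", "Lb", "Lc"),
                    receptor = c("Ra", "Rb", "Rc"),
                    prob = 0.5, p = 0.01, retained = TRUE,
                    stringsAsFactors = FALSE)
  class(res) <- c("communication_result", "data.frame")
  map <- c(T1_HDC = "T1", T1_DDC = "T1", T2_HDC = "T2", T2_DDC = "T2")
  esdegs <- list(T1 = c("Rb", "Lc"), T2 = c("Ra"))
  out <- select_dccp(res, esdegs, map)
  # row 1: receptor Ra is ESDEG of target type T2 -> incoming
  expect_true(out$incoming_dccp[out$pathway == "P1"])
  expect_false(out$outgoing_dccp[out$pathway == "P1"])
  # row 2: receptor Rb ESDEG of T1 (incoming), ligand Lb not
  expect_true(out$incoming_dccp[out$pathway == "P2"])
  # row 3: ligand Lc is ESDEG of source type T1 -> outgoing only
  expect_true(out$outgoing_dccp[out$pathway == "P3"])
  expect_false(out$incoming_dccp[out$pathway == "P3"])

  # no ESDEG overlap at all: empty table
  empty <- select_dccp(res, list(T1 = "zz", T2 = "zz"), map)
  expect_equal(nrow(empty), 0L)
  expect_error(select_dccp(res, esdegs, map[1:2]), "missing subcluster")
})
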