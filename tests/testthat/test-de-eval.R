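test_that("library-size normalization follows the exact formula", {
  m <- Matrix::Matrix(matrix(c(10, 9990, 0,
                               20, 19980, 0), nrow = 3,
                             dimnames = list(paste0("g", 1:3),
                                             c("c1", "c2"))), sparse = TRUE)
  norm <- normalize_counts(m)
  # count 10 of total 10000 -> log2(10/10000 * 1e4 + 1) = log2(11)
  expect_equal(norm["g1", "c1"], log2(11))
  expect_equal(norm["g3", "c1"], 0)  # zeros map to zero

  # Doubling all counts of a cell leaves normalized values unchanged
  norm2 <- normalize_counts(m * 2)
  expect_equal(as.matrix(norm2), as.matrix(norm))

  # Zero-total cells are excluded with a warning
  mz <- cbind(m, Matrix::Matrix(0, 3, 1, sparse = TRUE,
                                dimnames = list(rownames(m), "z")))
  expect_warning(nz <- normalize_counts(mz), "zero-total")
  expect_equal(ncol(nz), 2)
})

test_that("hurdle test handles degenerate genes and separates signal", {
  set.seed(151)
  # Identical groups: statistic 0, p = 1
  a <- matrix(rep(c(1, 2, 0, 3), 5), nrow = 2)
  p_id <- hurdle_test(a, a)
  expect_equal(unname(p_id), rep(1, 2))

  # All-zero gene in both groups: p = 1
  z <- matrix(0, 1, 10)
  expect_equal(unname(hurdle_test(z, z)), 1)

  # Strongly separated generator-style gene at n = 199/group
  det_a <- rbinom(199, 1, 0.9) * rnorm(199, 3, 0.5)
  det_b <- rbinom(199, 1, 0.1) * rnorm(199, 3, 0.5)
  p_sep <- hurdle_test(matrix(det_a, 1), matrix(det_b, 1))
  expect_lt(p_sep, 1e-4)

  expect_error(hurdle_test(matrix(1, 1, 1), matrix(1, 1, 5)), "2 cells")
})

test_that("hurdle p-values agree with a permutation-null oracle", {
  set.seed(152)
  # A moderately separated gene, so the permutation tail is resolvable
  xa <- rbinom(60, 1, 0.65) * rnorm(60, 2, 1)
  xb <- rbinom(60, 1, 0.45) * rnorm(60, 2.3, 1)
  p_obs <- hurdle_test(matrix(xa, 1), matrix(xb, 1))
  pooled <- c(xa, xb)
  B <- 4000
  p_perm <- mean(vapply(seq_len(B), function(i) {
    idx <- sample.int(120, 60)
    hurdle_test(matrix(pooled[idx], 1), matrix(pooled[-idx], 1))
  }, numeric(1)) <= p_obs)
  mc_err <- 3 * sqrt(p_perm * (1 - p_perm) / B) + 1 / B
  expect_lt(abs(p_perm - p_obs), max(0.05, mc_err + 0.03))
})

test_that("hurdle p-values are near-uniform under the null", {
  ds <- local({
    gt <- generate_ground_truth(1000, 20, seed = 153)
    cfg <- sim_config(cells_per_type = c(EL4 = 398, IVA12 = 0, Jurkat = 0,
                                         TALL104 = 0),
                      lib_size_median = c(EL4 = 5000, IVA12 = 1, Jurkat = 1,
                                          TALL104 = 1),
                      n_empty = 0, multiplet_rate = 0, damaged_frac = 0,
                      seed = 154)
    simulate_cells(gt, cfg)
  })
  norm <- normalize_counts(ds$counts)
  norm <- norm[grepl("^mm_", rownames(norm)), ]
  p <- hurdle_test(norm[, 1:199], norm[, 200:398])
  informative <- p < 1  # exclude genes with no estimable part
  ks <- suppressWarnings(stats::ks.test(p[informative], "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("rank-sum test matches the reference implementation", {
  set.seed(161)
  # Identical constant groups: all ties -> p = 1
  cst <- matrix(2, 1, 10)
  expect_equal(unname(wilcoxon_test(cst, cst)), 1)

  # Against stats::wilcox.test (normal approximation with ties)
  for (i in 1:20) {
    xa <- round(rnorm(25, 0, 2), 1)
    xb <- round(rnorm(30, 0.5, 2), 1)
    mine <- wilcoxon_test(matrix(xa, 1), matrix(xb, 1))
    ref <- suppressWarnings(stats::wilcox.test(xa, xb, exact = FALSE,
                                               correct = TRUE))$p.value
    expect_equal(unname(mine), ref, tolerance = 1e-10)
  }

  # Exact enumeration oracle at small n (no ties)
  xa <- seq(1, 20) + 0.1
  xb <- seq(21, 40) + 0.2  # disjoint supports
  p_approx <- unname(wilcoxon_test(matrix(xa, 1), matrix(xb, 1)))
  p_exact <- stats::wilcox.test(xa, xb, exact = TRUE)$p.value
  expect_lt(p_approx, 1e-5)
  expect_lt(p_exact, p_approx)  # the approximation is conservative here

  # Overlapping case: approximation close to exact enumeration
  set.seed(162)
  ya <- rnorm(15)
  yb <- rnorm(15, 0.8)
  expect_equal(unname(wilcoxon_test(matrix(ya, 1), matrix(yb, 1))),
               stats::wilcox.test(ya, yb, exact = TRUE)$p.value,
               tolerance = 0.02)

  # Symmetric label swap leaves p unchanged
  expect_equal(wilcoxon_test(matrix(ya, 1), matrix(yb, 1)),
               wilcoxon_test(matrix(yb, 1), matrix(ya, 1)))
})

test_that("BH adjustment follows the step-up closed form", {
  expect_equal(unname(bh_fdr(c(0.01, 0.02, 0.03))), rep(0.03, 3))
  expect_equal(bh_fdr(0.2), 0.2)
  set.seed(171)
  p <- runif(100)^2
  expect_true(all(bh_fdr(p) >= p))
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
})

test_that("down-sampled testing is deterministic and gains power with n", {
  ds <- tiny_ds(seed = 181, cells = 150, n_empty = 0,
                lib = c(3000, 3000, 3000, 800))
  sing <- singlet_cids(ds$truth)
  lab <- ds$truth$label[match(sing, ds$truth$cid)]
  el4 <- sing[lab == "EL4"]
  iva <- sing[lab == "IVA12"]
  mouse_genes <- ds$features$gene[ds$features$species == "mouse"]
  norm <- normalize_counts(ds$counts[, c(el4, iva)])[mouse_genes, ]
  na <- norm[, el4, drop = FALSE]
  nb <- norm[, iva, drop = FALSE]

  r1 <- subsample_and_test(na, nb, n = 50, reps = 3, seed = 9)
  r2 <- subsample_and_test(na, nb, n = 50, reps = 3, seed = 9)
  expect_identical(r1$n_de, r2$n_de)
  expect_identical(r1$sig_genes, r2$sig_genes)

  # More cells per repetition -> more discoveries
  r_small <- subsample_and_test(na, nb, n = 40, reps = 3, seed = 10)
  r_large <- subsample_and_test(na, nb, n = 130, reps = 3, seed = 10)
  expect_gt(r_large$mean_nde, r_small$mean_nde)

  # Capping warning when a group is smaller than n
  expect_warning(subsample_and_test(na, nb, n = 1000, reps = 2, seed = 1),
                 "capped")

  # Null split of one group: essentially nothing at FDR < 1e-4
  half <- length(el4) %/% 2
  r0 <- subsample_and_test(na[, seq_len(half), drop = FALSE],
                           na[, (half + 1):length(el4), drop = FALSE],
                           n = half, reps = 3, seed = 11)
  expect_lte(r0$mean_nde, 1)
})

test_that("recall/precision reproduce confusion-matrix arithmetic", {
  # TP = 30, FN = 20, FP = 10 -> recall 0.6, precision 0.75
  bulkA <- c(rep(10, 50), rep(1, 60))   # 50 bulk-true genes
  bulkB <- rep(1, 110)
  names(bulkA) <- names(bulkB) <- paste0("g", 1:110)
  sig <- c(paste0("g", 1:30), paste0("g", 51:60))  # 30 TP + 10 FP
  sc <- bulk_truth_and_score(bulkA, bulkB, sig)
  expect_equal(sc$tp, 30)
  expect_equal(sc$fp, 10)
  expect_equal(sc$fn, 20)
  expect_equal(sc$recall, 0.6)
  expect_equal(sc$precision, 0.75)
  expect_equal(sc$n_true, 50)

  # Empty significant set: recall 0, precision undefined
  sc0 <- bulk_truth_and_score(bulkA, bulkB, character(0))
  expect_equal(sc0$recall, 0)
  expect_true(is.na(sc0$precision))

  # Fold-change rule is symmetric with the +1 pseudocount
  sc2 <- bulk_truth_and_score(c(g1 = 0), c(g1 = 10), "g1")
  expect_equal(sc2$tp, 1)
  expect_error(bulk_truth_and_score(c(a = 1), c(b = 1), "a"), "universe")
})
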