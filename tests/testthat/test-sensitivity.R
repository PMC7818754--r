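test_that("detection statistics follow their definitions", {
  m <- Matrix::Matrix(cbind(c1 = c(2, 0, 3),    # spec cell: nUMI 5, nGene 2
                            c2 = c(0, 4, 0),
                            c3 = c(1, 1, 2)),
                      sparse = TRUE)
  rownames(m) <- c("mm_G1", "mm_G2", "mm_MT-1")
  st <- detection_stats(m, reads_per_cid = c(c1 = 30, c2 = 20, c3 = 40))
  expect_equal(st$n_umi, c(5, 4, 4))
  expect_equal(st$n_gene, c(2, 1, 3))
  expect_equal(st$reads_per_umi, c(6, 5, 10))
  expect_equal(st$reads_per_gene, c(15, 20, 40 / 3))
  expect_equal(st$mito_frac, c(3 / 5, 0, 2 / 4))

  # Degenerate all-zero cell: undefined ratios reported missing
  z <- Matrix::Matrix(matrix(0, 2, 1, dimnames = list(c("mm_G1", "mm_G2"),
                                                      "c1")), sparse = TRUE)
  stz <- detection_stats(z, reads_per_cid = c(c1 = 5))
  expect_equal(stz$n_umi, 0)
  expect_equal(stz$n_gene, 0)
  expect_true(is.na(stz$reads_per_umi))
  expect_true(is.na(stz$mito_frac))

  # reads/gene on a constructed cell: 30 reads over 3 genes -> 10
  m3 <- Matrix::Matrix(matrix(c(1, 1, 1), 3, 1,
                              dimnames = list(paste0("mm_G", 1:3), "c1")),
                       sparse = TRUE)
  expect_equal(detection_stats(m3, c(c1 = 30))$reads_per_gene, 10)
})

test_that("mitochondrial filtering keeps cells strictly below threshold", {
  st <- data.frame(cid = c("a", "b", "c", "d"),
                   mito_frac = c(0.25, 0.19, NA, 0.999))
  expect_equal(mito_filter(st, 0.2), "b")
  expect_equal(mito_filter(st, 1.0), c("a", "b", "d"))
  expect_error(mito_filter(st, 0), "threshold")

  # Generator damaged cells are preferentially excluded
  ds <- tiny_ds(seed = 111, cells = 80, n_empty = 0,
                damaged_mito_boost = 10)
  st2 <- detection_stats(ds$counts, features = ds$features)
  kept <- mito_filter(st2, 0.2)
  dmg <- ds$truth$cid[ds$truth$damaged]
  intact <- ds$truth$cid[!ds$truth$damaged & !ds$truth$is_empty]
  expect_lt(mean(dmg %in% kept), mean(intact %in% kept))
})

test_that("gene accumulation matches exhaustive enumeration on a toy pool", {
  m <- Matrix::Matrix(matrix(c(1, 0, 0,
                               0, 2, 0,
                               0, 3, 1,
                               0, 0, 0), nrow = 4, byrow = TRUE,
                             dimnames = list(paste0("g", 1:4),
                                             paste0("c", 1:3))),
                      sparse = TRUE)
  # Cells detect gene sets {g1}, {g2, g3}, {g3}; exhaustive subsets give
  # size 1 -> mean(1, 2, 1); size 2 -> mean(3, 2, 2); size 3 -> 3
  exact <- c(mean(c(1, 2, 1)), mean(c(3, 2, 2)), 3)
  acc <- gene_accumulation(m, sizes = 1:3, iterations = 3000, seed = 7)
  expect_equal(acc$mean_genes[3], exact[3])  # all cells: deterministic
  expect_lt(abs(acc$mean_genes[1] - exact[1]), 0.05)
  expect_lt(abs(acc$mean_genes[2] - exact[2]), 0.05)

  # Mean curve is non-decreasing in pool size
  ds <- tiny_ds(seed = 112, cells = 40, n_empty = 0)
  acc2 <- gene_accumulation(ds$counts[, singlet_cids(ds$truth)],
                            sizes = 1:10, iterations = 20, seed = 8)
  expect_true(all(diff(acc2$mean_genes) >= 0))

  expect_warning(gene_accumulation(m, sizes = 1:5, iterations = 5, seed = 1),
                 "capped")
})

test_that("dropout fits recover noiseless parameters and GD50 closed forms", {
  x <- exp(seq(log(0.1), log(500), length.out = 100))
  fit <- fit_dropout(x, pmin(1, exp(-0.05 * x)))
  expect_equal(fit$a, 1, tolerance = 1e-6)
  expect_equal(fit$b, 0.05, tolerance = 1e-6)
  expect_equal(fit$gd50, log(2) / 0.05, tolerance = 1e-6)
  expect_lt(fit$residual, 1e-10)

  # Amplitude below 0.5: the curve never reaches 0.5, GD50 undefined
  fit2 <- fit_dropout(x, 0.4 * exp(-0.05 * x))
  expect_true(is.na(fit2$gd50))
  expect_equal(fit2$a, 0.4, tolerance = 1e-6)

  # gd50 = ln(2a)/b for a > 0.5
  fit3 <- fit_dropout(x, 0.9 * exp(-0.1 * x))
  expect_equal(fit3$gd50, log(1.8) / 0.1, tolerance = 1e-6)

  expect_error(fit_dropout(x[1:20], rep(0.5, 20)), "at least 50")
  expect_error(fit_dropout(x, rep(1.5, length(x))), "dropout")

  # S3 surface
  expect_equal(unname(coef(fit3)), c(fit3$a, fit3$b))
  expect_equal(predict(fit3, 10), 0.9 * exp(-1))
})

test_that("dropout fractions use only the species-matched gene set", {
  ds <- tiny_ds(seed = 113, cells = 30, n_empty = 0)
  mouse_genes <- ds$features$gene[ds$features$species == "mouse"]
  sing <- singlet_cids(ds$truth)
  el4 <- sing[ds$truth$label[match(sing, ds$truth$cid)] == "EL4"]
  dr <- dropout_fractions(ds$counts[, el4], mouse_genes)
  expect_equal(length(dr), length(mouse_genes))
  expect_true(all(dr >= 0 & dr <= 1))
  # A gene with zero counts everywhere has dropout 1; detected-in-all gives 0
  sub <- ds$counts[mouse_genes, el4]
  all_zero <- Matrix::rowSums(sub) == 0
  all_hit <- Matrix::rowSums(sub > 0) == ncol(sub)
  expect_true(all(dr[all_zero] == 1))
  expect_true(all(dr[all_hit] == 0))
})

test_that("UMI-binned dropout models show the depth-sensitivity gradient", {
  gt <- tiny_gt(121, n_genes = 400, n_markers = 20)
  cfg <- sim_config(cells_per_type = c(EL4 = 400, IVA12 = 0, Jurkat = 0,
                                       TALL104 = 0),
                    lib_size_median = c(EL4 = 600, IVA12 = 1, Jurkat = 1,
                                        TALL104 = 1),
                    lib_size_sdlog = 0.9,  # wide depth spread across bins
                    n_empty = 0, multiplet_rate = 0, damaged_frac = 0,
                    seed = 122)
  ds <- simulate_cells(gt, cfg)
  cells <- ds$truth$cid[!ds$truth$is_empty]
  labels <- setNames(rep("EL4", length(cells)), cells)
  bd <- binned_dropout(ds$counts, labels, ds$bulk, ds$features,
                       n_bins = 4, cells_per_fit = 40, iterations = 10,
                       seed = 123)
  # Equal-occupancy bins (rank-based split)
  occ <- table(ceiling(rank(Matrix::colSums(ds$counts[, cells]),
                            ties.method = "first") * 4 / length(cells)))
  expect_lte(diff(range(occ)), 1)
  # GD50 decreases from the lowest to the highest UMI bin
  expect_equal(bd$bin, 1:4)
  expect_lt(bd$mean_gd50[4], bd$mean_gd50[1])
  expect_true(all(diff(bd$mean_gd50) < 0))

  # A type present only in some bins is reported only there
  labels2 <- labels
  drop_cells <- names(sort(Matrix::colSums(ds$counts[, cells]))[1:200])
  labels2[drop_cells] <- "Jurkat"  # fake a low-depth-only second type
  bd2 <- suppressWarnings(
    binned_dropout(ds$counts, labels2, ds$bulk, ds$features,
                   n_bins = 4, cells_per_fit = 40, iterations = 3,
                   seed = 124))
  expect_true(all(bd2$bin[bd2$type == "Jurkat"] %in% 1:2))
})
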