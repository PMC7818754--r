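test_that("ground truth is seed-deterministic, species-exclusive, and marker-recoverable", {
  gt1 <- generate_ground_truth(300, 20, seed = 42)
  gt2 <- generate_ground_truth(300, 20, seed = 42)
  expect_identical(gt1$means, gt2$means)
  expect_identical(gt1$features, gt2$features)

  # Every gene belongs to one species; at least one mito gene per species
  expect_true(all(gt1$features$species %in% c("human", "mouse")))
  for (sp in c("human", "mouse"))
    expect_gte(sum(gt1$features$mito & gt1$features$species == sp), 1)

  # Mouse types are zero on human genes and vice versa
  hg <- gt1$features$species == "human"
  expect_true(all(gt1$means[hg, c("EL4", "IVA12")] == 0))
  expect_true(all(gt1$means[!hg, c("Jurkat", "TALL104")] == 0))
  expect_true(all(gt1$means >= 0))

  # Noiseless bulk = the mean table itself; marker filter recovers >= 20
  # markers per within-species contrast
  bulk0 <- data.frame(gene = gt1$features$gene,
                      species = gt1$features$species, gt1$means,
                      check.names = FALSE)
  panel <- select_markers(bulk0)
  expect_gte(sum(panel$species == "mouse"), 20)
  expect_gte(sum(panel$species == "human"), 20)

  expect_error(generate_ground_truth(10, 10), "n_markers")
  expect_error(generate_ground_truth(0, 1), "n_genes_per_species")
})

test_that("simulated datasets respect truth labels, totals and species purity", {
  ds <- tiny_ds(seed = 7)
  counts <- ds$counts
  truth <- ds$truth

  # Truth covers every CID exactly once; totals match the matrix
  expect_identical(sort(truth$cid), sort(colnames(counts)))
  expect_equal(truth$true_total, unname(Matrix::colSums(counts)))

  # Singlets touch only their species' genes
  hg <- ds$features$species == "human"
  sing <- singlet_cids(truth)
  lab <- truth$label[match(sing, truth$cid)]
  mouse_cells <- sing[lab %in% c("EL4", "IVA12")]
  human_cells <- sing[lab %in% c("Jurkat", "TALL104")]
  expect_true(all(counts[hg, mouse_cells] == 0))
  expect_true(all(counts[!hg, human_cells] == 0))

  # Multiplets list >= 2 member types; conservation of member totals
  multi <- truth$cid[truth$is_multiplet]
  expect_true(all(truth$n_members[match(multi, truth$cid)] >= 2))
  mem_tot <- tapply(ds$members$size, ds$members$cid, sum)
  expect_equal(as.numeric(mem_tot[truth$cid[!truth$is_empty]]),
               truth$true_total[!truth$is_empty])

  # Zero multiplet rate boundary
  ds0 <- tiny_ds(seed = 3, cells = 30, n_empty = 50, multiplet_rate = 0)
  expect_identical(sum(ds0$truth$is_multiplet), 0L)

  # Seed determinism end to end
  ds_a <- tiny_ds(seed = 5, cells = 20, n_empty = 40)
  ds_b <- tiny_ds(seed = 5, cells = 20, n_empty = 40)
  expect_equal(ds_a$counts, ds_b$counts)
  expect_identical(ds_a$truth, ds_b$truth)
})

test_that("type frequencies follow the configured mixture", {
  gt <- tiny_gt(2, n_genes = 100, n_markers = 10)
  cfg <- sim_config(cells_per_type = c(EL4 = 2500, IVA12 = 2500,
                                       Jurkat = 2500, TALL104 = 2500),
                    lib_size_median = c(EL4 = 50, IVA12 = 50, Jurkat = 50,
                                        TALL104 = 50),
                    n_empty = 0, multiplet_rate = 0, seed = 9)
  ds <- simulate_cells(gt, cfg)
  lab <- ds$truth$label[!ds$truth$is_empty]
  n <- length(lab)
  sd3 <- 3 * sqrt(0.25 * 0.75 / n)
  for (ty in c("EL4", "IVA12", "Jurkat", "TALL104"))
    expect_lt(abs(mean(lab == ty) - 0.25), sd3)
})

test_that("raising a type's library-size median raises its median nUMI", {
  gt <- tiny_gt(4, n_genes = 100, n_markers = 10)
  med <- function(lib, seed) {
    cfg <- sim_config(cells_per_type = c(EL4 = 80, IVA12 = 0, Jurkat = 0,
                                         TALL104 = 0),
                      lib_size_median = c(EL4 = lib, IVA12 = 1, Jurkat = 1,
                                          TALL104 = 1),
                      n_empty = 0, multiplet_rate = 0, seed = seed)
    ds <- simulate_cells(gt, cfg)
    median(ds$truth$true_total[!ds$truth$is_empty])
  }
  for (s in 1:3) expect_gt(med(2000, s), med(500, s + 10))
})

test_that("dropout-curve simulation matches its binomial law", {
  a <- 0.8
  b <- 0.05
  x50 <- log(2 * a) / b  # a*exp(-b*x) = 0.5 here
  det <- simulate_dropout_curve(a, b, rep(x50, 40), n_cells = 400, seed = 1)
  frac_detected <- mean(det)
  expect_lt(abs((1 - frac_detected) - 0.5), 3 * sqrt(0.25 / length(det)))

  # a = 1, b -> 0+: detection fraction -> 0
  det0 <- simulate_dropout_curve(1, 1e-12, c(1, 10, 100), 200, seed = 2)
  expect_identical(sum(det0), 0L)

  expect_error(simulate_dropout_curve(1.2, 1, 1, 10), "'a'")
  expect_error(simulate_dropout_curve(0.5, -1, 1, 10), "'b'")
  expect_error(simulate_dropout_curve(0.5, 1, c(-1, 2), 10), "x_grid")
})

test_that("dropout model parameters are recovered from simulated detection", {
  a <- 0.9
  b <- 0.04
  x <- exp(runif(3000, log(0.1), log(1000)))
  det <- simulate_dropout_curve(a, b, x, n_cells = 500, seed = 11)
  fit <- fit_dropout(x, 1 - rowMeans(det))
  expect_lt(abs(fit$a - a) / a, 0.05)
  expect_lt(abs(fit$b - b) / b, 0.05)
})

test_that("tagged reads reproduce true UMI counts at zero error rate", {
  gt <- tiny_gt(6, n_genes = 60, n_markers = 10)
  cfg <- sim_config(cells_per_type = c(EL4 = 10, IVA12 = 0, Jurkat = 0,
                                       TALL104 = 0),
                    lib_size_median = c(EL4 = 300, IVA12 = 1, Jurkat = 1,
                                        TALL104 = 1),
                    n_empty = 0, multiplet_rate = 0, umi_error_rate = 0,
                    seed = 13)
  ds <- simulate_cells(gt, cfg)
  tr <- emit_tagged_reads(ds)
  # distinct observed UMIs per (cid, gene) == true count (no collisions at
  # UMI length 12 and these depths)
  obs <- table(paste(tr$cid, tr$gene))
  tm <- as(ds$counts, "TsparseMatrix")
  key <- paste(colnames(ds$counts)[tm@j + 1], rownames(ds$counts)[tm@i + 1])
  expect_equal(unname(obs[key]), as.integer(tm@x), ignore_attr = TRUE)
  expect_identical(tr$umi, tr$true_umi)

  # Byte-identical under the same seed
  tr2 <- emit_tagged_reads(ds)
  expect_identical(tr, tr2)

  # Tiny UMI space forces collisions -> warning, not error
  cfg4 <- sim_config(cells_per_type = c(EL4 = 2, IVA12 = 0, Jurkat = 0,
                                        TALL104 = 0),
                     lib_size_median = c(EL4 = 2000, IVA12 = 1, Jurkat = 1,
                                         TALL104 = 1),
                     n_empty = 0, umi_length = 4, umi_error_rate = 0,
                     seed = 14)
  ds4 <- simulate_cells(gt, cfg4)
  expect_warning(emit_tagged_reads(ds4), "collision")
})
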