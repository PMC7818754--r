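#' Default benchmark configuration
#'
#' Assembles the configuration consumed by [run_benchmark()]: the synthetic
#' world (ground-truth and simulator parameters), analysis thresholds, and
#' the DE evaluation design. Any element can be overridden via `...` using
#' the same nesting, e.g. `benchmark_config(seed = 7, de = list(reps = 5))`.
#'
#' @param seed Root seed; each stage derives its own seed from it by a fixed
#'   offset so stages stay independently re-runnable.
#' @param ... Named overrides merged (recursively for lists) over the
#'   defaults.
#' @return Nested configuration list of class `benchmark_config`.
#' @export
benchmark_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = seed,
    synthetic = list(
      n_genes_per_species = 1000, n_markers = 46,
      cells_per_type = c(EL4 = 500, IVA12 = 500, Jurkat = 500,
                         TALL104 = 500),
      lib_size_median = c(EL4 = 25000, IVA12 = 25000, Jurkat = 25000,
                          TALL104 = 5000),
      lib_size_sdlog = 0.35, n_empty = 10000,
      ambient_depth_median = 100, ambient_depth_sdlog = 1,
      multiplet_rate = 0.05, damaged_frac = 0.05, damaged_mito_boost = 5,
      umi_length = 12, umi_error_rate = 0.01, reads_per_umi_mean = 2),
    n_loaded = 4000,
    rule_variant = "standard",
    fpkm_min = 50, ln_fc_min = 3,
    significance_frac = 0.05,
    mito_threshold = 0.2,
    concordance = list(sizes = 1:50, iterations = 50),
    de = list(n = 199, reps = 10, test = "hurdle", alpha = 1e-4,
              fc_threshold = 1.5),
    outdir = NULL)
  ov <- list(...)
  merge_in <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]]))
        base[[nm]] <- merge_in(base[[nm]], over[[nm]])
      else base[[nm]] <- over[[nm]]
    }
    base
  }
  cfg <- merge_in(cfg, ov)
  class(cfg) <- "benchmark_config"
  cfg
}

#' Load a benchmark configuration from a JSON file
#'
#' Reads a JSON file of overrides and merges it over the defaults of
#' [benchmark_config()].
#'
#' @param path JSON file path.
#' @return A `benchmark_config`.
#' @export
read_benchmark_config <- function(path) {
  ov <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("cells_per_type", "lib_size_median"))
    if (!is.null(ov$synthetic[[nm]])) ov$synthetic[[nm]] <-
      unlist(ov$synthetic[[nm]])
  do.call(benchmark_config, ov)
}

#' Run the benchmarking pipeline end to end
#'
#' Generates (or loads) a barnyard dataset, then runs cell calling,
#' classification, multiplet-rate estimation, depth diagnostics, detection /
#' dropout sensitivity, pseudo-bulk concordance and DE evaluation, returning
#' a Table-1-style report. All randomness derives from `config$seed`;
#' identical configurations give identical reports.
#'
#' @param config A [benchmark_config()], a JSON path, or a list of
#'   overrides.
#' @param dataset Optional pre-built `synthetic_dataset` (skips simulation;
#'   its ground truth is still used for report validation fields).
#' @return Object of class `benchmark_report`; see [print.benchmark_report()].
#' @export
run_benchmark <- function(config = benchmark_config(), dataset = NULL) {
  if (is.character(config)) config <- read_benchmark_config(config)
  if (!inherits(config, "benchmark_config"))
    config <- do.call(benchmark_config, config)
  seed <- config$seed
  syn <- config$synthetic

  if (is.null(dataset)) {
    gt <- generate_ground_truth(syn$n_genes_per_species, syn$n_markers,
                                seed = stage_seed(seed, 1))
    scfg <- sim_config(
      cells_per_type = syn$cells_per_type,
      lib_size_median = syn$lib_size_median,
      lib_size_sdlog = syn$lib_size_sdlog,
      n_empty = syn$n_empty,
      ambient_depth_median = syn$ambient_depth_median,
      ambient_depth_sdlog = syn$ambient_depth_sdlog,
      multiplet_rate = syn$multiplet_rate,
      damaged_frac = syn$damaged_frac,
      damaged_mito_boost = syn$damaged_mito_boost,
      umi_length = syn$umi_length,
      umi_error_rate = syn$umi_error_rate,
      reads_per_umi_mean = syn$reads_per_umi_mean,
      seed = stage_seed(seed, 2))
    dataset <- simulate_cells(gt, scfg)
  }
  counts <- dataset$counts
  features <- dataset$features
  bulk <- dataset$bulk
  totals <- Matrix::colSums(counts)

  # Classification on the top 2 x expected CIDs.
  panel <- select_markers(bulk, config$fpkm_min, config$ln_fc_min)
  rules <- classification_rules(config$rule_variant)
  n_expected <- sum(dataset$config$cells_per_type)
  assignment <- classify_cells(counts, bulk, panel, rules, n_expected)
  classified <- assignment[assignment$label != "unclassified", ]

  # Rank curve and thresholds; lower bound from classified CIDs.
  curve <- build_rank_curve(totals)
  lower <- if (nrow(classified)) max(min(classified$total), 1)
           else quantile(totals, 0.999)
  points <- knee_inflection(curve, lower_bound = lower)
  eff <- efficiency_metrics(points, totals, config$n_loaded)

  above <- colnames(counts)[totals > points$inflection$total]
  counts_cells <- counts[, above, drop = FALSE]
  assignment_above <- assignment[assignment$cid %in% above, ]

  # Multiplet rate among CIDs above the inflection point.
  mp <- detect_multiplets(counts_cells, assignment_above, features)
  mrate <- if (mp$available)
    adjusted_multiplet_rate(mp$n_hm, length(above), mp$n_h, mp$n_m, mp$n_hm)
  else list(rate = NA_real_, lambda = NA_real_,
            observed_fraction = NA_real_)

  # Depth diagnostics on the called cells.
  modal_depth <- first_significant_mode(totals[above],
                                        config$significance_frac)
  plan <- scaling_factors(c(sample = modal_depth))

  # Sensitivity: per-type medians and global dropout models.
  stats <- detection_stats(counts_cells, features = features)
  keep_cids <- mito_filter(stats, config$mito_threshold)
  cls <- assignment_above[assignment_above$label != "unclassified" &
                            assignment_above$cid %in% keep_cids, ]
  labels <- setNames(cls$label, cls$cid)
  bm <- bulk_matrix(bulk)
  per_type <- lapply(setNames(BARNYARD_TYPES, BARNYARD_TYPES),
                     function(ty) {
    cids <- names(labels)[labels == ty]
    if (length(cids) < 2) return(NULL)
    st <- stats[match(cids, stats$cid), ]
    sp_genes <- features$gene[features$species == TYPE_SPECIES[ty]]
    gd50 <- NA_real_
    if (length(cids) >= 50) {
      dr <- dropout_fractions(counts_cells[, cids, drop = FALSE], sp_genes)
      xs <- bm[sp_genes, ty]
      fit <- fit_dropout(xs[xs > 0], dr[xs > 0])
      gd50 <- fit$gd50
    }
    list(n_cells = length(cids), median_numi = median(st$n_umi),
         median_ngene = median(st$n_gene), gd50 = gd50)
  })

  # Concordance curves.
  conc <- pseudobulk_concordance(
    counts_cells, labels, bulk, features,
    sizes = config$concordance$sizes,
    iterations = config$concordance$iterations,
    seed = stage_seed(seed, 5))

  # DE between the two mouse types, scored against bulk fold changes.
  de <- NULL
  el4 <- names(labels)[labels == "EL4"]
  iva <- names(labels)[labels == "IVA12"]
  if (length(el4) >= 2 && length(iva) >= 2) {
    mouse_genes <- features$gene[features$species == "mouse"]
    norm <- normalize_counts(counts_cells[, c(el4, iva), drop = FALSE])
    norm <- norm[mouse_genes, , drop = FALSE]
    ss <- subsample_and_test(norm[, el4, drop = FALSE],
                             norm[, iva, drop = FALSE],
                             n = config$de$n, reps = config$de$reps,
                             seed = stage_seed(seed, 6),
                             test = config$de$test,
                             alpha = config$de$alpha)
    scores <- lapply(ss$sig_genes, function(sig)
      bulk_truth_and_score(bm[mouse_genes, "EL4"], bm[mouse_genes, "IVA12"],
                           sig, config$de$fc_threshold))
    de <- list(subsample = ss,
               recall = mean(vapply(scores, `[[`, numeric(1), "recall")),
               precision = mean(vapply(scores, `[[`, numeric(1),
                                       "precision")),
               scores = scores)
  }

  report <- list(
    config = config,
    n_cid = ncol(counts), n_above_inflection = length(above),
    thresholds = points, efficiency = eff,
    multiplet = c(mrate, mp[c("n_h", "n_m", "n_hm", "available")]),
    modal_depth = modal_depth, scaling_plan = plan,
    assignment = assignment, per_type = per_type,
    concordance = conc, de = de,
    truth_summary = if (!is.null(dataset$truth)) list(
      n_cells = sum(!dataset$truth$is_empty),
      n_multiplets = sum(dataset$truth$is_multiplet)) else NULL)
  class(report) <- "benchmark_report"

  if (!is.null(config$outdir)) write_report(report, dataset, config$outdir)
  report
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("Barnyard benchmark report\n")
  cat(sprintf("  CIDs: %d (%d above inflection; capture %.1f%%, pool %.1f%%)\n",
              x$n_cid, x$n_above_inflection, 100 * x$efficiency$capture,
              100 * x$efficiency$pool))
  if (!is.na(x$multiplet$rate))
    cat(sprintf("  adjusted multiplet rate: %.2f%% (lambda %.3f)\n",
                100 * x$multiplet$rate, x$multiplet$lambda))
  cat(sprintf("  modal depth: %.0f counts/cell\n", x$modal_depth))
  for (ty in names(x$per_type)) {
    pt <- x$per_type[[ty]]
    if (is.null(pt)) next
    cat(sprintf("  %-8s n=%-5d median nUMI %-7.0f median nGene %-6.0f GD50 %s\n",
                ty, pt$n_cells, pt$median_numi, pt$median_ngene,
                if (is.na(pt$gd50)) "NA" else sprintf("%.1f", pt$gd50)))
  }
  if (!is.null(x$de))
    cat(sprintf("  DE (%s, n=%d x %d reps): mean nDE %.1f [%.1f, %.1f]; recall %.3f, precision %.3f\n",
                x$de$subsample$test, x$de$subsample$n_used,
                length(x$de$subsample$n_de), x$de$subsample$mean_nde,
                x$de$subsample$ci[1], x$de$subsample$ci[2],
                x$de$recall, x$de$precision))
  invisible(x)
}

# Artifact writer: MTX + truth + assignments + JSON report summary.
write_report <- function(report, dataset, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_count_matrix(dataset$counts, file.path(outdir, "counts"),
                     dataset$features)
  if (!is.null(dataset$truth))
    write.table(dataset$truth, file.path(outdir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  write_bulk_signature(dataset$bulk, file.path(outdir, "bulk_signature.csv"))
  write.table(as.data.frame(report$assignment),
              file.path(outdir, "assignments.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_scaling_plan(report$scaling_plan, file.path(outdir,
                                                    "scaling_plan.csv"))
  summary <- list(
    n_cid = report$n_cid,
    n_above_inflection = report$n_above_inflection,
    knee = report$thresholds$knee,
    inflection = report$thresholds$inflection,
    capture_efficiency = report$efficiency$capture,
    pool_efficiency = report$efficiency$pool,
    multiplet_rate = report$multiplet$rate,
    lambda = report$multiplet$lambda,
    modal_depth = report$modal_depth,
    per_type = report$per_type,
    de = if (!is.null(report$de)) list(
      mean_nde = report$de$subsample$mean_nde,
      ci = report$de$subsample$ci,
      recall = report$de$recall,
      precision = report$de$precision) else NULL)
  jsonlite::write_json(summary, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
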