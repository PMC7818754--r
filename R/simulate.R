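#' Configuration for the synthetic barnyard simulator
#'
#' Collects all tunable parameters of [simulate_cells()] and
#' [emit_tagged_reads()] with defaults emulating the benchmarking design: a
#' 1:1:1:1 four-cell-line mixture where the TALL-104-like type has ~5x lower
#' mRNA content, empty droplets carrying ambient RNA, ~5% two-cell
#' multiplets, a small damaged-cell fraction with inflated mitochondrial
#' counts, and UMI sequencing errors at the read level.
#'
#' @param cells_per_type Named integer vector of cell-containing CIDs per
#'   type (the 1:1:1:1 design by default).
#' @param lib_size_median Named vector of median library sizes (UMIs) per
#'   type; the low-mRNA TALL-104-like type defaults 5x below the others.
#' @param lib_size_sdlog Log-scale dispersion of library sizes.
#' @param n_empty Number of empty (ambient-only) CIDs.
#' @param ambient_depth_median,ambient_depth_sdlog Median and log-SD of
#'   ambient totals (UMIs) in empty CIDs.
#' @param multiplet_rate Probability that a cell-containing CID holds two
#'   cells instead of one.
#' @param damaged_frac Fraction of cells with a mitochondrial boost.
#' @param damaged_mito_boost Multiplier on mitochondrial expression for
#'   damaged cells.
#' @param umi_length UMI length in bases (>= 4).
#' @param umi_error_rate Per-read probability of a single-base UMI
#'   substitution error.
#' @param reads_per_umi_mean Mean reads per UMI (1 + Poisson distributed).
#' @param seed Root seed for the simulation.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(cells_per_type = c(EL4 = 500, IVA12 = 500,
                                          Jurkat = 500, TALL104 = 500),
                       lib_size_median = c(EL4 = 25000, IVA12 = 25000,
                                           Jurkat = 25000, TALL104 = 5000),
                       lib_size_sdlog = 0.35,
                       n_empty = 10000,
                       ambient_depth_median = 100,
                       ambient_depth_sdlog = 1,
                       multiplet_rate = 0.05,
                       damaged_frac = 0.05,
                       damaged_mito_boost = 5,
                       umi_length = 12,
                       umi_error_rate = 0.01,
                       reads_per_umi_mean = 2,
                       seed = 1L) {
  if (is.null(names(cells_per_type)))
    names(cells_per_type) <- BARNYARD_TYPES[seq_along(cells_per_type)]
  if (!all(names(cells_per_type) %in% BARNYARD_TYPES))
    stop("'cells_per_type' names must be among: ",
         paste(BARNYARD_TYPES, collapse = ", "), call. = FALSE)
  assert_count(cells_per_type, "cells_per_type")
  assert_count(n_empty, "n_empty")
  assert_count(umi_length, "umi_length", min = 4L)
  assert_fraction(multiplet_rate, "multiplet_rate")
  assert_fraction(damaged_frac, "damaged_frac")
  assert_fraction(umi_error_rate, "umi_error_rate")
  stopifnot(lib_size_sdlog >= 0, ambient_depth_median > 0,
            ambient_depth_sdlog >= 0, damaged_mito_boost >= 1,
            reads_per_umi_mean >= 1)
  if (is.null(names(lib_size_median)))
    names(lib_size_median) <- names(cells_per_type)
  stopifnot(all(lib_size_median > 0))
  cfg <- list(cells_per_type = cells_per_type,
              lib_size_median = lib_size_median,
              lib_size_sdlog = lib_size_sdlog,
              n_empty = as.integer(n_empty),
              ambient_depth_median = ambient_depth_median,
              ambient_depth_sdlog = ambient_depth_sdlog,
              multiplet_rate = multiplet_rate,
              damaged_frac = damaged_frac,
              damaged_mito_boost = damaged_mito_boost,
              umi_length = as.integer(umi_length),
              umi_error_rate = umi_error_rate,
              reads_per_umi_mean = reads_per_umi_mean,
              seed = seed)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Barnyard simulation config\n")
  cat("  cells/type: ",
      paste(sprintf("%s=%d", names(x$cells_per_type), x$cells_per_type),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  empty CIDs: %d; multiplet rate: %.3f; damaged: %.3f\n",
              x$n_empty, x$multiplet_rate, x$damaged_frac))
  cat(sprintf("  UMI length %d, error rate %.3g, mean reads/UMI %.2f\n",
              x$umi_length, x$umi_error_rate, x$reads_per_umi_mean))
  invisible(x)
}

random_barcodes <- function(n, width = 16L) {
  repeat {
    bc <- vapply(seq_len(n), function(i)
      paste(UMI_BASES[sample.int(4L, width, replace = TRUE)], collapse = ""),
      character(1))
    if (!anyDuplicated(bc)) return(bc)
  }
}

#' Simulate a barnyard single-cell dataset with known ground truth
#'
#' Draws a sparse UMI count matrix (genes x CIDs) from a
#' [generate_ground_truth()] world under a [sim_config()]. Per
#' cell-containing CID: with probability `multiplet_rate` two member cells
#' (types drawn independently from the mixture proportions) are summed under
#' one CID, otherwise one cell. Each member's library size is log-normal with
#' its type's median; gene counts are multinomial from the type's normalized
#' mean vector; damaged members have mitochondrial probabilities multiplied
#' by `damaged_mito_boost`. Empty CIDs receive multinomial draws from the
#' depth-weighted average cell profile at ambient depth. Column order is
#' shuffled so barcode position encodes nothing.
#'
#' @param gt A `ground_truth` object.
#' @param config A `sim_config` object.
#' @return An object of class `synthetic_dataset`: list with `counts` (sparse
#'   genes x CIDs UMI matrix), `features`, `truth` (per-CID data frame:
#'   `cid`, `label` ("+"-joined member types, "ambient" for empty CIDs),
#'   `is_empty`, `is_multiplet`, `n_members`, `damaged`, `true_total`),
#'   `members` (one row per member cell: `cid`, `type`, `size`, `damaged`),
#'   `bulk` (noisy bulk signature), and `config`.
#' @examples
#' gt <- generate_ground_truth(100, 10, seed = 1)
#' cfg <- sim_config(cells_per_type = c(EL4 = 30, IVA12 = 30, Jurkat = 30,
#'                                      TALL104 = 30),
#'                   lib_size_median = c(EL4 = 800, IVA12 = 800,
#'                                       Jurkat = 800, TALL104 = 200),
#'                   n_empty = 200, seed = 1)
#' ds <- simulate_cells(gt, cfg)
#' @export
simulate_cells <- function(gt, config = sim_config()) {
  stopifnot(inherits(gt, "ground_truth"), inherits(config, "sim_config"))
  if (nrow(gt$features) == 0 || all(gt$means == 0))
    stop("empty ground truth", call. = FALSE)

  with_seed(config$seed, {
    types <- names(config$cells_per_type)
    n_cells_cid <- sum(config$cells_per_type)
    if (n_cells_cid == 0) stop("no cells configured", call. = FALSE)
    type_prob <- config$cells_per_type / n_cells_cid
    genes <- gt$features$gene
    n_genes <- length(genes)
    mito <- gt$features$mito

    # Per-type sampling probability vectors (normal and damaged variants).
    prob_of <- function(ty, boost) {
      p <- gt$means[, ty]
      p[mito] <- p[mito] * boost
      p / sum(p)
    }
    probs <- lapply(setNames(types, types), prob_of, boost = 1)
    probs_dmg <- lapply(setNames(types, types), prob_of,
                        boost = config$damaged_mito_boost)

    # Membership: 1 or 2 cells per cell-containing CID.
    is_multi <- runif(n_cells_cid) < config$multiplet_rate
    n_members <- ifelse(is_multi, 2L, 1L)
    member_cid <- rep(seq_len(n_cells_cid), n_members)
    member_type <- sample(types, length(member_cid), replace = TRUE,
                          prob = type_prob)
    member_size <- pmax(1, round(rlnorm(
      length(member_cid),
      meanlog = log(config$lib_size_median[member_type]),
      sdlog = config$lib_size_sdlog)))
    member_damaged <- runif(length(member_cid)) < config$damaged_frac

    ii <- vector("list", length(member_cid))
    xx <- vector("list", length(member_cid))
    for (m in seq_along(member_cid)) {
      p <- if (member_damaged[m]) probs_dmg[[member_type[m]]]
           else probs[[member_type[m]]]
      draw <- rmultinom(1L, member_size[m], p)[, 1L]
      nz <- which(draw > 0L)
      ii[[m]] <- nz
      xx[[m]] <- draw[nz]
    }

    # Ambient profile: depth-weighted mean of the cell profiles drawn above.
    type_depth <- vapply(setNames(types, types), function(ty)
      sum(member_size[member_type == ty]), numeric(1))
    ambient <- Reduce(`+`, Map(function(p, w) p * w, probs,
                               as.list(type_depth)))
    ambient <- ambient / sum(ambient)

    n_empty <- config$n_empty
    if (n_empty > 0) {
      empty_size <- pmax(1, round(rlnorm(
        n_empty, meanlog = log(config$ambient_depth_median),
        sdlog = config$ambient_depth_sdlog)))
      ei <- vector("list", n_empty)
      ex <- vector("list", n_empty)
      for (e in seq_len(n_empty)) {
        draw <- rmultinom(1L, empty_size[e], ambient)[, 1L]
        nz <- which(draw > 0L)
        ei[[e]] <- nz
        ex[[e]] <- draw[nz]
      }
    } else {
      ei <- ex <- list()
    }

    n_cid <- n_cells_cid + n_empty
    cids <- random_barcodes(n_cid)
    # Shuffle CID order so position does not encode cell/empty status.
    perm <- sample.int(n_cid)

    col_of_member <- perm[member_cid]
    col_of_empty <- if (n_empty > 0) perm[n_cells_cid + seq_len(n_empty)]
                    else integer(0)
    i_all <- c(unlist(ii), unlist(ei))
    j_all <- c(rep(col_of_member, lengths(ii)),
               rep(col_of_empty, lengths(ei)))
    x_all <- c(unlist(xx), unlist(ex))
    counts <- Matrix::sparseMatrix(
      i = i_all, j = j_all, x = x_all, dims = c(n_genes, n_cid),
      dimnames = list(genes, cids))  # duplicate (i,j) summed: multiplets

    label <- vapply(seq_len(n_cells_cid), function(cc)
      paste(sort(member_type[member_cid == cc]), collapse = "+"),
      character(1))
    truth <- data.frame(
      cid = cids,
      label = "ambient",
      is_empty = TRUE, is_multiplet = FALSE,
      n_members = 0L, damaged = FALSE,
      stringsAsFactors = FALSE)
    cell_cols <- perm[seq_len(n_cells_cid)]
    truth$label[cell_cols] <- label
    truth$is_empty[cell_cols] <- FALSE
    truth$is_multiplet[cell_cols] <- is_multi
    truth$n_members[cell_cols] <- n_members
    truth$damaged[cell_cols] <- vapply(seq_len(n_cells_cid), function(cc)
      any(member_damaged[member_cid == cc]), logical(1))
    truth$true_total <- Matrix::colSums(counts)
    members <- data.frame(cid = cids[col_of_member], type = member_type,
                          size = member_size, damaged = member_damaged,
                          stringsAsFactors = FALSE)

    out <- list(counts = counts, features = gt$features, truth = truth,
                members = members, bulk = bulk_signature(gt),
                config = config)
    class(out) <- "synthetic_dataset"
    out
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic barnyard dataset\n")
  cat(sprintf("  %d genes x %d CIDs (%d cell-containing, %d empty)\n",
              nrow(x$counts), ncol(x$counts),
              sum(!x$truth$is_empty), sum(x$truth$is_empty)))
  cat(sprintf("  multiplet CIDs: %d; total UMIs: %.0f\n",
              sum(x$truth$is_multiplet), sum(x$truth$true_total)))
  invisible(x)
}

#' Simulate per-cell gene detection from an exponential dropout curve
#'
#' Under the dropout model `f(x) = a * exp(-b * x)`, a gene with bulk
#' expression `x` (FPKM) is undetected in a cell with probability
#' `min(1, a * exp(-b * x))`, independently across cells. Used to validate
#' [fit_dropout()] by parameter recovery.
#'
#' @param a Dropout amplitude, in (0, 1].
#' @param b Decay per FPKM, > 0.
#' @param x_grid Positive vector of expression levels (FPKM), one per gene.
#' @param n_cells Number of cells to simulate.
#' @param seed Optional seed.
#' @return Binary detection matrix (genes x cells) with attribute `x` (the
#'   expression grid); `1` = detected.
#' @export
simulate_dropout_curve <- function(a, b, x_grid, n_cells, seed = NULL) {
  assert_fraction(a, "a", allow_zero = FALSE)
  if (!is.numeric(b) || b <= 0) stop("'b' must be > 0", call. = FALSE)
  if (any(x_grid <= 0)) stop("'x_grid' must be positive", call. = FALSE)
  assert_count(n_cells, "n_cells", min = 1L)
  p_drop <- pmin(1, a * exp(-b * x_grid))
  with_seed(seed, {
    det <- matrix(rbinom(length(x_grid) * n_cells, 1L, 1 - p_drop),
                  nrow = length(x_grid), ncol = n_cells)
    attr(det, "x") <- x_grid
    det
  })
}
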