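#' Per-cell concordance with bulk signatures
#'
#' Pearson correlation of each cell's `ln(count + 1)` profile with each bulk
#' `ln(FPKM + 1)` signature over the marker panel. Values are returned for
#' all cells; a reporting threshold (figures often mask r <= 0.2) can be
#' applied with `mask_below` without dropping data.
#'
#' @param counts Sparse genes x CIDs count matrix.
#' @param bulk Bulk signature data frame.
#' @param panel A [select_markers()] panel.
#' @param mask_below Optional threshold; correlations at or below it are set
#'   to `NA` in the returned matrix (presentation only).
#' @return Cells x 4 matrix of correlations (NA for zero-variance cells).
#' @export
per_cell_concordance <- function(counts, bulk, panel, mask_below = NULL) {
  counts <- as_count_matrix(counts)
  stopifnot(inherits(panel, "marker_panel"))
  bm <- bulk_matrix(bulk)
  r <- signature_correlation(counts[panel$gene, , drop = FALSE],
                             bm[panel$gene, , drop = FALSE])
  if (!is.null(mask_below)) r[r <= mask_below] <- NA_real_
  r
}

#' Pseudo-bulk concordance curves
#'
#' For each cell type and pool size, sums UMI counts over cells sampled
#' without replacement from the type's pool, correlates `ln(sum + 1)`
#' against `ln(FPKM + 1)` over *all* genes of the type's species, and
#' averages across iterations.
#'
#' @param counts Sparse genes x CIDs count matrix.
#' @param labels Named character vector (cid -> type) of classified cells.
#' @param bulk Bulk signature data frame.
#' @param features Features data frame (`gene`, `species`).
#' @param sizes Pool sizes (default 1:50); capped at pool size with warning.
#' @param iterations Pools per size (default 50).
#' @param seed Optional seed.
#' @return Data frame with columns `type`, `size`, `mean_r`, `sd_r`.
#' @export
pseudobulk_concordance <- function(counts, labels, bulk, features,
                                   sizes = 1:50, iterations = 50,
                                   seed = NULL) {
  counts <- as_count_matrix(counts)
  bm <- bulk_matrix(bulk)
  labels <- labels[names(labels) %in% colnames(counts)]
  with_seed(seed, {
    rows <- list()
    for (ty in intersect(BARNYARD_TYPES, unique(labels))) {
      pool <- names(labels)[labels == ty]
      sp_genes <- features$gene[features$species == TYPE_SPECIES[ty]]
      y <- log1p(bm[sp_genes, ty])
      if (sd(y) == 0)
        stop("bulk signature is constant over the species' genes",
             call. = FALSE)
      sub <- counts[sp_genes, pool, drop = FALSE]
      szs <- sizes
      if (max(szs) > length(pool)) {
        warning(sprintf("pool for %s has %d cells; sizes capped",
                        ty, length(pool)), call. = FALSE)
        szs <- unique(pmin(szs, length(pool)))
      }
      for (s in szs) {
        r <- vapply(seq_len(iterations), function(it) {
          cols <- sample.int(length(pool), s)
          ps <- Matrix::rowSums(sub[, cols, drop = FALSE])
          suppressWarnings(cor(log1p(ps), y))
        }, numeric(1))
        rows[[length(rows) + 1L]] <- data.frame(
          type = ty, size = s, mean_r = mean(r, na.rm = TRUE),
          sd_r = sd(r), stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}
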