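#' Expand a synthetic count matrix into a tagged-read table
#'
#' Converts true UMI counts into the `<barcode, gene, UMI>` read groups that
#' the UMI-correction stage consumes. Every true UMI receives a random UMI
#' sequence (uniform over the 4^L sequence space; collisions within a
#' (CID, gene) pair trigger a warning, not an error). Reads per UMI are
#' `1 + Poisson(reads_per_umi_mean - 1)`. Each read's UMI is independently
#' corrupted by one random single-base substitution with probability
#' `umi_error_rate`; the true UMI of every observed group is retained in the
#' `true_umi` column for validation.
#'
#' Memory scales with the total number of UMIs, so restrict `cids` (or use a
#' small configuration) for large datasets.
#'
#' @param dataset A `synthetic_dataset`, or a sparse genes x CIDs count
#'   matrix.
#' @param config A `sim_config` (defaults to the dataset's own).
#' @param cids Optional subset of CID barcodes to expand.
#' @param seed Optional seed (defaults to `config$seed + 1`).
#' @return Data frame with columns `cid`, `gene`, `umi` (observed sequence),
#'   `true_umi` and `reads`, one row per observed (cid, gene, umi, true_umi)
#'   group.
#' @export
emit_tagged_reads <- function(dataset, config = NULL, cids = NULL,
                              seed = NULL) {
  if (inherits(dataset, "synthetic_dataset")) {
    counts <- dataset$counts
    if (is.null(config)) config <- dataset$config
  } else counts <- as_count_matrix(dataset)
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(cids)) counts <- counts[, cids, drop = FALSE]
  if (is.null(seed) && !is.null(config$seed)) seed <- config$seed + 1

  L <- config$umi_length
  tm <- as(counts, "TsparseMatrix")
  k <- as.integer(tm@x)                      # true UMIs per (cid, gene)
  if (length(k) == 0)
    return(data.frame(cid = character(0), gene = character(0),
                      umi = character(0), true_umi = character(0),
                      reads = integer(0), stringsAsFactors = FALSE))
  entry_cid <- colnames(counts)[tm@j + 1L]
  entry_gene <- rownames(counts)[tm@i + 1L]

  with_seed(seed, {
    U <- sum(k)
    cid_u <- rep(entry_cid, k)
    gene_u <- rep(entry_gene, k)
    base_mat <- matrix(UMI_BASES[sample.int(4L, U * L, replace = TRUE)],
                       nrow = U, ncol = L)
    umi_u <- do.call(paste0, as.data.frame(base_mat,
                                           stringsAsFactors = FALSE))
    # Collision check within (cid, gene)
    if (anyDuplicated(paste(rep(seq_along(k), k), umi_u)))
      warning("UMI space collision: identical UMI drawn twice for one ",
              "(cid, gene) pair", call. = FALSE)

    reads_u <- 1L + rpois(U, config$reads_per_umi_mean - 1)
    n_err <- rbinom(U, reads_u, config$umi_error_rate)

    clean <- reads_u - n_err
    keep <- clean > 0L
    out_clean <- data.frame(cid = cid_u[keep], gene = gene_u[keep],
                            umi = umi_u[keep], true_umi = umi_u[keep],
                            reads = clean[keep], stringsAsFactors = FALSE)

    tot_err <- sum(n_err)
    if (tot_err > 0) {
      parent <- rep(seq_len(U), n_err)
      pos <- sample.int(L, tot_err, replace = TRUE)
      shift <- sample.int(3L, tot_err, replace = TRUE)
      err_umi <- umi_u[parent]
      old <- match(substr(err_umi, pos, pos), UMI_BASES)
      newb <- UMI_BASES[((old - 1L + shift) %% 4L) + 1L]
      substr(err_umi, pos, pos) <- newb
      out_err <- data.frame(cid = cid_u[parent], gene = gene_u[parent],
                            umi = err_umi, true_umi = umi_u[parent],
                            reads = 1L, stringsAsFactors = FALSE)
      out <- rbind(out_clean, out_err)
    } else out <- out_clean

    # Aggregate duplicate (cid, gene, umi, true_umi) rows
    key <- paste(out$cid, out$gene, out$umi, out$true_umi, sep = "\x01")
    if (anyDuplicated(key)) {
      agg <- rowsum(out$reads, key)
      first <- !duplicated(key)
      out <- out[first, , drop = FALSE]
      out$reads <- as.integer(agg[match(key[first], rownames(agg)), 1L])
    }
    out <- out[order(out$cid, out$gene, out$umi, out$true_umi), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
  })
}
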