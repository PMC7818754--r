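#' Collapse tagged reads into UMI counts with single-base error correction
#'
#' Reads are grouped by `<cid, gene, umi>`; within each `(cid, gene)` pair, a
#' group whose UMI lies at Hamming distance 1 from a *strictly larger* group
#' is treated as a sequencing error of that group and merged into it. Merge
#' targets are resolved on the original (pre-merge) group sizes: each small
#' group joins its largest distance-1 neighbor, ties broken toward the
#' lexicographically smaller UMI, and chains (C -> B -> A) follow their
#' target's own merge so that all reads land on the final surviving UMI.
#' Equal-sized neighbors are never merged (the rule is asymmetric and
#' undefined on ties).
#'
#' @param groups Data frame with columns `cid`, `gene`, `umi` (fixed-length
#'   strings over A/C/G/T) and `reads` (positive integers). Duplicate rows
#'   with the same `(cid, gene, umi)` are pre-summed; extra columns (e.g.
#'   `true_umi` from [emit_tagged_reads()]) are ignored.
#' @return List with sparse genes x CIDs matrices `umi` (corrected UMI
#'   counts: surviving groups per cid/gene) and `reads` (total read counts,
#'   conserved by merging), plus `n_merged`, the number of collapsed groups.
#' @examples
#' tab <- data.frame(cid = "B1", gene = "G1",
#'                   umi = c("AAAA", "AAAT"), reads = c(10, 2))
#' collapse_umis(tab)$umi
#' @export
collapse_umis <- function(groups) {
  need <- c("cid", "gene", "umi", "reads")
  if (!all(need %in% names(groups)))
    stop("'groups' must have columns cid, gene, umi, reads", call. = FALSE)
  if (nrow(groups) == 0) {
    empty <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                  x = numeric(0), dims = c(0, 0))
    return(list(umi = empty, reads = empty, n_merged = 0L))
  }
  umi <- as.character(groups$umi)
  L <- unique(nchar(umi))
  if (length(L) != 1L)
    stop("mixed UMI lengths: all UMIs must have the same length",
         call. = FALSE)
  if (any(grepl("[^ACGT]", umi)))
    stop("UMIs must be strings over the alphabet {A, C, G, T}",
         call. = FALSE)
  reads <- as.numeric(groups$reads)
  if (any(reads < 1) || any(reads != floor(reads)))
    stop("'reads' must be positive integers", call. = FALSE)

  # Pre-sum duplicate (cid, gene, umi) rows.
  key3 <- paste(groups$cid, groups$gene, umi, sep = "\x01")
  if (anyDuplicated(key3)) {
    first <- !duplicated(key3)
    sums <- rowsum(reads, key3)
    groups <- groups[first, , drop = FALSE]
    umi <- umi[first]
    reads <- as.numeric(sums[match(key3[first], rownames(sums)), 1L])
    key3 <- key3[first]
  }
  cid <- as.character(groups$cid)
  gene <- as.character(groups$gene)
  pair <- paste(cid, gene, sep = "\x01")

  n <- length(umi)
  # For every group, scan all 3L single-base neighbors within the same
  # (cid, gene) pair; keep the largest strictly-bigger neighbor, ties broken
  # by lexicographically smaller UMI. Sizes are the original ones.
  target <- seq_len(n)
  best_reads <- reads
  best_umi <- umi
  has_target <- rep(FALSE, n)
  for (p in seq_len(L)) {
    cur <- substr(umi, p, p)
    for (b in UMI_BASES) {
      cand_umi <- umi
      substr(cand_umi, p, p) <- b
      same <- cand_umi == umi  # no-op substitution, skip
      j <- match(paste(pair, cand_umi, sep = "\x01"), key3)
      ok <- !is.na(j) & !same & reads[j] > reads
      if (!any(ok)) next
      jo <- j[ok]
      better <- reads[jo] > best_reads[ok] |
        (has_target[ok] & reads[jo] == best_reads[ok] &
           umi[jo] < best_umi[ok])
      upd <- which(ok)[better]
      ju <- jo[better]
      target[upd] <- ju
      best_reads[upd] <- reads[ju]
      best_umi[upd] <- umi[ju]
      has_target[upd] <- TRUE
    }
  }
  # Follow chains on original sizes: a group joins its target's survivor.
  while (any(target[target] != target)) target <- target[target]

  surviving <- target == seq_len(n)
  cid_f <- factor(cid)
  gene_f <- factor(gene)
  umi_mat <- Matrix::sparseMatrix(
    i = as.integer(gene_f)[surviving], j = as.integer(cid_f)[surviving],
    x = rep(1, sum(surviving)),
    dims = c(nlevels(gene_f), nlevels(cid_f)),
    dimnames = list(levels(gene_f), levels(cid_f)))
  read_mat <- Matrix::sparseMatrix(
    i = as.integer(gene_f), j = as.integer(cid_f), x = reads,
    dims = c(nlevels(gene_f), nlevels(cid_f)),
    dimnames = list(levels(gene_f), levels(cid_f)))
  list(umi = umi_mat, reads = read_mat, n_merged = sum(!surviving))
}
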