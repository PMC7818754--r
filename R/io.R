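# Plain-text IO: Matrix Market count matrices with barcode/feature TSVs
# (10x layout), tagged-read tables, bulk signatures, scaling plans.

#' Write a count matrix as a Matrix Market triple
#'
#' Writes `matrix.mtx`, `barcodes.tsv` and `features.tsv` (columns: gene,
#' species, mito flag) into `dir`.
#'
#' @param counts Sparse genes x CIDs count matrix.
#' @param dir Output directory (created if missing).
#' @param features Optional features data frame (`gene`, `species`, `mito`);
#'   `NULL` derives species/mito from gene-name prefixes.
#' @return `dir`, invisibly.
#' @export
write_count_matrix <- function(counts, dir, features = NULL) {
  counts <- as_count_matrix(counts)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(counts, file.path(dir, "matrix.mtx"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  if (is.null(features)) {
    features <- data.frame(gene = rownames(counts),
                           species = gene_species(rownames(counts)),
                           mito = grepl("^(hg_|mm_)MT-", rownames(counts)),
                           stringsAsFactors = FALSE)
  } else {
    features <- features[match(rownames(counts), features$gene), ,
                         drop = FALSE]
  }
  write.table(features, file.path(dir, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a count matrix written by [write_count_matrix()]
#'
#' @param dir Directory containing `matrix.mtx`, `barcodes.tsv`,
#'   `features.tsv`.
#' @return List with `counts` (sparse genes x CIDs) and `features`.
#' @export
read_count_matrix <- function(dir) {
  counts <- as_count_matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  features <- read.delim(file.path(dir, "features.tsv"),
                         stringsAsFactors = FALSE)
  dimnames(counts) <- list(features$gene, barcodes)
  list(counts = counts, features = features)
}

#' Write / read a tagged-read table
#'
#' Tab-separated with columns `cid`, `gene`, `umi`, `reads` (plus any extra
#' columns such as `true_umi`).
#'
#' @param reads Tagged-read data frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_tagged_reads <- function(reads, path) {
  write.table(reads, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tagged_reads
#' @export
read_tagged_reads <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(cid = "character", gene = "character",
                                   umi = "character"))
  need <- c("cid", "gene", "umi", "reads")
  if (!all(need %in% names(out)))
    stop("tagged-read table needs columns cid, gene, umi, reads",
         call. = FALSE)
  out
}

#' Write / read a bulk signature CSV
#'
#' Comma-separated with columns `gene`, `species`, and one FPKM column per
#' cell type (EL4, IVA12, Jurkat, TALL104).
#'
#' @param bulk Bulk signature data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_bulk_signature <- function(bulk, path) {
  write.csv(bulk, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bulk_signature
#' @export
read_bulk_signature <- function(path) {
  bulk <- read.csv(path, stringsAsFactors = FALSE)
  bulk_matrix(bulk)  # validates the type columns
  bulk
}

#' Write a scaling plan as CSV
#'
#' @param plan A [scaling_factors()] plan.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scaling_plan <- function(plan, path) {
  write.csv(as.data.frame(plan), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
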