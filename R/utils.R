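# Internal helpers shared across stages.

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. seed = NULL uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Stage seeds derived from one root seed; offsets keep stages re-runnable
# independently. Kept below 2^31.
stage_seed <- function(root, offset) {
  if (is.null(root)) return(NULL)
  as.integer((as.numeric(root) + offset) %% .Machine$integer.max)
}

assert_fraction <- function(x, name, allow_zero = TRUE, allow_one = TRUE) {
  lo <- if (allow_zero) 0 else .Machine$double.eps
  hi <- if (allow_one) 1 else 1 - .Machine$double.eps
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < lo) || any(x > hi))
    stop(sprintf("'%s' must be a fraction in [%s, %s]", name,
                 if (allow_zero) "0" else "(0", if (allow_one) "1]" else "1)"),
         call. = FALSE)
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < min) ||
      any(x != floor(x)))
    stop(sprintf("'%s' must be integer(s) >= %d", name, min), call. = FALSE)
  invisible(x)
}

# Coerce to sparse column-compressed counts, keeping dimnames.
as_count_matrix <- function(x) {
  if (is(x, "dgCMatrix")) return(x)
  as(as(as(x, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}

# log(x + 1) correlation of count columns against bulk FPKM columns.
# Returns a cells x signatures matrix; zero-variance cells give NA.
signature_correlation <- function(counts, signature) {
  stopifnot(nrow(counts) == nrow(signature))
  lx <- log1p(as.matrix(counts))
  ly <- log1p(as.matrix(signature))
  suppressWarnings(t(cor(ly, lx)))  # cells x signatures after transpose
}

# FPKM matrix (genes x cell types) from a bulk signature data frame.
bulk_matrix <- function(bulk, types = BARNYARD_TYPES) {
  missing <- setdiff(types, colnames(bulk))
  if (length(missing))
    stop("bulk signature is missing cell type(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  m <- as.matrix(bulk[, types, drop = FALSE])
  rownames(m) <- bulk$gene
  storage.mode(m) <- "double"
  m
}

# Species of each gene from a features table or from hg_/mm_ name prefixes.
gene_species <- function(genes) {
  sp <- rep(NA_character_, length(genes))
  sp[startsWith(genes, SPECIES_PREFIX[["human"]])] <- "human"
  sp[startsWith(genes, SPECIES_PREFIX[["mouse"]])] <- "mouse"
  if (anyNA(sp))
    stop("gene names must carry an 'hg_' or 'mm_' species prefix",
         call. = FALSE)
  sp
}
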