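#' Per-cell detection statistics
#'
#' For every CID: number of UMIs (column total), number of genes with at
#' least one count, total reads (when a per-CID read total is supplied),
#' reads per UMI, reads per gene, and the mitochondrial count fraction.
#' Ratios of a zero denominator are reported as `NA`.
#'
#' @param counts Sparse genes x CIDs UMI count matrix.
#' @param reads_per_cid Optional named vector of read totals per CID.
#' @param features Features data frame with `gene` and `mito` columns;
#'   `NULL` flags genes whose name (after the species prefix) starts with
#'   `"MT-"`.
#' @return Data frame with one row per CID: `cid`, `n_umi`, `n_gene`,
#'   `reads`, `reads_per_umi`, `reads_per_gene`, `mito_frac`.
#' @export
detection_stats <- function(counts, reads_per_cid = NULL, features = NULL) {
  counts <- as_count_matrix(counts)
  n_umi <- Matrix::colSums(counts)
  n_gene <- Matrix::colSums(counts > 0)
  if (is.null(features)) {
    mito <- grepl("^(hg_|mm_)?MT-", rownames(counts))
  } else {
    mito <- features$mito[match(rownames(counts), features$gene)]
    mito[is.na(mito)] <- FALSE
  }
  mito_counts <- Matrix::colSums(counts[mito, , drop = FALSE])
  reads <- rep(NA_real_, ncol(counts))
  if (!is.null(reads_per_cid)) {
    if (!is.null(names(reads_per_cid)))
      reads <- as.numeric(reads_per_cid[colnames(counts)])
    else reads <- as.numeric(reads_per_cid)
  }
  data.frame(
    cid = colnames(counts),
    n_umi = unname(n_umi),
    n_gene = unname(n_gene),
    reads = unname(reads),
    reads_per_umi = ifelse(n_umi > 0, reads / n_umi, NA_real_),
    reads_per_gene = ifelse(n_gene > 0, reads / n_gene, NA_real_),
    mito_frac = ifelse(n_umi > 0, mito_counts / n_umi, NA_real_),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter cells by mitochondrial count fraction
#'
#' Keeps cells whose mitochondrial fraction is strictly below `threshold`;
#' cells with an undefined fraction (zero totals) are dropped.
#'
#' @param stats A [detection_stats()] data frame.
#' @param threshold Mitochondrial fraction cutoff in (0, 1].
#' @return Character vector of retained CIDs.
#' @export
mito_filter <- function(stats, threshold = 0.2) {
  assert_fraction(threshold, "threshold", allow_zero = FALSE)
  stats$cid[!is.na(stats$mito_frac) & stats$mito_frac < threshold]
}

#' Gene accumulation curve over pooled cells
#'
#' For each pool size, repeatedly samples that many cells without
#' replacement from one cell type's pool, sums their counts, and counts
#' genes with at least one count; reports the mean (and SD) across
#' iterations.
#'
#' @param counts Sparse genes x cells count matrix of one cell type's pool.
#' @param sizes Pool sizes (default 1:50). Sizes exceeding the pool are
#'   capped with a warning.
#' @param iterations Random pools per size (default 50).
#' @param seed Optional seed.
#' @return Data frame with columns `size`, `mean_genes`, `sd_genes`.
#' @export
gene_accumulation <- function(counts, sizes = 1:50, iterations = 50,
                              seed = NULL) {
  counts <- as_count_matrix(counts)
  n <- ncol(counts)
  if (n == 0) stop("empty cell pool", call. = FALSE)
  if (max(sizes) > n) {
    warning(sprintf("pool has %d cells; sizes capped", n), call. = FALSE)
    sizes <- unique(pmin(sizes, n))
  }
  with_seed(seed, {
    rows <- lapply(sizes, function(s) {
      g <- vapply(seq_len(iterations), function(it) {
        cols <- sample.int(n, s)
        sum(Matrix::rowSums(counts[, cols, drop = FALSE]) > 0)
      }, numeric(1))
      data.frame(size = s, mean_genes = mean(g), sd_genes = sd(g))
    })
    do.call(rbind, rows)
  })
}

#' Fit the exponential dropout model and derive GD50
#'
#' Nonlinear least squares fit of the dropout curve `f(x) = a * exp(-b * x)`
#' to per-gene dropout fractions against bulk expression `x` (FPKM),
#' initialized at `a = 1`, `b = ln(2) / median(x)` and bounded to
#' `a` in (0, 1.5], `b > 0`. The GD50 — the expression level at which the
#' fitted curve crosses a detection probability of 0.5 — follows in closed
#' form as `ln(2a) / b`, defined only when `a > 0.5` and `b > 0`. If the
#' bounded Gauss-Newton fit fails, a quasi-Newton fallback on log-scale
#' parameters minimizes the same sum of squares.
#'
#' @param x Per-gene bulk expression (FPKM); at least 50 positive values.
#' @param dropout Per-gene dropout fractions in `[0, 1]` (fraction of cells
#'   with a zero count).
#' @param a_max Upper bound for `a` (default 1.5).
#' @return Object of class `dropout_fit`: list with `a`, `b`, `gd50`,
#'   `residual` (sum of squared residuals), `converged`, `n_genes`, and the
#'   fitted data.
#' @examples
#' x <- exp(seq(log(0.1), log(500), length.out = 100))
#' fit <- fit_dropout(x, exp(-0.05 * x))
#' fit$gd50  # ln(2)/0.05
#' @export
fit_dropout <- function(x, dropout, a_max = 1.5) {
  keep <- is.finite(x) & is.finite(dropout) & x > 0
  x <- x[keep]
  dropout <- dropout[keep]
  if (length(x) < 50)
    stop("need at least 50 genes with positive expression", call. = FALSE)
  assert_fraction(dropout, "dropout")
  b0 <- log(2) / median(x)
  converged <- TRUE
  fit <- tryCatch(
    nls(dropout ~ a * exp(-b * x), start = list(a = 1, b = b0),
        algorithm = "port", lower = c(a = 1e-8, b = 1e-12),
        upper = c(a = a_max, b = Inf),
        control = nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- coef(fit)
    a <- unname(cf["a"])
    b <- unname(cf["b"])
  } else {
    # Fallback: quasi-Newton on log-parameters (always returns a value).
    sse <- function(p) {
      a <- min(exp(p[1]), a_max)
      sum((dropout - a * exp(-exp(p[2]) * x))^2)
    }
    op <- optim(c(0, log(b0)), sse, method = "BFGS",
                control = list(maxit = 500))
    a <- min(exp(op$par[1]), a_max)
    b <- exp(op$par[2])
    converged <- op$convergence == 0
  }
  residual <- sum((dropout - a * exp(-b * x))^2)
  gd50 <- if (a > 0.5 && b > 0) log(2 * a) / b else NA_real_
  out <- list(a = a, b = b, gd50 = gd50, residual = residual,
              converged = converged, n_genes = length(x),
              x = x, dropout = dropout)
  class(out) <- "dropout_fit"
  out
}

#' @export
print.dropout_fit <- function(x, ...) {
  cat("Exponential dropout model: a * exp(-b * x)\n")
  cat(sprintf("  a = %.4f, b = %.5g (%d genes%s)\n", x$a, x$b, x$n_genes,
              if (x$converged) "" else "; NOT converged"))
  if (is.na(x$gd50)) {
    cat("  GD50: undefined (curve never reaches 0.5)\n")
  } else {
    cat(sprintf("  GD50 = %.2f FPKM\n", x$gd50))
  }
  invisible(x)
}

#' @export
coef.dropout_fit <- function(object, ...) c(a = object$a, b = object$b)

#' @export
predict.dropout_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x
       else if (is.list(newdata)) newdata$x else newdata
  object$a * exp(-object$b * x)
}

#' @export
plot.dropout_fit <- function(x, ...) {
  plot(x$x, x$dropout, log = "x", xlab = "bulk expression (FPKM)",
       ylab = "dropout rate", col = "grey50", ...)
  xs <- exp(seq(log(min(x$x)), log(max(x$x)), length.out = 200))
  lines(xs, predict(x, xs), col = "red", lwd = 2)
  if (!is.na(x$gd50)) abline(v = x$gd50, lty = 2)
  invisible(x)
}

#' Per-gene dropout fractions for one cell type
#'
#' Fraction of cells with a zero count, per gene, restricted to the genes of
#' the cell type's species.
#'
#' @param counts Sparse genes x cells matrix of the type's cells.
#' @param species_genes Character vector of that species' gene names.
#' @return Named numeric vector of dropout fractions.
#' @export
dropout_fractions <- function(counts, species_genes) {
  counts <- as_count_matrix(counts)
  sub <- counts[intersect(species_genes, rownames(counts)), , drop = FALSE]
  if (ncol(sub) == 0) stop("no cells", call. = FALSE)
  1 - Matrix::rowSums(sub > 0) / ncol(sub)
}

#' Dropout models within UMI-quantile bins
#'
#' Cells are split into `n_bins` equal-occupancy bins by their total UMI
#' count (rank-based, so occupancies differ by at most one cell). For every
#' (bin, cell type) with at least `cells_per_fit` cells, `iterations` random
#' subsets of `cells_per_fit` cells are drawn, a dropout model is fitted to
#' each against the type's bulk FPKM over its species' genes, and the
#' parameters and GD50 are averaged across iterations.
#'
#' @param counts Sparse genes x CIDs count matrix.
#' @param labels Named character vector (cid -> cell type) of classified
#'   cells; unclassified CIDs are ignored.
#' @param bulk Bulk signature data frame.
#' @param features Features data frame (`gene`, `species`).
#' @param n_bins Number of UMI-quantile bins (default 6).
#' @param cells_per_fit Cells per fitted subset (default 50).
#' @param iterations Random subsets per (bin, type) (default 50).
#' @param seed Optional seed.
#' @return Data frame with one row per fitted (bin, type): `bin`, `type`,
#'   `n_cells`, `mean_a`, `mean_b`, `mean_gd50`, `n_fits` (iterations with a
#'   defined GD50).
#' @export
binned_dropout <- function(counts, labels, bulk, features,
                           n_bins = 6, cells_per_fit = 50, iterations = 50,
                           seed = NULL) {
  counts <- as_count_matrix(counts)
  labels <- labels[names(labels) %in% colnames(counts)]
  labels <- labels[labels %in% BARNYARD_TYPES]
  cells <- names(labels)
  n_umi <- Matrix::colSums(counts[, cells, drop = FALSE])
  bin <- ceiling(rank(n_umi, ties.method = "first") * n_bins / length(cells))
  bm <- bulk_matrix(bulk)
  with_seed(seed, {
    rows <- list()
    for (bn in seq_len(n_bins)) {
      for (ty in BARNYARD_TYPES) {
        pool <- cells[bin == bn & labels == ty]
        if (length(pool) < cells_per_fit) next
        sp_genes <- features$gene[features$species == TYPE_SPECIES[ty]]
        xs <- bm[sp_genes, ty]
        pos <- xs > 0
        res <- vapply(seq_len(iterations), function(it) {
          sub <- sample(pool, cells_per_fit)
          dr <- dropout_fractions(counts[, sub, drop = FALSE], sp_genes)
          ft <- fit_dropout(xs[pos], dr[pos])
          c(ft$a, ft$b, ft$gd50)
        }, numeric(3))
        rows[[length(rows) + 1L]] <- data.frame(
          bin = bn, type = ty, n_cells = length(pool),
          mean_a = mean(res[1, ]), mean_b = mean(res[2, ]),
          mean_gd50 = mean(res[3, ], na.rm = TRUE),
          n_fits = sum(!is.na(res[3, ])), stringsAsFactors = FALSE)
      }
    }
    if (!length(rows))
      stop("no (bin, type) combination had enough cells", call. = FALSE)
    do.call(rbind, rows)
  })
}
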