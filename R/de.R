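#' Library-size normalize and log-transform a count matrix
#'
#' Each count is divided by its cell's total, multiplied by 10^4, and
#' transformed as `log2(x + 1)`. Zeros map to zero, so sparsity is
#' preserved; zero-total cells are excluded with a warning.
#'
#' @param counts Sparse genes x CIDs count matrix.
#' @return Sparse genes x CIDs matrix of normalized log expression.
#' @examples
#' m <- Matrix::Matrix(c(10, 0, 9990, 0), 2, 2, sparse = TRUE)
#' @export
normalize_counts <- function(counts) {
  counts <- as_count_matrix(counts)
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) {
    warning(sprintf("%d zero-total cell(s) excluded", sum(totals == 0)),
            call. = FALSE)
    counts <- counts[, totals > 0, drop = FALSE]
    totals <- totals[totals > 0]
  }
  per_col <- diff(counts@p)
  counts@x <- log2(counts@x / rep(totals, per_col) * 1e4 + 1)
  counts
}

#' Two-part hurdle differential expression test
#'
#' Per gene, combines (1) a binomial likelihood-ratio test comparing
#' detection frequencies between groups and (2) a Gaussian likelihood-ratio
#' test comparing mean expression among detected (nonzero) values. The
#' summed statistic is referred to a chi-square with degrees of freedom
#' equal to the number of estimable parts: the discrete part counts when
#' detection varies (neither all-zero nor all-detected overall), the
#' continuous part when both groups contain detected cells and at least
#' three cells are detected in total. Genes with no estimable part (e.g.
#' all-zero in both groups) get p = 1.
#'
#' @param normA,normB Genes x cells matrices of normalized expression for
#'   the two groups (same genes, same order); each group needs >= 2 cells.
#' @return Named vector of per-gene p-values.
#' @export
hurdle_test <- function(normA, normB) {
  if (ncol(normA) < 2 || ncol(normB) < 2)
    stop("each group needs at least 2 cells", call. = FALSE)
  if (nrow(normA) != nrow(normB))
    stop("groups must share the same gene universe", call. = FALSE)
  A <- as.matrix(normA)
  B <- as.matrix(normB)
  nA <- ncol(A)
  nB <- ncol(B)
  dA <- A > 0
  dB <- B > 0
  kA <- rowSums(dA)
  kB <- rowSums(dB)
  k <- kA + kB
  n <- nA + nB

  # Part 1: binomial LRT on detection frequency.
  ll <- function(kk, nn) {
    p <- kk / nn
    out <- numeric(length(kk))
    pos <- kk > 0
    out[pos] <- out[pos] + kk[pos] * log(p[pos])
    sub <- kk < nn
    out[sub] <- out[sub] + (nn - kk[sub]) * log(1 - p[sub])
    out
  }
  d1 <- 2 * (ll(kA, nA) + ll(kB, nB) - ll(k, n))
  est1 <- k > 0 & k < n
  d1[!est1] <- 0

  # Part 2: Gaussian LRT on the mean of detected values.
  sA <- rowSums(A * dA)
  sB <- rowSums(B * dB)
  qA <- rowSums(A^2 * dA)
  qB <- rowSums(B^2 * dB)
  rss1 <- pmax(0, qA - ifelse(kA > 0, sA^2 / kA, 0)) +
          pmax(0, qB - ifelse(kB > 0, sB^2 / kB, 0))
  rss0 <- pmax(0, (qA + qB) - ifelse(k > 0, (sA + sB)^2 / k, 0))
  est2 <- kA >= 1 & kB >= 1 & k >= 3 & rss0 > 0
  d2 <- numeric(length(kA))
  ok <- est2 & rss1 > 0
  d2[ok] <- k[ok] * (log(rss0[ok]) - log(rss1[ok]))
  d2[est2 & rss1 == 0] <- Inf  # groups separate perfectly
  d2[!est2] <- 0

  df <- est1 + est2
  stat <- d1 + d2
  p <- rep(1, length(stat))
  pos <- df > 0
  p[pos] <- pchisq(stat[pos], df = df[pos], lower.tail = FALSE)
  names(p) <- rownames(A)
  p
}

#' Wilcoxon rank-sum differential expression test
#'
#' Per-gene two-sided rank-sum test with tie correction and the
#' continuity-corrected normal approximation. Genes with all-tied values
#' (e.g. all zero) get p = 1.
#'
#' @inheritParams hurdle_test
#' @return Named vector of per-gene p-values.
#' @export
wilcoxon_test <- function(normA, normB) {
  if (ncol(normA) < 2 || ncol(normB) < 2)
    stop("each group needs at least 2 cells", call. = FALSE)
  if (nrow(normA) != nrow(normB))
    stop("groups must share the same gene universe", call. = FALSE)
  A <- as.matrix(normA)
  B <- as.matrix(normB)
  nA <- ncol(A)
  nB <- ncol(B)
  n <- nA + nB
  p <- vapply(seq_len(nrow(A)), function(g) {
    v <- c(A[g, ], B[g, ])
    r <- rank(v)
    w <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
    ties <- table(v)
    tie_term <- sum(ties^3 - ties)
    sigma2 <- nA * nB / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    mu <- nA * nB / 2
    z <- w - mu
    z <- z - sign(z) * 0.5  # continuity correction
    2 * pnorm(-abs(z) / sqrt(sigma2))
  }, numeric(1))
  p <- pmin(p, 1)
  names(p) <- rownames(A)
  p
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment of a p-value vector.
#'
#' @param pvalues Vector of p-values in `[0, 1]`.
#' @return Adjusted values (same length and names).
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(pvalues, method = "BH")
}

#' Repeated down-sampled differential expression testing
#'
#' Samples `n` cells per group without replacement, runs the chosen test and
#' BH adjustment, and counts genes significant at `fdr < alpha`; repeated
#' `reps` times to estimate the mean number of DE genes with a Student-t 95%
#' confidence interval.
#'
#' @param normA,normB Genes x cells normalized matrices of the two groups.
#' @param n Cells per group per repetition (default 199, capped with a
#'   warning when a group is smaller).
#' @param reps Repetitions (default 10).
#' @param seed Optional seed.
#' @param test `"hurdle"` or `"wilcoxon"`.
#' @param alpha FDR significance threshold (default 1e-4).
#' @return List with `mean_nde`, `sd_nde`, `ci` (95% t-interval),
#'   `n_de` (per-rep counts), `sig_genes` (per-rep significant gene sets),
#'   `n_used`, `test`.
#' @export
subsample_and_test <- function(normA, normB, n = 199, reps = 10,
                               seed = NULL, test = c("hurdle", "wilcoxon"),
                               alpha = 1e-4) {
  test <- match.arg(test)
  n_use <- min(n, ncol(normA), ncol(normB))
  if (n_use < n)
    warning(sprintf("groups have %d / %d cells; n capped at %d",
                    ncol(normA), ncol(normB), n_use), call. = FALSE)
  fun <- if (test == "hurdle") hurdle_test else wilcoxon_test
  with_seed(seed, {
    sig_sets <- vector("list", reps)
    counts <- numeric(reps)
    for (r in seq_len(reps)) {
      sa <- normA[, sample.int(ncol(normA), n_use), drop = FALSE]
      sb <- normB[, sample.int(ncol(normB), n_use), drop = FALSE]
      fdr <- bh_fdr(fun(sa, sb))
      sig <- names(fdr)[!is.na(fdr) & fdr < alpha]
      sig_sets[[r]] <- sig
      counts[r] <- length(sig)
    }
    m <- mean(counts)
    s <- sd(counts)
    half <- if (reps > 1 && s > 0) qt(0.975, reps - 1) * s / sqrt(reps)
            else 0
    list(mean_nde = m, sd_nde = s, ci = c(m - half, m + half),
         n_de = counts, sig_genes = sig_sets, n_used = n_use, test = test)
  })
}

#' Score single-cell DE calls against bulk fold-change ground truth
#'
#' A gene is bulk-true when its pseudocounted bulk fold change
#' `(FPKM_A + 1) / (FPKM_B + 1)` exceeds `fc_threshold` in either direction.
#' True positives are significant single-cell DE genes that are bulk-true;
#' false positives are significant but not bulk-true; false negatives are
#' bulk-true but not significant. Recall = TP / (TP + FN),
#' precision = TP / (TP + FP) (NA when no gene is called significant).
#'
#' @param bulkA,bulkB Named FPKM vectors of the two cell types over a shared
#'   gene universe.
#' @param sc_significant Character vector of significant single-cell DE
#'   genes.
#' @param fc_threshold Bulk fold-change threshold (default 1.5).
#' @return List with `tp`, `fp`, `fn`, `recall`, `precision`, `n_true`.
#' @examples
#' bulk_truth_and_score(c(g1 = 10, g2 = 5), c(g1 = 1, g2 = 5), "g1")
#' @export
bulk_truth_and_score <- function(bulkA, bulkB, sc_significant,
                                 fc_threshold = 1.5) {
  genes <- intersect(names(bulkA), names(bulkB))
  if (length(genes) == 0) stop("empty gene universe", call. = FALSE)
  fc <- (bulkA[genes] + 1) / (bulkB[genes] + 1)
  truth <- fc > fc_threshold | fc < 1 / fc_threshold
  sig <- genes %in% sc_significant
  tp <- sum(sig & truth)
  fp <- sum(sig & !truth)
  fn <- sum(!sig & truth)
  list(tp = tp, fp = fp, fn = fn,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       n_true = sum(truth))
}
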