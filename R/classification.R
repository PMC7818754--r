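#' Select marker genes from a bulk signature
#'
#' A gene is a marker if it is highly expressed (FPKM > `fpkm_min` in at
#' least one of the four bulk samples) and strongly variable within its
#' species contrast: `|ln(x_A + 1) - ln(x_B + 1)| > ln_fc_min` between the
#' two cell types of the gene's species (EL4 vs IVA12 for mouse genes,
#' Jurkat vs TALL-104 for human genes).
#'
#' @param bulk Bulk signature data frame (`gene`, `species`, one FPKM column
#'   per cell type), e.g. from [bulk_signature()] or [read_bulk_signature()].
#' @param fpkm_min Expression filter (default 50 FPKM).
#' @param ln_fc_min Natural-log fold-difference filter (default 3), computed
#'   with a +1 pseudocount.
#' @return Object of class `marker_panel`: data frame with columns `gene`,
#'   `species`, `contrast`, `up_type` (the higher-expressing type) and
#'   `ln_fc`.
#' @export
select_markers <- function(bulk, fpkm_min = 50, ln_fc_min = 3) {
  bm <- bulk_matrix(bulk)
  species <- if ("species" %in% names(bulk)) bulk$species
             else gene_species(bulk$gene)
  rows <- lapply(c("human", "mouse"), function(sp) {
    pair <- BARNYARD_TYPES[TYPE_SPECIES == sp]
    idx <- which(species == sp)
    a <- bm[idx, pair[1]]
    b <- bm[idx, pair[2]]
    ln_fc <- log(a + 1) - log(b + 1)
    keep <- apply(bm[idx, , drop = FALSE], 1, max) > fpkm_min &
      abs(ln_fc) > ln_fc_min
    data.frame(gene = bulk$gene[idx][keep], species = sp,
               contrast = paste(pair, collapse = "-vs-"),
               up_type = ifelse(ln_fc[keep] > 0, pair[1], pair[2]),
               ln_fc = ln_fc[keep], stringsAsFactors = FALSE)
  })
  panel <- do.call(rbind, rows)
  rownames(panel) <- NULL
  if (!all(c("human", "mouse") %in% panel$species))
    stop("marker panel is empty for at least one species; ",
         "lower the filter thresholds or check the bulk signature",
         call. = FALSE)
  class(panel) <- c("marker_panel", "data.frame")
  panel
}

#' Correlation classification rules
#'
#' Threshold rules on the vector of Pearson correlations
#' `f = (f_EL4, f_IVA12, f_Jurkat, f_TALL104)` between a cell's ln(count+1)
#' profile and each bulk ln(FPKM+1) signature over the marker panel. A cell
#' is assigned to a type when its correlation with that type exceeds the
#' type's minimum *and* the correlations with all other types stay below
#' their maxima; the rules are pairwise mutually exclusive. The `"relaxed"`
#' variant lowers the own-correlation minima for sparser data.
#'
#' @param variant `"standard"` or `"relaxed"`.
#' @return Object of class `rule_set`: list with `variant`, `own_min` (named
#'   minimum own-correlation per type) and `other_max` (named maximum
#'   allowed correlation with each type when it is not the assigned one).
#' @export
classification_rules <- function(variant = c("standard", "relaxed")) {
  variant <- match.arg(variant)
  own_min <- switch(variant,
    standard = c(EL4 = 0.60, IVA12 = 0.60, Jurkat = 0.40, TALL104 = 0.40),
    relaxed  = c(EL4 = 0.40, IVA12 = 0.40, Jurkat = 0.35, TALL104 = 0.25))
  other_max <- c(EL4 = 0.05, IVA12 = 0.05, Jurkat = 0.05, TALL104 = 0.20)
  out <- list(variant = variant, own_min = own_min, other_max = other_max)
  class(out) <- "rule_set"
  out
}

#' @export
print.rule_set <- function(x, ...) {
  cat(sprintf("Classification rules (%s)\n", x$variant))
  for (ty in names(x$own_min))
    cat(sprintf("  %-8s own > %.2f, others < (%s)\n", ty, x$own_min[ty],
                paste(sprintf("%s %.2f", names(x$other_max)[
                  names(x$other_max) != ty],
                  x$other_max[names(x$other_max) != ty]), collapse = ", ")))
  invisible(x)
}

# Apply a rule set to a cells x 4 correlation matrix -> label vector.
apply_rules <- function(f, rules) {
  types <- names(rules$own_min)
  hits <- matrix(FALSE, nrow(f), length(types),
                 dimnames = list(rownames(f), types))
  for (ty in types) {
    others <- setdiff(types, ty)
    ok <- f[, ty] > rules$own_min[ty]
    for (ot in others) ok <- ok & f[, ot] < rules$other_max[ot]
    ok[is.na(ok)] <- FALSE
    hits[, ty] <- ok
  }
  n_hit <- rowSums(hits)
  label <- rep("unclassified", nrow(f))
  one <- n_hit == 1L
  label[one] <- types[max.col(hits[one, , drop = FALSE])]
  # Safeguard (rules are exclusive, so this is a no-op in practice):
  label[n_hit > 1L] <- "unclassified"
  label
}

#' Classify CIDs against bulk signatures by marker-panel correlation
#'
#' Restricts to the top `2 * n_expected` CIDs by total count, computes the
#' Pearson correlation between `ln(count + 1)` and `ln(FPKM + 1)` over the
#' marker panel for each of the four bulk signatures, and applies the
#' threshold rules. CIDs whose correlation vector satisfies no rule (or has
#' zero variance over the panel) are `"unclassified"`.
#'
#' @param counts Sparse genes x CIDs count matrix.
#' @param bulk Bulk signature data frame.
#' @param panel A [select_markers()] panel.
#' @param rules A [classification_rules()] rule set.
#' @param n_expected Expected number of cells; `NULL` classifies every CID.
#' @return Object of class `cell_assignment`: data frame with `cid`,
#'   `label`, `total`, and correlation columns `f_EL4` .. `f_TALL104`.
#' @export
classify_cells <- function(counts, bulk, panel,
                           rules = classification_rules(),
                           n_expected = NULL) {
  counts <- as_count_matrix(counts)
  stopifnot(inherits(panel, "marker_panel"), inherits(rules, "rule_set"))
  if (!all(panel$gene %in% rownames(counts)))
    stop("marker panel genes missing from the count matrix", call. = FALSE)
  totals <- Matrix::colSums(counts)
  sel <- seq_len(ncol(counts))
  if (!is.null(n_expected)) {
    keep_n <- min(2L * as.integer(n_expected), ncol(counts))
    sel <- order(totals, decreasing = TRUE)[seq_len(keep_n)]
  }
  bm <- bulk_matrix(bulk)
  pg <- panel$gene
  f <- signature_correlation(counts[pg, sel, drop = FALSE],
                             bm[pg, , drop = FALSE])
  label <- apply_rules(f, rules)
  out <- data.frame(cid = colnames(counts)[sel], label = label,
                    total = totals[sel], stringsAsFactors = FALSE)
  fdf <- as.data.frame(f)
  names(fdf) <- paste0("f_", colnames(f))
  out <- cbind(out, fdf)
  rownames(out) <- NULL
  class(out) <- c("cell_assignment", "data.frame")
  out
}

#' @export
print.cell_assignment <- function(x, ...) {
  tab <- table(x$label)
  cat(sprintf("Cell assignment for %d CIDs:\n", nrow(x)))
  for (nm in names(tab)) cat(sprintf("  %-12s %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' Flag cross-species multiplet CIDs by the 10th-percentile rule
#'
#' Per-species total counts are summed over each species' genes. From the
#' classified cells of each species, the 10th percentile of that species'
#' totals defines a detection threshold; a CID is flagged as a multi-species
#' multiplet when its totals from *both* species strictly exceed both
#' thresholds.
#'
#' @param counts Sparse genes x CIDs count matrix of the CIDs under
#'   consideration (typically those above the inflection point).
#' @param assignment A [classify_cells()] assignment covering these CIDs.
#' @param features Features data frame with `gene` and `species` columns
#'   (`NULL` infers species from hg_/mm_ prefixes).
#' @param percentile Detection percentile (default 0.10), computed as a
#'   linear-interpolation empirical quantile.
#' @return List with `flag` (named logical per CID), `threshold_human`,
#'   `threshold_mouse`, `n_h`, `n_m` (classified human/mouse cells),
#'   `n_hm` (flagged CIDs) and `available` (FALSE when a species has fewer
#'   than 10 classified cells, in which case no flags are set).
#' @export
detect_multiplets <- function(counts, assignment, features = NULL,
                              percentile = 0.10) {
  counts <- as_count_matrix(counts)
  species <- if (is.null(features)) gene_species(rownames(counts))
             else features$species[match(rownames(counts), features$gene)]
  h_tot <- Matrix::colSums(counts[species == "human", , drop = FALSE])
  m_tot <- Matrix::colSums(counts[species == "mouse", , drop = FALSE])

  lab <- assignment$label[match(colnames(counts), assignment$cid)]
  human_types <- names(TYPE_SPECIES)[TYPE_SPECIES == "human"]
  mouse_types <- names(TYPE_SPECIES)[TYPE_SPECIES == "mouse"]
  is_h <- !is.na(lab) & lab %in% human_types
  is_m <- !is.na(lab) & lab %in% mouse_types
  n_h <- sum(is_h)
  n_m <- sum(is_m)
  if (n_h < 10 || n_m < 10) {
    warning("fewer than 10 classified cells in at least one species; ",
            "multiplet estimation unavailable", call. = FALSE)
    return(list(flag = setNames(rep(NA, ncol(counts)), colnames(counts)),
                threshold_human = NA_real_, threshold_mouse = NA_real_,
                n_h = n_h, n_m = n_m, n_hm = 0L, available = FALSE))
  }
  th_h <- quantile(h_tot[is_h], percentile, names = FALSE, type = 7)
  th_m <- quantile(m_tot[is_m], percentile, names = FALSE, type = 7)
  flag <- h_tot > th_h & m_tot > th_m
  list(flag = flag, threshold_human = th_h, threshold_mouse = th_m,
       n_h = n_h, n_m = n_m, n_hm = sum(flag), available = TRUE)
}

#' Occupancy-adjusted multiplet rate
#'
#' Cross-species multiplets are only a fraction of all multiplets; the
#' observed fraction is divided by the adjustment factor
#' `lambda = 2 * n_h * n_m / (n_h + n_m - n_hm)^2`, which estimates the
#' probability that a random two-cell multiplet is cross-species given the
#' observed species composition.
#'
#' @param n_multiplets Flagged cross-species multiplet CIDs.
#' @param n_cells CIDs above the inflection point (the denominator).
#' @param n_h,n_m Classified human / mouse cells.
#' @param n_hm Observed cross-species multiplets (typically equal to
#'   `n_multiplets`).
#' @return List with `rate` (the adjusted multiplet rate), `lambda`, and
#'   `observed_fraction`.
#' @examples
#' adjusted_multiplet_rate(5, 200, 100, 100, 5)
#' @export
adjusted_multiplet_rate <- function(n_multiplets, n_cells, n_h, n_m, n_hm) {
  if (n_h <= 0 || n_m <= 0)
    stop("need classified cells of both species (n_h > 0, n_m > 0)",
         call. = FALSE)
  if (n_cells <= 0) stop("'n_cells' must be positive", call. = FALSE)
  denom <- n_h + n_m - n_hm
  if (denom <= 0)
    stop("n_h + n_m - n_hm must be positive", call. = FALSE)
  lambda <- 2 * n_h * n_m / denom^2
  if (lambda == 0) stop("adjustment factor lambda is zero", call. = FALSE)
  observed <- n_multiplets / n_cells
  list(rate = observed / lambda, lambda = lambda,
       observed_fraction = observed)
}
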