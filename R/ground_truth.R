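#' Generate a ground-truth expression world for a barnyard mixture
#'
#' Builds the latent state behind a synthetic two-species experiment: a gene
#' universe split evenly between a human-like and a mouse-like genome (each
#' with mitochondrial genes), and a mean expression vector (FPKM-like units)
#' for each of the four cell lines. Each cell type expresses only its own
#' species' genes. Within each species, `n_markers` genes are planted with at
#' least an e^3.5-fold mean separation between the two cell types of that
#' species and a high absolute level, so that the marker filter used for
#' classification (FPKM > 50 in some sample, ln fold difference > 3) recovers
#' them from noiseless bulk signatures.
#'
#' Non-marker means are heavy-tailed (log-normal, meanlog 1, sdlog 1.5),
#' reproducing the many-lowly-expressed-genes regime that drives dropouts;
#' the two types of a species share a common base profile modulated by
#' per-type log-normal noise so their signatures are correlated but
#' distinguishable. Mitochondrial genes are given elevated means so that the
#' baseline mitochondrial fraction of simulated cells is a realistic few
#' percent.
#'
#' @param n_genes_per_species Number of genes per species (desk-scale
#'   stand-in for a genome-wide annotation).
#' @param n_markers Number of marker genes planted per within-species
#'   contrast (EL4 vs IVA12, Jurkat vs TALL-104), split evenly between the
#'   two directions. The default gives a panel of ~184 markers across both
#'   species at the default filter thresholds.
#' @param seed Integer seed; identical seeds give identical truth tables.
#'
#' @return An object of class `ground_truth`: a list with `features` (data
#'   frame: `gene`, `species`, `mito`), `means` (genes x 4 cell types matrix
#'   of FPKM-like means), `markers` (data frame of planted marker genes with
#'   their up-regulated type) and `n_genes_per_species`.
#' @examples
#' gt <- generate_ground_truth(200, n_markers = 10, seed = 1)
#' head(gt$features)
#' @export
generate_ground_truth <- function(n_genes_per_species = 1000,
                                  n_markers = 46,
                                  seed = 1L) {
  assert_count(n_genes_per_species, "n_genes_per_species", min = 1L)
  assert_count(n_markers, "n_markers", min = 1L)
  if (n_markers >= n_genes_per_species)
    stop("'n_markers' must be smaller than 'n_genes_per_species'",
         call. = FALSE)

  with_seed(seed, {
    n <- n_genes_per_species
    n_mito <- max(1L, min(13L, floor(n * 0.02)))  # 13 = mt protein genes
    species_of <- c(rep("human", n), rep("mouse", n))
    feats <- lapply(c("human", "mouse"), function(sp) {
      pre <- SPECIES_PREFIX[[sp]]
      gene <- c(paste0(pre, "MT-", seq_len(n_mito)),
                paste0(pre, "G", sprintf("%05d", seq_len(n - n_mito))))
      data.frame(gene = gene, species = sp,
                 mito = c(rep(TRUE, n_mito), rep(FALSE, n - n_mito)),
                 stringsAsFactors = FALSE)
    })
    features <- do.call(rbind, feats)

    means <- matrix(0, nrow = nrow(features), ncol = length(BARNYARD_TYPES),
                    dimnames = list(features$gene, BARNYARD_TYPES))
    marker_rows <- list()
    for (sp in c("human", "mouse")) {
      idx <- which(features$species == sp)
      pair <- BARNYARD_TYPES[TYPE_SPECIES == sp]
      base <- rlnorm(length(idx), meanlog = 1, sdlog = 1.5)
      base[features$mito[idx]] <- rlnorm(sum(features$mito[idx]),
                                         meanlog = log(50), sdlog = 0.5)
      for (ty in pair)
        means[idx, ty] <- base * rlnorm(length(idx), 0, 0.3)

      # Plant markers on non-mitochondrial genes: high in one type, at least
      # e^3.5-fold lower in the other, clearing both filter thresholds.
      cand <- idx[!features$mito[idx]]
      mk <- sample(cand, n_markers)
      up <- rep(pair, length.out = n_markers)
      hi <- exp(runif(n_markers, log(100), log(1000)))
      lo <- hi / exp(runif(n_markers, 3.5, 9))
      for (k in seq_len(n_markers)) {
        dn <- setdiff(pair, up[k])
        means[mk[k], up[k]] <- hi[k]
        means[mk[k], dn] <- lo[k]
      }
      marker_rows[[sp]] <- data.frame(
        gene = features$gene[mk], species = sp,
        contrast = paste(pair, collapse = "-vs-"),
        up_type = up, stringsAsFactors = FALSE)
    }

    out <- list(features = features, means = means,
                markers = do.call(rbind, marker_rows),
                n_genes_per_species = n, seed = seed)
    class(out) <- "ground_truth"
    out
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Barnyard ground truth\n")
  cat(sprintf("  %d genes per species (%d mitochondrial each)\n",
              x$n_genes_per_species,
              sum(x$features$mito & x$features$species == "human")))
  cat(sprintf("  %d planted markers per within-species contrast\n",
              sum(x$markers$species == "human")))
  invisible(x)
}

#' Derive a noisy bulk RNA-seq signature from ground-truth means
#'
#' Applies small multiplicative (log-normal) noise to the true mean table,
#' mimicking an independent bulk RNA-seq measurement of the four cell lines.
#'
#' @param gt A [generate_ground_truth()] object.
#' @param sdlog Log-scale noise SD (default 0.05, i.e. ~5% measurement noise).
#' @param seed Optional seed.
#' @return Data frame with columns `gene`, `species` and one FPKM column per
#'   cell type.
#' @export
bulk_signature <- function(gt, sdlog = 0.05, seed = NULL) {
  stopifnot(inherits(gt, "ground_truth"))
  with_seed(seed, {
    noisy <- gt$means * matrix(rlnorm(length(gt$means), 0, sdlog),
                               nrow = nrow(gt$means))
    data.frame(gene = gt$features$gene, species = gt$features$species,
               noisy, row.names = NULL, check.names = FALSE,
               stringsAsFactors = FALSE)
  })
}
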