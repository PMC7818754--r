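# Shared fixtures: small synthetic worlds built in code.

tiny_gt <- function(seed = 1, n_genes = 300, n_markers = 20) {
  generate_ground_truth(n_genes, n_markers, seed = seed)
}

tiny_ds <- function(seed = 1, gt = tiny_gt(seed), cells = 60,
                    lib = c(2000, 2000, 2000, 400), n_empty = 300, ...) {
  cfg <- sim_config(
    cells_per_type = c(EL4 = cells, IVA12 = cells, Jurkat = cells,
                       TALL104 = cells),
    lib_size_median = c(EL4 = lib[1], IVA12 = lib[2], Jurkat = lib[3],
                        TALL104 = lib[4]),
    n_empty = n_empty, ambient_depth_median = 20, seed = seed + 1, ...)
  simulate_cells(gt, cfg)
}

# Truth helpers
cross_species_multiplet <- function(truth) {
  truth$is_multiplet &
    grepl("EL4|IVA12", truth$label) &
    grepl("Jurkat|TALL104", truth$label)
}

singlet_cids <- function(truth) {
  truth$cid[!truth$is_empty & !truth$is_multiplet]
}

# Two-regime barcode-rank world: n_cells around cell_depth, n_ambient
# around ambient_depth (log-normal).
two_regime_totals <- function(n_cells = 500, n_ambient = 20000,
                              cell_depth = 10000, ambient_depth = 100,
                              sdlog = 0.3) {
  c(round(rlnorm(n_cells, log(cell_depth), sdlog)),
    round(rlnorm(n_ambient, log(ambient_depth), 0.8)))
}

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Literal brute-force oracle for the single-base UMI merge rule, written
# independently of the implementation: explicit O(n^2) distance matrix,
# per-group largest strictly-bigger distance-1 neighbor (ties by lex
# smaller UMI), chains followed on original sizes.
collapse_oracle <- function(umi, reads) {
  n <- length(umi)
  target <- seq_len(n)
  for (i in seq_len(n)) {
    nbr <- integer(0)
    for (j in seq_len(n)) {
      if (i != j && reads[j] > reads[i] && hamming(umi[i], umi[j]) == 1)
        nbr <- c(nbr, j)
    }
    if (length(nbr)) {
      best <- nbr[order(-reads[nbr], umi[nbr])][1]
      target[i] <- best
    }
  }
  follow <- function(i) {
    while (target[i] != i) i <- target[i]
    i
  }
  survivors <- unique(vapply(seq_len(n), follow, integer(1)))
  list(n_umi = length(survivors), reads = sum(reads))
}
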