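#' Modal sequencing depth of the high-mRNA cell population
#'
#' Fits a Gaussian kernel density estimate (normal-reference bandwidth,
#' `bw.nrd`) to log10 per-CID totals of cell-containing CIDs and returns the
#' "first significant mode": among local density maxima reaching at least
#' `significance_frac` of the global maximum density, the mode at the largest
#' depth. That mode is interpreted as the sequencing depth of the cell
#' population with the highest mRNA content and anchors library scaling.
#'
#' @param totals Per-CID totals (reads or UMIs) of cell-containing CIDs;
#'   at least 10 positive values.
#' @param significance_frac Fraction of the global maximum density a local
#'   maximum must reach to count as significant (default 0.05).
#' @return Modal depth on the original (count) scale.
#' @examples
#' d <- first_significant_mode(10^rnorm(500, 4.7, 0.1))
#' @export
first_significant_mode <- function(totals, significance_frac = 0.05) {
  totals <- as.numeric(totals)
  if (length(totals) < 10)
    stop("need at least 10 totals to locate a density mode", call. = FALSE)
  if (any(totals <= 0)) stop("totals must be positive", call. = FALSE)
  assert_fraction(significance_frac, "significance_frac")
  lx <- log10(totals)
  if (sd(lx) == 0) return(unique(totals))  # degenerate point mass
  den <- density(lx, bw = "nrd")
  y <- den$y
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                     y[2:(n - 1)] >= y[3:n], FALSE)
  sig <- is_max & y >= significance_frac * max(y)
  if (!any(sig)) sig[which.max(y)] <- TRUE
  10^max(den$x[sig])
}

#' Library scaling factors from modal depths
#'
#' Scales every library down to the shallowest one: `s_i = min(d) / d_i`,
#' so the minimum-depth library keeps factor 1 and the common target depth is
#' `min(d)`.
#'
#' @param modal_depths Positive vector of per-library modal depths, e.g. from
#'   [first_significant_mode()]; names are kept as library identifiers.
#' @return An object of class `scaling_plan`: data frame with columns
#'   `library`, `modal_depth`, `scaling_factor`.
#' @examples
#' scaling_factors(c(A = 100000, B = 50000))
#' @export
scaling_factors <- function(modal_depths) {
  d <- as.numeric(modal_depths)
  if (length(d) == 0 || any(!is.finite(d)) || any(d <= 0))
    stop("modal depths must be positive", call. = FALSE)
  libs <- names(modal_depths)
  if (is.null(libs)) libs <- paste0("lib", seq_along(d))
  plan <- data.frame(library = libs, modal_depth = d,
                     scaling_factor = min(d) / d,
                     stringsAsFactors = FALSE)
  class(plan) <- c("scaling_plan", "data.frame")
  plan
}

#' Thin a count matrix by binomial downsampling
#'
#' Replaces every count by a binomial draw with retention probability `s`,
#' the count-level equivalent of downsampling raw reads by factor `s`.
#' `s = 1` returns the matrix unchanged.
#'
#' @param counts Sparse or dense count matrix.
#' @param s Retention probability in (0, 1].
#' @param seed Optional seed.
#' @return Matrix of the same class and dimnames with thinned counts.
#' @export
downsample_counts <- function(counts, s, seed = NULL) {
  if (!is.numeric(s) || length(s) != 1L || s <= 0 || s > 1)
    stop("'s' must be a single value in (0, 1]", call. = FALSE)
  if (s == 1) return(counts)
  with_seed(seed, {
    if (is(counts, "dgCMatrix")) {
      counts@x <- as.numeric(rbinom(length(counts@x), counts@x, s))
      Matrix::drop0(counts)
    } else {
      out <- counts
      out[] <- rbinom(length(counts), as.integer(counts), s)
      out
    }
  })
}
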