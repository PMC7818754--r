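#' Build a barcode-rank curve from per-CID totals
#'
#' The transposed log-log empirical cumulative density of per-CID totals:
#' unique total values in decreasing order, each paired with the average rank
#' of its tied CIDs, on natural-log coordinates. Zero totals cannot be placed
#' on the log curve and are dropped (recorded in `n_zero`).
#'
#' @param totals Per-CID totals (reads or UMIs); at least 100 CIDs.
#' @return Object of class `rank_curve`: data frame with columns `total`,
#'   `rank`, `log_rank`, `log_total` (totals strictly decreasing), plus
#'   attributes `n_cid` and `n_zero`.
#' @examples
#' rc <- build_rank_curve(c(rpois(200, 1000), rpois(200, 10)) + 1)
#' @export
build_rank_curve <- function(totals) {
  totals <- as.numeric(totals)
  if (length(totals) < 100)
    stop("need at least 100 CIDs to build a rank curve", call. = FALSE)
  n_zero <- sum(totals == 0)
  tt <- totals[totals > 0]
  u <- sort(unique(tt), decreasing = TRUE)
  if (length(u) < 2)
    stop("degenerate rank curve: all totals are equal", call. = FALSE)
  cnt <- as.integer(table(factor(tt, levels = u)))
  hi <- cumsum(cnt)
  lo <- hi - cnt + 1L
  curve <- data.frame(total = u, rank = (lo + hi) / 2)
  curve$log_rank <- log(curve$rank)
  curve$log_total <- log(curve$total)
  attr(curve, "n_cid") <- length(totals)
  attr(curve, "n_zero") <- n_zero
  class(curve) <- c("rank_curve", "data.frame")
  curve
}

#' @export
print.rank_curve <- function(x, ...) {
  cat(sprintf("Barcode-rank curve: %d points from %d CIDs (max total %.0f)\n",
              nrow(x), attr(x, "n_cid"), x$total[1]))
  invisible(x)
}

#' @export
plot.rank_curve <- function(x, ...) {
  plot(x$rank, x$total, log = "xy", type = "l",
       xlab = "CID rank", ylab = "total count", ...)
  invisible(x)
}

#' Knee and inflection points of a barcode-rank curve
#'
#' Fits a cubic smoothing spline (default 20 degrees of freedom) to
#' log-total versus log-rank over curve points with total >= `lower_bound`,
#' then evaluates first and second derivatives on a dense uniform log-rank
#' grid. The knee is the grid argmin of the signed curvature
#' `y'' / (1 + y'^2)^(3/2)`; the inflection is the argmin of the first
#' derivative. Both are mapped back to the nearest curve point. Curves
#' without a two-regime transition (spline slope essentially constant, as on
#' a pure power law) are flagged `no_transition` with both thresholds at the
#' boundary (largest fitted rank).
#'
#' @param curve A [build_rank_curve()] object.
#' @param lower_bound Only curve points with total >= this enter the fit
#'   (default 100; the pipeline overrides it with the smallest total among
#'   classified CIDs when classification is available).
#' @param df Spline degrees of freedom (default 20; reduced if fewer points).
#' @param grid_n Grid size for derivative evaluation (default 10000).
#' @return Object of class `threshold_points`: list with `knee` and
#'   `inflection` (each `list(rank, total)`), `no_transition` flag, the
#'   fitted spline `fit`, and the evaluation `grid` (data frame with
#'   `log_rank`, `d1`, `curvature`).
#' @export
knee_inflection <- function(curve, lower_bound = 100, df = 20,
                            grid_n = 10000) {
  stopifnot(inherits(curve, "rank_curve"))
  pts <- curve[curve$total >= lower_bound, , drop = FALSE]
  if (nrow(pts) < 20)
    stop("need at least 20 curve points above 'lower_bound'", call. = FALSE)
  df_use <- min(df, nrow(pts) - 1)
  fit <- smooth.spline(pts$log_rank, pts$log_total, df = df_use)
  grid <- seq(min(pts$log_rank), max(pts$log_rank), length.out = grid_n)
  d1 <- predict(fit, grid, deriv = 1)$y
  d2 <- predict(fit, grid, deriv = 2)$y
  curvature <- d2 / (1 + d1^2)^1.5

  # No-transition check: on a single power-law regime the log-log slope is
  # essentially constant, so the slope range is small next to its magnitude.
  no_transition <- (max(d1) - min(d1)) < 0.5 * abs(median(d1))

  nearest <- function(lr) {
    i <- which.min(abs(pts$log_rank - lr))
    list(rank = pts$rank[i], total = pts$total[i])
  }
  if (no_transition) {
    boundary <- nearest(max(pts$log_rank))
    knee <- inflection <- boundary
  } else {
    knee <- nearest(grid[which.min(curvature)])
    inflection <- nearest(grid[which.min(d1)])
  }
  out <- list(knee = knee, inflection = inflection,
              no_transition = no_transition, fit = fit,
              lower_bound = lower_bound,
              grid = data.frame(log_rank = grid, d1 = d1,
                                curvature = curvature))
  class(out) <- "threshold_points"
  out
}

#' @export
print.threshold_points <- function(x, ...) {
  if (x$no_transition) {
    cat("Rank-curve thresholds: no transition detected (boundary values)\n")
  } else {
    cat("Rank-curve thresholds:\n")
  }
  cat(sprintf("  knee:       rank %.1f, total %.0f\n",
              x$knee$rank, x$knee$total))
  cat(sprintf("  inflection: rank %.1f, total %.0f\n",
              x$inflection$rank, x$inflection$total))
  invisible(x)
}

#' Cell capture and library pool efficiency
#'
#' Capture efficiency is the number of CIDs with totals strictly above the
#' inflection total divided by the number of cells loaded; library pool
#' efficiency is the fraction of all counts that fall in those CIDs.
#'
#' @param points A [knee_inflection()] object.
#' @param totals Per-CID totals of *all* CIDs (cells and ambient).
#' @param n_loaded Number of cells loaded on the instrument.
#' @return List with `capture`, `pool`, `n_above` and the `inflection_total`
#'   used as the threshold.
#' @export
efficiency_metrics <- function(points, totals, n_loaded) {
  stopifnot(inherits(points, "threshold_points"))
  if (!is.numeric(n_loaded) || n_loaded <= 0)
    stop("'n_loaded' must be positive", call. = FALSE)
  thr <- points$inflection$total
  above <- totals > thr
  list(capture = sum(above) / n_loaded,
       pool = sum(totals[above]) / sum(totals),
       n_above = sum(above),
       inflection_total = thr)
}

#' Theoretical cell capture rate under a loading model
#'
#' Three idealized loading models: `"sub_poisson"` passes through a stated
#' capture fraction (controlled bead loading); `"poisson_occupancy"` equates
#' capture with a droplet occupancy probability; `"well_poisson"` returns the
#' single-cell fraction `lambda * exp(-lambda)` of Poisson-loaded wells.
#'
#' @param model One of `"sub_poisson"`, `"poisson_occupancy"`,
#'   `"well_poisson"`.
#' @param value The stated fraction (first two models) or the mean cell
#'   occupancy `lambda` (well model, > 0).
#' @return Theoretical capture fraction.
#' @examples
#' theoretical_capture("well_poisson", 1)  # exp(-1)
#' @export
theoretical_capture <- function(model = c("sub_poisson", "poisson_occupancy",
                                          "well_poisson"), value) {
  model <- match.arg(model)
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value))
    stop("'value' must be a single finite number", call. = FALSE)
  switch(model,
    sub_poisson = ,
    poisson_occupancy = assert_fraction(value, "value"),
    well_poisson = {
      if (value <= 0) stop("'value' (lambda) must be > 0", call. = FALSE)
      value * exp(-value)
    })
}
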