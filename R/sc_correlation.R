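#' Single-cell correlation analysis
#'
#' Kendall tau-b correlation of paired single-cell fluorescence intensities
#' (e.g. a transcription factor and one of its targets), a Fisher-z
#' comparison of two independent correlations across genotypes, and a loess
#' trend for display.
#'
#' @name sc-correlation
NULL

#' Kendall tau-b rank correlation
#'
#' Tie-corrected tau: `(C - D) / sqrt((n0 - n1)(n0 - n2))` with C/D the
#' concordant/discordant pair counts, `n0 = n(n-1)/2` and `n1`/`n2` the tie
#' terms of each margin. Fluorescence data contain ties after digitization,
#' so the b-variant is the right one.
#'
#' @param x,y Numeric vectors of equal length >= 5.
#' @return tau-b in \[-1, 1\].
#' @export
kendall_tau <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 5L) stop("kendall_tau() needs at least 5 observations")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop("tau-b is undefined when a variable is entirely tied")
  }
  stats::cor(x, y, method = "kendall")
}

#' Compare two independent Kendall correlations via Fisher z
#'
#' Each tau is Fisher-transformed (`atanh`); the variance of the transform
#' for Kendall's tau uses Fieller's approximation `0.437 / (n - 4)` (the
#' Pearson-style `1 / (n - 3)` is available for sensitivity checks). The
#' difference is referred to a standard normal, two-sided.
#'
#' @param tau_1,tau_2 Correlations with |tau| < 1.
#' @param n_1,n_2 Sample sizes (>= 10).
#' @param variance `"fieller"` (default) or `"pearson"`.
#' @return List with `tau_1`, `tau_2`, `n_1`, `n_2`, `z`, `p.value`.
#' @export
compare_correlations <- function(tau_1, n_1, tau_2, n_2,
                                 variance = c("fieller", "pearson")) {
  variance <- match.arg(variance)
  stopifnot(n_1 >= 10, n_2 >= 10)
  if (abs(tau_1) >= 1 || abs(tau_2) >= 1) {
    stop("|tau| must be < 1 for the Fisher transform")
  }
  se2 <- function(n) if (variance == "fieller") 0.437 / (n - 4) else 1 / (n - 3)
  z <- (atanh(tau_1) - atanh(tau_2)) / sqrt(se2(n_1) + se2(n_2))
  list(tau_1 = tau_1, tau_2 = tau_2, n_1 = n_1, n_2 = n_2,
       z = z, p.value = min(1, 2 * stats::pnorm(-abs(z))))
}

#' Loess trend with a pointwise standard-error band
#'
#' Local linear regression (tricube weights) evaluated on a regular grid,
#' with the pointwise standard error of the fit. Thin wrapper over
#' [stats::loess()] with `degree = 1` and exact (`surface = "direct"`)
#' evaluation.
#'
#' @param x,y Numeric vectors (n >= 20).
#' @param span Loess span (default 0.75).
#' @param n_grid Number of evaluation points (default 100).
#' @return `data.frame` with columns `x`, `fit`, `se`.
#' @export
loess_trend <- function(x, y, span = 0.75, n_grid = 100L) {
  stopifnot(length(x) == length(y))
  if (length(x) < 20L) stop("loess_trend() needs at least 20 observations")
  fit <- stats::loess(y ~ x, span = span, degree = 1, family = "gaussian",
                      surface = "direct",
                      data = data.frame(x = x, y = y))
  grid <- seq(min(x), max(x), length.out = n_grid)
  pr <- stats::predict(fit, newdata = data.frame(x = grid), se = TRUE)
  data.frame(x = grid, fit = as.numeric(pr$fit), se = as.numeric(pr$se.fit))
}

#' Read a cell-by-marker intensity table
#'
#' TSV with header `cell_id`, optional `group`, then one numeric column per
#' marker. Rows with missing values are dropped with a message.
#'
#' @param path Path to the TSV file.
#' @return `data.frame`; attribute `n_dropped` counts removed rows.
#' @export
read_cells <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!"cell_id" %in% names(df)) stop("cell table must have a cell_id column")
  complete <- stats::complete.cases(df)
  if (any(!complete)) {
    message("dropping ", sum(!complete), " cells with missing intensities")
  }
  out <- df[complete, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!complete)
  out
}
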