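#' Significance threshold specifications
#'
#' A threshold is always expressed on a scan's `score` scale ("larger =
#' stronger evidence"; `-log10 P` for LDLA/EMMA, the Bayes factor for
#' BayesC), so that detection works identically across methods.
#'
#' @param kind one of `"bonferroni"`, `"bf150"`, `"pseudo_null_5pct"`,
#'   `"max_quantile_10"`, `"max_quantile_20"`.
#' @param cutoff the score cutoff.
#' @param provenance list recording how the cutoff was derived (number of
#'   tests, pseudo-null sample counts, ...).
#' @return a list of class `"threshold_spec"`.
#' @export
threshold_spec <- function(kind, cutoff, provenance = list()) {
  stopifnot(kind %in% c("bonferroni", "bf150", "pseudo_null_5pct",
                        "max_quantile_10", "max_quantile_20"),
            is.finite(cutoff))
  structure(list(kind = kind, cutoff = cutoff, provenance = provenance),
            class = "threshold_spec")
}

threshold_score_cutoff <- function(th, method) th$cutoff

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf("threshold [%s]: score cutoff %.4g\n", x$kind, x$cutoff))
  invisible(x)
}

#' Chromosome-wise Bonferroni threshold
#'
#' Rejects when `P < alpha / n_tests`, i.e. score
#' `> -log10(alpha / n_tests)`; `n_tests` is the number of scanned positions
#' on the chromosome.
#'
#' @param alpha nominal chromosome-wise level.
#' @param n_tests number of scanned positions.
#' @return a [threshold_spec()] (with `provenance$p_cutoff` carrying the
#'   P-scale cutoff `alpha / n_tests`).
#' @examples
#' bonferroni_threshold(0.05, 2854)$provenance$p_cutoff  # 1.7519e-05
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(n_tests >= 1, alpha > 0, alpha < 1)
  p_cut <- alpha / n_tests
  threshold_spec("bonferroni", -log10(p_cut),
                 provenance = list(alpha = alpha, n_tests = n_tests, p_cutoff = p_cut))
}

#' Fixed Bayes-factor threshold
#'
#' A Bayes factor of 150 is the conventional "very strong evidence" cutoff
#' used for declaring QTL in the Bayesian scan on real data.
#'
#' @param cutoff Bayes-factor cutoff (default 150).
#' @return a [threshold_spec()].
#' @export
bf_threshold <- function(cutoff = 150) {
  threshold_spec("bf150", cutoff, provenance = list(bf = cutoff))
}

#' Empirical pseudo-null thresholds
#'
#' The pseudo-null distribution is the distribution of scan statistics at
#' non-QTL positions of simulations that do contain a QTL elsewhere.  Three
#' thresholds are built from it: (a) the 5% empirical threshold — the 95th
#' percentile of the pooled per-position scores (e.g. 20 replicates x 1000
#' non-QTL positions = 20000 samples); (b) two more stringent thresholds —
#' for each replicate the most significant non-QTL score is retained, and
#' the 10% and 20% quantiles of these per-replicate extremes (taken in the
#' most-extreme direction, i.e. the 90% and 80% score quantiles) become the
#' cutoffs.  All quantiles use the type-7 linear-interpolation definition.
#'
#' @param non_qtl_scores per-position scores at non-QTL positions, pooled
#'   over replicates.
#' @param per_replicate_maxima the best (largest) non-QTL score of each
#'   replicate; at least 10 required for the stringent thresholds (pass
#'   `NULL` to get only the 5% threshold).
#' @return named list of [threshold_spec()]s: `pseudo_null_5pct`, and (if
#'   maxima are given) `max_quantile_10`, `max_quantile_20`.
#' @export
pseudo_null_thresholds <- function(non_qtl_scores, per_replicate_maxima = NULL) {
  non_qtl_scores <- non_qtl_scores[is.finite(non_qtl_scores)]
  if (length(non_qtl_scores) == 0) stop_config("no pooled pseudo-null samples")
  out <- list(pseudo_null_5pct = threshold_spec(
    "pseudo_null_5pct", quantile7(non_qtl_scores, 0.95),
    provenance = list(n_pooled = length(non_qtl_scores))))
  if (!is.null(per_replicate_maxima)) {
    if (length(per_replicate_maxima) < 10)
      stop_config("need at least 10 per-replicate maxima (got %d)",
                  length(per_replicate_maxima))
    out$max_quantile_10 <- threshold_spec(
      "max_quantile_10", quantile7(per_replicate_maxima, 0.90),
      provenance = list(n_maxima = length(per_replicate_maxima)))
    out$max_quantile_20 <- threshold_spec(
      "max_quantile_20", quantile7(per_replicate_maxima, 0.80),
      provenance = list(n_maxima = length(per_replicate_maxima)))
  }
  out
}

#' Declare the top signal of a scan
#'
#' At most one QTL is declared per scan: the position with the most extreme
#' score, and only if it beats the threshold (strictly).  Ties are broken by
#' the smallest cM position.
#'
#' @param scan a `qtl_scan`.
#' @param threshold a [threshold_spec()].
#' @return list of class `"detection_result"`: `declared` (logical),
#'   `pos_cM`, `score`, `threshold`.
#' @export
top_signal <- function(scan, threshold) {
  tb <- scan$table
  ok <- tb$flag == "ok" & !is.na(tb$score)   # +Inf (saturated Bayes factor) is a valid extreme
  if (!any(ok)) return(structure(list(declared = FALSE, pos_cM = NA_real_,
                                      score = NA_real_, threshold = threshold),
                                 class = "detection_result"))
  sc <- ifelse(ok, tb$score, -Inf)
  best <- which(sc == max(sc))[1]   # ties: positions sorted, take leftmost
  declared <- sc[best] > threshold$cutoff
  structure(list(declared = declared,
                 pos_cM = if (declared) tb$pos_cM[best] else NA_real_,
                 score = sc[best], threshold = threshold),
            class = "detection_result")
}

#' Score detections against the simulated truth
#'
#' Power is the fraction of replicates whose declared position falls within
#' `half_width` cM of a true QTL; FDR is the fraction of replicates with a
#' declaration outside every true-QTL window; the localization MSE (cM^2) is
#' the mean squared distance between the declaration and the nearest true
#' QTL, over replicates with an in-window declaration (out-of-window
#' declarations are excluded; see the package vignette).  With two QTL the
#' declaration is matched to the nearest.
#'
#' @param detections list of [top_signal()] results, one per replicate.
#' @param truth a [assign_qtl()] result (true positions in `pos_cM`), or a
#'   numeric vector of true positions.
#' @param half_width half-width of the QTL region in cM (0.5, 1 or 2).
#' @return list `mse`, `power`, `fdr`, `n_replicates`, `n_declared`
#'   (`mse` is `NA` when no in-window declaration exists).
#' @export
score_replicates <- function(detections, truth, half_width) {
  stopifnot(length(detections) >= 1, half_width > 0)
  true_pos <- if (is.numeric(truth)) truth else truth$pos_cM
  pos <- vapply(detections, function(d) d$pos_cM, 0)
  declared <- vapply(detections, function(d) isTRUE(d$declared), TRUE)
  dist <- vapply(pos, function(x) if (is.na(x)) NA_real_ else min(abs(x - true_pos)), 0)
  in_win <- declared & !is.na(dist) & dist <= half_width
  out_win <- declared & !in_win
  n <- length(detections)
  list(mse = if (any(in_win)) mean(dist[in_win]^2) else NA_real_,
       power = sum(in_win) / n,
       fdr = sum(out_win) / n,
       n_replicates = n,
       n_declared = sum(declared))
}

#' Effective number of independent tests along a scan
#'
#' Treats the score series along the chromosome as a stationary sequence and
#' returns its effective sample size, `N / (1 + 2 sum_k rho_k)`, with the
#' autocorrelation sum truncated by the initial positive/monotone sequence
#' rule (pairwise sums `Gamma_m = rho_2m + rho_2m+1` kept while positive,
#' forced non-increasing).  A highly redundant scan (smooth, family-driven
#' signal) has a small effective number of tests.
#'
#' @param scan a `qtl_scan`, or a plain numeric series.
#' @return effective number of independent tests in (0, N\]; 1 for a
#'   constant series.
#' @export
effective_tests <- function(scan) {
  x <- if (inherits(scan, "qtl_scan")) scan$table$score[scan$table$flag == "ok"] else as.numeric(scan)
  x <- x[is.finite(x)]
  N <- length(x)
  if (N < 10) stop_config("need at least 10 positions")
  if (stats::var(x) == 0) return(1)
  rho <- stats::acf(x, lag.max = N - 2, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  n_pairs <- floor(length(rho) / 2)
  Gamma <- rho[2 * seq_len(n_pairs) - 1] + rho[2 * seq_len(n_pairs)]
  ## initial positive sequence ...
  pos <- which(Gamma <= 0)
  if (length(pos) > 0) Gamma <- Gamma[seq_len(pos[1] - 1)]
  ## ... made monotone non-increasing
  if (length(Gamma) > 1) Gamma <- cummin(Gamma)
  tau <- max(2 * sum(Gamma) - 1, 1)   # integrated autocorrelation time >= 1
  min(N / tau, N)
}

#' Average per-replicate scores over the simulation factorial
#'
#' Takes a long-format data.frame of per-cell quality indicators and returns
#' the averaged grid: one value per (fixture, scenario, method, threshold,
#' window half-width) cell and indicator.  A complete design of 5 fixtures x
#' 5 scenarios x 3 methods x 3 thresholds x 3 window sizes has 675 cells per
#' indicator.
#'
#' @param cells data.frame with columns `fixture`, `scenario`, `method`,
#'   `threshold`, `half_width`, `indicator`, `value` (one row per replicate
#'   group or already-averaged cell), and optionally `n`.
#' @return data.frame of class `"quality_grid"` with the cell means and
#'   replicate counts; attribute `"missing_cells"` counts factor
#'   combinations with no data (reported, never imputed).
#' @export
aggregate_grid <- function(cells) {
  needed <- c("fixture", "scenario", "method", "threshold", "half_width",
              "indicator", "value")
  if (!all(needed %in% names(cells)))
    stop_config("cells must have columns %s", paste(needed, collapse = ", "))
  agg <- stats::aggregate(value ~ fixture + scenario + method + threshold +
                            half_width + indicator,
                          data = cells, FUN = mean, na.rm = TRUE, na.action = NULL)
  cnt <- stats::aggregate(value ~ fixture + scenario + method + threshold +
                            half_width + indicator,
                          data = cells, FUN = function(v) sum(!is.na(v)),
                          na.action = NULL)
  agg$n <- cnt$value
  full <- prod(vapply(cells[c("fixture", "scenario", "method", "threshold",
                              "half_width", "indicator")],
                      function(v) length(unique(v)), 1L))
  attr(agg, "missing_cells") <- full - nrow(agg)
  class(agg) <- c("quality_grid", "data.frame")
  agg
}

#' Marginal method means over a balanced quality grid
#'
#' @param grid an [aggregate_grid()] result.
#' @param indicator which indicator to marginalize (`"mse"`, `"power"`,
#'   `"fdr"`).
#' @return named vector of per-method means over all other factors.
#' @export
method_means <- function(grid, indicator) {
  g <- grid[grid$indicator == indicator, ]
  tapply(g$value, g$method, mean, na.rm = TRUE)
}
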