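new_qtl_scan <- function(method, pos, stat, p, score, flag, details = list()) {
  if (is.unsorted(pos, strictly = FALSE)) stop_config("scan positions must be increasing")
  structure(list(method = method,
                 table = data.frame(pos_cM = pos, stat = stat, p = p,
                                    score = score, flag = flag,
                                    stringsAsFactors = FALSE),
                 details = details),
            class = "qtl_scan")
}

#' Scan a chromosome for QTL
#'
#' The common fitting front end of the package: runs one of the three
#' whole-genome QTL mapping methods over a genotype panel and returns a
#' `qtl_scan` object, the common currency of thresholding, detection and
#' evaluation.
#'
#' * `"emma"` — per-SNP mixed-model association with a genomic relationship
#'   matrix ([emma_scan()]); statistic t, P from the standard normal.
#' * `"ldla"` — haplotype-cluster variance-component scan with a pedigree
#'   polygenic term ([ldla_scan()]); statistic LRT, P from the boundary
#'   mixture chi-squared.
#' * `"bayesc"` — Bayesian variable-selection regression
#'   ([bayesc_scan()]); statistic Bayes factor, no P.
#'
#' Every scan carries a `score` column ("larger = stronger evidence":
#' `-log10 P` for the frequentist methods, the Bayes factor for BayesC) on
#' which thresholds and detections operate within a method.
#'
#' @param y named phenotype vector.
#' @param panel a [genotype_panel()] (phased, for LDLA).
#' @param method `"emma"`, `"ldla"` or `"bayesc"`.
#' @param pedigree required for `"ldla"`.
#' @param kinship the relationship matrix: genomic G for `"emma"`, pedigree
#'   A for `"ldla"`; computed from `panel` / `pedigree` if omitted.
#' @param ... passed to the method-specific scan function.
#' @return an object of class `"qtl_scan"` with `print`, `summary` and
#'   `plot` methods.
#' @examples
#' \donttest{
#' ped <- build_pedigree(pedigree_design("large_half_sib", 200, 5), seed = 1)
#' panel <- sim_panel(ped, genetic_map(60, 50), seed = 2)
#' sc <- simulation_scenario(1)
#' qtl <- assign_qtl(panel, sc, seed = 3)
#' phen <- simulate_phenotypes(panel, ped, qtl, sc, seed = 4)
#' scan <- qtl_scan(phen$y, mask_qtl(panel, qtl), method = "emma")
#' summary(scan)
#' }
#' @export
qtl_scan <- function(y, panel, method = c("emma", "ldla", "bayesc"),
                     pedigree = NULL, kinship = NULL, ...) {
  method <- match.arg(method)
  switch(method,
    emma = {
      G <- kinship %||% genomic_relationship(subset_panel(panel, individuals = names(y)))
      emma_scan(y, panel, G, ...)
    },
    ldla = {
      if (is.null(pedigree)) stop_config("ldla needs a pedigree")
      A <- kinship %||% pedigree_nrm(pedigree)
      phased <- phase_panel(panel, pedigree)
      ldla_scan(y, phased, pedigree, A, ...)
    },
    bayesc = bayesc_scan(y, panel, ...))
}

#' @export
print.qtl_scan <- function(x, ...) {
  tb <- x$table
  ok <- tb$flag == "ok"
  cat(sprintf("qtl_scan [%s]: %d positions, %.1f-%.1f cM\n",
              x$method, nrow(tb), min(tb$pos_cM), max(tb$pos_cM)))
  if (any(ok)) {
    top <- which.max(ifelse(ok, tb$score, -Inf))
    cat(sprintf("top signal: %.2f cM, stat = %.3f%s\n", tb$pos_cM[top], tb$stat[top],
                if (!is.na(tb$p[top])) sprintf(", P = %.3g", tb$p[top]) else ""))
  }
  if (any(!ok)) cat(sprintf("%d flagged position(s)\n", sum(!ok)))
  invisible(x)
}

#' @export
summary.qtl_scan <- function(object, n_top = 5L, ...) {
  tb <- object$table
  ord <- order(-ifelse(tb$flag == "ok", tb$score, -Inf))
  out <- list(method = object$method, n = nrow(tb),
              top = tb[ord[seq_len(min(n_top, nrow(tb)))], ],
              ess = tryCatch(effective_tests(object), error = function(e) NA_real_))
  class(out) <- "summary.qtl_scan"
  out
}

#' @export
print.summary.qtl_scan <- function(x, ...) {
  cat(sprintf("qtl_scan [%s]: %d positions, effective number of tests %.1f\n",
              x$method, x$n, x$ess))
  cat("strongest signals:\n")
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' Manhattan-style plot of a scan
#'
#' Plots `-log10(1/P)`-style evidence (the scan `score`; log10 Bayes factor
#' for BayesC) against position in cM, with an optional threshold line.
#'
#' @param x a `qtl_scan`.
#' @param threshold optional [threshold_spec()] drawn as a horizontal line.
#' @param ... further arguments to [graphics::plot()].
#' @export
plot.qtl_scan <- function(x, threshold = NULL, ...) {
  tb <- x$table[x$table$flag == "ok", ]
  yv <- if (x$method == "bayesc") log10(pmax(tb$score, 1e-12)) else tb$score
  ylab <- if (x$method == "bayesc") "log10(BF)" else "log10(1/P)"
  graphics::plot(tb$pos_cM, yv, pch = 20, cex = 0.5, col = "grey25",
                 xlab = "position (cM)", ylab = ylab,
                 main = sprintf("%s scan", toupper(x$method)), ...)
  if (!is.null(threshold)) {
    cut <- if (x$method == "bayesc") log10(threshold$cutoff) else
      threshold_score_cutoff(threshold, x$method)
    graphics::abline(h = cut, col = "blue")
  }
  invisible(x)
}
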