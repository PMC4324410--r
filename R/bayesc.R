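#' BayesC configuration
#'
#' Settings for the Bayesian variable-selection regression: a point mass at
#' zero with prior inclusion probability `pi` on every SNP effect, a common
#' effect variance, and scaled-inverse-chi-squared hyperpriors.  The default
#' hyperprior scales follow the usual heuristic: the effect-variance scale
#' is matched to an expected genetic variance (half the phenotypic variance
#' by default) spread over the `pi * m` markers expected in the model with
#' average heterozygosity `2 mean(p(1-p))`, and the residual scale to half
#' the phenotypic variance; both use `nu = 4` degrees of belief and are
#' resolved against the data inside [bayesc_scan()].
#'
#' @param pi prior inclusion probability Pr(d_i = 1) (default 1/1000).
#' @param n_iter Gibbs chain length (default 100000).
#' @param burn_in discarded initial iterations (default `n_iter / 5`).
#' @param thin keep every `thin`-th post-burn-in sample.
#' @param nu degrees of freedom of both scaled-inverse-chi-squared
#'   hyperpriors.
#' @param genetic_variance_fraction phenotypic-variance fraction used to set
#'   the effect-variance prior scale.
#' @param seed integer seed for the chain.
#' @return a list of class `"bayesc_config"`.
#' @export
bayesc_config <- function(pi = 1 / 1000, n_iter = 100000L, burn_in = NULL,
                          thin = 10L, nu = 4, genetic_variance_fraction = 0.5,
                          seed = NULL) {
  stopifnot(pi > 0, pi < 1, n_iter > 0)
  burn_in <- as.integer(burn_in %||% (n_iter %/% 5L))
  if (burn_in < 0 || burn_in >= n_iter) stop_config("need n_iter > burn_in >= 0")
  structure(list(pi = pi, n_iter = as.integer(n_iter), burn_in = burn_in,
                 thin = as.integer(thin), nu = nu,
                 genetic_variance_fraction = genetic_variance_fraction,
                 seed = seed),
            class = "bayesc_config")
}

#' BayesC whole-panel regression by Gibbs sampling
#'
#' Fits `y = 1 mu + sum_i w_i d_i s_i + e` where `d_i` indicates whether SNP
#' i is in the model (prior probability `pi`) and `s_i` is its effect.  The
#' Gibbs chain samples, for every SNP in turn, the indicator from its
#' conditional odds (effect integrated out) and then the effect from its
#' conditional normal; the common effect variance and the residual variance
#' have scaled-inverse-chi-squared conditionals.  The posterior inclusion
#' probability `d_hat_i` is the post-burn-in mean of the indicator samples
#' and is converted to a per-SNP Bayes factor by [bayes_factor()].
#'
#' @param y named phenotype vector.
#' @param panel a [genotype_panel()] (dosages are centered internally;
#'   monomorphic markers are flagged and never enter the model).
#' @param config a [bayesc_config()].
#' @return a `qtl_scan` object with `stat` = Bayes factor and
#'   `score = stat`; `details` carries the full posterior summary
#'   (`d_hat`, posterior mean effects, variance components, chain size).
#' @export
bayesc_scan <- function(y, panel, config = bayesc_config()) {
  ids <- names(y)
  if (is.null(ids)) stop_config("y must be named by individual id")
  if (stats::var(y) == 0) stop_config("phenotypes have zero variance")
  sub <- subset_panel(panel, individuals = ids)
  W <- sub$dosage
  p <- colMeans(W) / 2
  poly <- colMeans(W^2) - colMeans(W)^2 > 0
  Wc <- sweep(W, 2, colMeans(W))
  Wc[, !poly] <- 0
  m <- sum(poly)
  vy <- stats::var(y)
  het <- 2 * mean(p[poly] * (1 - p[poly]))
  scale_s <- config$genetic_variance_fraction * vy / (config$pi * m * het)
  scale_e <- 0.5 * vy
  res <- with_seed(config$seed, {
    .bayesc_gibbs(as.numeric(y), Wc, config$pi, config$n_iter,
                  config$burn_in, config$thin, config$nu, scale_s,
                  config$nu, scale_e)
  })
  bf <- bayes_factor(res$d_hat, config$pi)
  bf[!poly] <- NA_real_
  d_hat <- res$d_hat; d_hat[!poly] <- NA_real_
  flag <- ifelse(poly, "ok", "monomorphic")
  new_qtl_scan(method = "bayesc", pos = sub$map$cM, stat = bf, p = rep(NA_real_, ncol(W)),
               score = bf, flag = flag,
               details = list(d_hat = d_hat, effect = res$effect,
                              n_samples = res$n_samples,
                              s2_effect = res$s2_effect,
                              s2_residual = res$s2_residual,
                              mu = res$mu, config = config,
                              marker_id = sub$map$id))
}

#' Write the BayesC posterior summary (TSV: marker, d_hat, mean effect)
#'
#' @param scan a [bayesc_scan()] result.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_bayesc_posterior <- function(scan, file) {
  stopifnot(inherits(scan, "qtl_scan"), scan$method == "bayesc")
  utils::write.table(
    data.frame(marker = scan$details$marker_id,
               d_hat = scan$details$d_hat,
               effect = scan$details$effect),
    file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Bayes factor from prior and posterior inclusion probabilities
#'
#' `BF = [d_hat / (1 - d_hat)] / [pi / (1 - pi)]` — the increase from prior
#' to posterior odds of the SNP being in the model.  With `pi = 1/1000` this
#' is `999 * d_hat / (1 - d_hat)`.  A posterior probability of exactly 1
#' (every retained chain sample included the SNP) yields `Inf`.
#'
#' @param d_hat posterior inclusion probability(ies) in \[0, 1\].
#' @param pi prior inclusion probability in (0, 1).
#' @return numeric Bayes factor(s).
#' @examples
#' bayes_factor(0.5, 1/1000)   # 999
#' bayes_factor(1/1000, 1/1000) # 1
#' @export
bayes_factor <- function(d_hat, pi) {
  if (pi <= 0 || pi >= 1) stop_config("pi must be in (0, 1)")
  if (any(d_hat < 0 | d_hat > 1, na.rm = TRUE)) stop_config("d_hat must be in [0, 1]")
  (d_hat / (1 - d_hat)) / (pi / (1 - pi))
}
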