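#' Mixed-model association scan (EMMA)
#'
#' Single-SNP association with a polygenic random effect whose covariance is
#' a genomic relationship matrix: at each marker the model
#' `y = 1 mu + u + w s + e`, `Var(u) = G s2u`, is fitted and the substitution
#' effect tested with `t = s_hat / se(s_hat)` (two-sided P from the standard
#' normal; at the sample sizes involved the difference from a t reference is
#' negligible).
#'
#' By default the variance components are estimated once by REML under the
#' no-SNP null model and reused for every marker (the standard
#' "population parameters previously determined" approximation, two orders
#' of magnitude faster); `refit = TRUE` re-estimates the variance ratio per
#' SNP with the SNP in the fixed design (exact per-locus REML on the same
#' eigenbasis).
#'
#' @param y named numeric phenotype vector (names = individual ids).
#' @param panel a [genotype_panel()]; individuals not in `y` are ignored.
#' @param G genomic [kinship matrix][genomic_relationship()] covering the
#'   phenotyped individuals.
#' @param refit re-estimate variance components per SNP (slower, exact).
#' @return a `qtl_scan` object (see [qtl_scan()]) with per-marker `stat`
#'   (t), `p`, and `score = -log10(p)`; monomorphic markers are flagged and
#'   skipped.
#' @export
emma_scan <- function(y, panel, G, refit = FALSE) {
  ids <- names(y)
  if (is.null(ids)) stop_config("y must be named by individual id")
  sub <- subset_panel(panel, individuals = ids)
  gi <- match(ids, rownames(G))
  if (anyNA(gi)) stop_config("G does not cover all phenotyped individuals")
  G <- G[gi, gi]
  n <- length(y)
  null_fit <- reml(y, random = list(G = G))
  U <- null_fit$eigen$U
  d <- null_fit$eigen$d
  yt <- null_fit$yt
  onet <- null_fit$Xt
  Wt <- crossprod(U, sub$dosage)       # rotated dosages, all markers at once
  m <- ncol(Wt)
  maf <- panel_maf(sub)
  stat <- p <- rep(NA_real_, m)
  flag <- rep("ok", m)
  s2 <- null_fit$sigma2
  w0 <- s2[1] * d + s2[2]
  for (j in seq_len(m)) {
    if (maf[j] == 0) { flag[j] <- "monomorphic"; next }
    if (refit) {
      res <- emma_refit_one(yt, cbind(onet, Wt[, j]), d)
      stat[j] <- res$t
    } else {
      iw <- 1 / w0
      x2 <- Wt[, j]
      a11 <- sum(onet^2 * iw); a12 <- sum(onet * x2 * iw); a22 <- sum(x2^2 * iw)
      b1 <- sum(onet * yt * iw); b2 <- sum(x2 * yt * iw)
      det <- a11 * a22 - a12^2
      if (det <= 0) { flag[j] <- "collinear"; next }
      mu_hat <- (a22 * b1 - a12 * b2) / det
      s_hat <- (a11 * b2 - a12 * b1) / det
      ## re-profile the overall scale on the augmented design (see
      ## gls_fixed_effect); with V = I this is exactly the OLS t
      rss <- sum(yt^2 * iw) - (mu_hat * b1 + s_hat * b2)
      se <- sqrt(a11 / det * max(rss, 1e-300) / (n - 2))
      stat[j] <- s_hat / se
    }
    p[j] <- 2 * stats::pnorm(-abs(stat[j]))
  }
  new_qtl_scan(method = "emma", pos = sub$map$cM, stat = stat, p = p,
               score = -log10(p), flag = flag,
               details = list(null_fit = null_fit, refit = refit,
                              marker_id = sub$map$id))
}

## exact per-SNP REML refit on the shared eigenbasis of G
emma_refit_one <- function(yt, Xt, d) {
  n <- length(yt); p <- ncol(Xt)
  prof <- function(logdelta) {
    w <- d + exp(logdelta)
    iw <- 1 / w
    XtWi <- Xt * iw
    XtViX <- crossprod(Xt, XtWi)
    beta <- solve(XtViX, crossprod(XtWi, yt))
    r <- yt - Xt %*% beta
    s2u <- sum(r^2 * iw) / (n - p)
    -0.5 * ((n - p) * (log(2 * pi * s2u) + 1) + sum(log(w)) +
              determinant(XtViX, logarithm = TRUE)$modulus)
  }
  opt <- stats::optimize(prof, c(-14, 14), maximum = TRUE, tol = 1e-8)
  w <- d + exp(opt$maximum)
  iw <- 1 / w
  XtWi <- Xt * iw
  XtViX <- crossprod(Xt, XtWi)
  beta <- solve(XtViX, crossprod(XtWi, yt))
  r <- yt - Xt %*% beta
  s2u <- sum(r^2 * iw) / (n - p)
  Ci <- solve(XtViX) * s2u
  k <- ncol(Xt)
  list(estimate = beta[k], se = sqrt(Ci[k, k]), t = beta[k] / sqrt(Ci[k, k]))
}
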