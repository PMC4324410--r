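#' Restricted maximum likelihood for variance-component models
#'
#' Fits `y = X b + u_1 + ... + u_K + e` with `u_k ~ N(0, V_k s2_k)` and
#' `e ~ N(0, I s2_e)` by REML.  With a single random term the restricted
#' likelihood is maximized exactly on the eigenbasis of its covariance
#' (one-dimensional profile over the variance ratio).  With several terms an
#' expectation-style fixed-point iteration is used
#' (`s2_k <- s2_k * (y'P V_k P y) / tr(P V_k)`, components floored at zero),
#' which is unconditionally stable for the small per-locus models that a
#' chromosome scan fits thousands of times.
#'
#' @param y numeric response.
#' @param X fixed-effect design matrix; `NULL` means intercept only.
#' @param random named list of random-term covariances.  Each element is
#'   either an `n x n` covariance matrix (incidence = identity) or a list
#'   `list(Z = incidence, G = covariance)`.
#' @param tol relative convergence tolerance on the restricted
#'   log-likelihood.
#' @param max_iter maximum fixed-point iterations (multi-term case).
#' @param eigen_G optional precomputed `eigen(G, symmetric = TRUE)` of the
#'   single random term's covariance, for repeated fits against the same
#'   relationship matrix (ignored with two or more terms).
#' @return an object of class `"reml_fit"`: `sigma2` (named vector incl.
#'   `residual`), `logLik` (restricted), `beta`, `se_beta`, `converged`,
#'   `iterations`.
#' @examples
#' set.seed(1)
#' A <- crossprod(matrix(rnorm(100), 10))/10 + diag(10)
#' y <- drop(chol(A) %*% rnorm(10)) + rnorm(10)
#' fit <- reml(y, random = list(animal = A))
#' fit$sigma2
#' @export
reml <- function(y, X = NULL, random, tol = 1e-6, max_iter = 200L,
                 eigen_G = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  p <- ncol(X)
  if (n < p + 2) stop_config("need n >= number of fixed effects + 2")
  if (is.null(names(random)) || any(names(random) == ""))
    names(random) <- paste0("vc", seq_along(random))
  Vk <- lapply(random, function(r) {
    if (is.list(r)) {
      Z <- as.matrix(r$Z); G <- as.matrix(r$G)
      Z %*% G %*% t(Z)
    } else as.matrix(r)
  })
  if (any(vapply(Vk, nrow, 1L) != n)) stop_config("random-term covariance dimensions must match length(y)")
  if (length(Vk) == 1L) reml_spectral(y, X, Vk, tol, eigen_G)
  else reml_em(y, X, Vk, tol, max_iter)
}

## restricted log-likelihood for a diagonalized model: weights w_i,
## rotated response yt and design Xt
rll_diag <- function(yt, Xt, w) {
  iw <- 1 / w
  XtWi <- Xt * iw
  XtViX <- crossprod(Xt, XtWi)
  beta <- solve(XtViX, crossprod(XtWi, yt))
  r <- yt - Xt %*% beta
  yPy <- sum(r^2 * iw)
  ld <- determinant(XtViX, logarithm = TRUE)$modulus
  list(logLik = -0.5 * (sum(log(w)) + ld + yPy +
                          (length(yt) - ncol(Xt)) * log(2 * pi)),
       beta = drop(beta), XtViX = XtViX, yPy = yPy)
}

## exact REML with one random covariance: profile over delta = s2e/s2u
reml_spectral <- function(y, X, Vk, tol, eigen_G = NULL) {
  n <- length(y); p <- ncol(X)
  eg <- eigen_G %||% eigen(Vk[[1]], symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)
  prof <- function(logdelta) {
    w <- d + exp(logdelta)
    iw <- 1 / w
    XtWi <- Xt * iw
    XtViX <- crossprod(Xt, XtWi)
    beta <- solve(XtViX, crossprod(XtWi, yt))
    r <- yt - Xt %*% beta
    S <- sum(r^2 * iw)
    s2u <- S / (n - p)
    -0.5 * ((n - p) * (log(2 * pi * s2u) + 1) + sum(log(w)) +
              determinant(XtViX, logarithm = TRUE)$modulus)
  }
  opt <- stats::optimize(prof, c(-14, 14), maximum = TRUE, tol = 1e-9)
  ## compare against the boundaries (effectively s2u = 0 or s2e ~ 0)
  cands <- c(opt$maximum, -14, 14)
  vals <- c(opt$objective, prof(-14), prof(14))
  logdelta <- cands[which.max(vals)]
  delta <- exp(logdelta)
  w <- d + delta
  iw <- 1 / w
  XtWi <- Xt * iw
  XtViX <- crossprod(Xt, XtWi)
  beta <- solve(XtViX, crossprod(XtWi, yt))
  r <- yt - Xt %*% beta
  s2u <- sum(r^2 * iw) / (n - p)
  s2e <- delta * s2u
  if (logdelta >= 14) { s2u_out <- 0 } else s2u_out <- s2u
  out <- rll_diag(yt, Xt, s2u * w)
  sigma2 <- stats::setNames(c(s2u_out, s2e), c(names(Vk), "residual"))
  structure(list(sigma2 = sigma2, logLik = drop(out$logLik),
                 beta = out$beta, se_beta = sqrt(diag(solve(out$XtViX))),
                 converged = TRUE, iterations = 0L,
                 method = "spectral",
                 eigen = list(U = U, d = d), yt = yt, Xt = Xt,
                 y = y, X = X),
            class = "reml_fit")
}

## expectation-style fixed-point REML for >= 2 random terms (dense algebra)
reml_em <- function(y, X, Vk, tol, max_iter) {
  n <- length(y); p <- ncol(X); K <- length(Vk)
  vy <- stats::var(y)
  s2 <- rep(vy / (K + 1), K + 1)  # components + residual
  best <- list(logLik = -Inf)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    V <- diag(s2[K + 1], n)
    for (k in seq_len(K)) V <- V + s2[k] * Vk[[k]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) { s2 <- s2 + 1e-8 * vy; next }
    Vi <- chol2inv(ch)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    XtViXi <- solve(XtViX)
    Viy <- Vi %*% y
    beta <- XtViXi %*% crossprod(X, Viy)
    r <- Viy - ViX %*% beta            # P y
    yPy <- sum(y * r)
    ll <- -0.5 * (2 * sum(log(diag(ch))) +
                    determinant(XtViX, logarithm = TRUE)$modulus +
                    yPy + (n - p) * log(2 * pi))
    if (ll > best$logLik)
      best <- list(logLik = drop(ll), sigma2 = s2, beta = drop(beta),
                   se_beta = sqrt(diag(XtViXi)), Vi = Vi)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll))) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    ## fixed-point update s2_k * (r' Vk r) / tr(P Vk); tr(P M) computed as
    ## tr(Vi M) - tr(XtViXi %*% (X'Vi M Vi X)) with symmetric elementwise sums
    for (k in seq_len(K + 1)) {
      M <- if (k <= K) Vk[[k]] else NULL
      if (k <= K) {
        num <- drop(crossprod(r, M %*% r))
        trv <- sum(Vi * M) - sum(XtViXi * crossprod(ViX, M %*% ViX))
      } else {
        num <- sum(r^2)
        trv <- sum(diag(Vi)) - sum(XtViXi * crossprod(ViX))
      }
      if (is.finite(trv) && trv > 1e-12) s2[k] <- max(s2[k] * num / trv, 1e-10 * vy)
    }
  }
  sigma2 <- stats::setNames(best$sigma2, c(names(Vk), "residual"))
  structure(list(sigma2 = sigma2, logLik = best$logLik, beta = best$beta,
                 se_beta = best$se_beta, converged = converged,
                 iterations = iter, method = "em", Vi = best$Vi,
                 y = y, X = X),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("REML fit (", x$method, ")\n", sep = "")
  cat("variance components:\n")
  print(round(x$sigma2, 6))
  cat(sprintf("restricted logLik: %.4f  (%s, %d iterations)\n",
              x$logLik, if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' @export
logLik.reml_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$sigma2), class = "logLik")
}

#' @export
coef.reml_fit <- function(object, ...) object$beta

#' Generalized least-squares estimate of a marker effect
#'
#' Adds a covariate `w` (e.g. SNP dosages) to the fixed design of a fitted
#' variance-component model and returns its GLS estimate and standard error
#' at the REML-estimated components, plus `t = estimate / se`.
#'
#' @param fit a [reml()] result.
#' @param w numeric covariate, same length and order as the response.
#' @return list with `estimate`, `se`, `t` (all `NA` and `flag = "collinear"`
#'   if `w` has no variation).
#' @export
gls_fixed_effect <- function(fit, w) {
  stopifnot(inherits(fit, "reml_fit"))
  w <- as.numeric(w)
  if (stats::var(w) == 0)
    return(list(estimate = NA_real_, se = NA_real_, t = NA_real_, flag = "collinear"))
  ## the overall scale is re-profiled on the augmented design, so that with
  ## an identity covariance the test reduces exactly to ordinary least
  ## squares (same residual degrees of freedom)
  if (fit$method == "spectral") {
    s2 <- fit$sigma2
    wts <- s2[1] * fit$eigen$d + s2[2]
    Xt <- cbind(fit$Xt, crossprod(fit$eigen$U, w))
    out <- rll_diag(fit$yt, Xt, wts)
    k <- ncol(Xt)
    n <- length(fit$yt)
    yy <- sum(fit$yt^2 / wts)
    b <- crossprod(Xt / wts, fit$yt)
    scale <- max(drop(yy - crossprod(out$beta, b)), 1e-300) / (n - k)
    Ci <- solve(out$XtViX) * scale
    est <- unname(out$beta[k])
    list(estimate = est, se = sqrt(Ci[k, k]), t = est / sqrt(Ci[k, k]), flag = "ok")
  } else {
    Vi <- fit$Vi
    X <- cbind(fit$X, w)
    XtViX <- crossprod(X, Vi %*% X)
    Ci <- solve(XtViX)
    b <- crossprod(X, Vi %*% fit$y)
    beta <- Ci %*% b
    k <- ncol(X)
    n <- length(fit$y)
    scale <- max(drop(crossprod(fit$y, Vi %*% fit$y) - crossprod(beta, b)), 1e-300) / (n - k)
    Ci <- Ci * scale
    est <- unname(drop(beta[k]))
    list(estimate = est, se = sqrt(Ci[k, k]), t = est / sqrt(Ci[k, k]), flag = "ok")
  }
}

## ---- internal fast path used by the LDLA scan -----------------------------
## Two random terms on the eigenbasis of the first: Var(y) =
## s2u * diag(d) + s2h * B H B' + s2e * I, with B low-rank (clusters).
## Woodbury identities keep every iteration O(n c^2).
reml_two_lowrank <- function(yt, Xt, d, B, H, init, tol = 1e-6, max_iter = 200L) {
  n <- length(yt); p <- ncol(Xt); cc <- ncol(B)
  s2 <- init  # c(u, h, e)
  vy <- stats::var(yt)
  best <- list(logLik = -Inf, sigma2 = s2)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  Ic <- diag(cc)
  while (iter < max_iter) {
    iter <- iter + 1L
    w <- s2[1] * d + s2[3]
    iw <- 1 / w
    C <- B * iw                       # W^-1 B
    Q <- crossprod(B, C)              # B' W^-1 B
    Km <- s2[2] * H
    IKQ <- Ic + Km %*% Q
    S <- tryCatch(solve(IKQ, Km), error = function(e) NULL)
    if (is.null(S)) { s2[2] <- s2[2] * 0.5; next }
    S <- 0.5 * (S + t(S))
    vi <- function(x) x * iw - C %*% (S %*% crossprod(C, x))
    a <- vi(Xt)                       # V^-1 X
    XtViX <- crossprod(Xt, a)
    XtViXi <- solve(XtViX)
    Viy <- drop(vi(yt))
    beta <- XtViXi %*% crossprod(Xt, Viy)
    r <- Viy - drop(a %*% beta)       # P y
    yPy <- sum(yt * r)
    ldV <- sum(log(w)) + determinant(IKQ, logarithm = TRUE)$modulus
    ll <- -0.5 * (ldV + determinant(XtViX, logarithm = TRUE)$modulus +
                    yPy + (n - p) * log(2 * pi))
    if (ll > best$logLik)
      best <- list(logLik = drop(ll), sigma2 = s2, beta = drop(beta),
                   XtViXi = XtViXi)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll))) {
      converged <- TRUE; break
    }
    ll_old <- ll
    ## traces of Vi against each component
    CtDC <- crossprod(C, d * C)
    CtC <- crossprod(C)
    trVi_D <- sum(d * iw) - sum(S * CtDC)
    trVi_I <- sum(iw) - sum(S * CtC)
    QSQ <- Q - Q %*% S %*% Q          # B' Vi B
    trVi_H <- sum(QSQ * H)
    ## fixed-effect corrections: tr(P M) = tr(Vi M) - tr(XtViXi a' M a)
    aDa <- crossprod(a, d * a)
    aa <- crossprod(a)
    Ba <- crossprod(B, a)
    aHa <- crossprod(Ba, H %*% Ba)
    trP_D <- trVi_D - sum(XtViXi * aDa)
    trP_I <- trVi_I - sum(XtViXi * aa)
    trP_H <- trVi_H - sum(XtViXi * aHa)
    Br <- drop(crossprod(B, r))
    num_u <- sum(d * r^2)
    num_h <- drop(crossprod(Br, H %*% Br))
    num_e <- sum(r^2)
    if (is.finite(trP_D) && trP_D > 1e-12) s2[1] <- max(s2[1] * num_u / trP_D, 1e-10 * vy)
    if (is.finite(trP_H) && trP_H > 1e-12) s2[2] <- max(s2[2] * num_h / trP_H, 1e-12 * vy)
    if (is.finite(trP_I) && trP_I > 1e-12) s2[3] <- max(s2[3] * num_e / trP_I, 1e-10 * vy)
  }
  list(logLik = best$logLik, sigma2 = best$sigma2, converged = converged,
       iterations = iter)
}
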