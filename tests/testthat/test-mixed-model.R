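# REML engine and GLS fixed effects.

test_that("REML drives the genetic variance to zero for pure noise", {
  set.seed(101)
  ped <- build_pedigree(pedigree_design("large_half_sib", 1000, 20), seed = 1)
  A <- pedigree_nrm(ped)
  ids <- as.character(nonfounders(ped))
  A <- A[ids, ids]
  y <- rnorm(1000)
  fit <- reml(y, random = list(u = A))
  expect_lte(fit$sigma2[["u"]] / fit$sigma2[["residual"]], 0.02)
})

test_that("REML recovers planted variance components on a known A", {
  ped <- build_pedigree(pedigree_design("large_half_sib", 500, 10), seed = 2)
  A <- pedigree_nrm(ped)
  ids <- as.character(nonfounders(ped))
  A <- A[ids, ids]
  L <- t(chol(A))
  set.seed(102)
  est <- replicate(10, {
    y <- drop(L %*% rnorm(500)) + rnorm(500)
    f <- reml(y, random = list(u = A))
    f$sigma2
  })
  expect_equal(mean(est["u", ]), 1, tolerance = 0.15)
  expect_equal(mean(est["residual", ]), 1, tolerance = 0.15)
})

test_that("nested restricted likelihoods are ordered and the EM engine agrees with the spectral one", {
  set.seed(103)
  ped <- build_pedigree(pedigree_design("large_half_sib", 200, 5), seed = 3)
  A <- pedigree_nrm(ped)
  ids <- as.character(nonfounders(ped))
  A <- A[ids, ids]
  L <- t(chol(A))
  y <- drop(L %*% rnorm(200)) + rnorm(200)
  f1 <- reml(y, random = list(u = A))
  ## a second, junk random term can only increase the restricted likelihood
  set.seed(104)
  B <- crossprod(matrix(rnorm(200 * 5), 5)) / 5 + diag(200)
  f2 <- reml(y, random = list(u = A, junk = B))
  expect_gte(f2$logLik + 1e-6, f1$logLik)
  ## same engine started from a single-component problem: EM path run on the
  ## duplicated A recovers the spectral likelihood (split arbitrary)
  f3 <- reml(y, random = list(u = A, u2 = A), tol = 1e-10, max_iter = 2000L)
  expect_equal(f3$sigma2[["u"]] + f3$sigma2[["u2"]], f1$sigma2[["u"]], tolerance = 0.05)
  expect_equal(f3$logLik, f1$logLik, tolerance = 1e-3)
})

test_that("REML matches the closed-form ANOVA estimator on a balanced design", {
  ## balanced one-way random-effects design: q groups of size k
  set.seed(105)
  q <- 40; k <- 6
  s2g <- 2; s2e <- 1
  g <- rep(rnorm(q, 0, sqrt(s2g)), each = k)
  y <- g + rnorm(q * k, 0, sqrt(s2e))
  Z <- kronecker(diag(q), matrix(1, k, 1))
  fit <- reml(y, random = list(grp = list(Z = Z, G = diag(q))))
  ## ANOVA (= REML on balanced data): s2g_hat = (MSB - MSW) / k
  grp <- rep(seq_len(q), each = k)
  msb <- k * var(tapply(y, grp, mean))
  msw <- sum((y - ave(y, grp))^2) / (q * (k - 1))
  expect_equal(fit$sigma2[["grp"]], (msb - msw) / k, tolerance = 1e-4)
  expect_equal(fit$sigma2[["residual"]], msw, tolerance = 1e-4)
})

test_that("REML estimates are invariant to consistent reordering of individuals", {
  set.seed(106)
  ped <- build_pedigree(pedigree_design("small_half_sib", 150, 30), seed = 4)
  A <- pedigree_nrm(ped)
  ids <- as.character(nonfounders(ped))
  A <- A[ids, ids]
  y <- drop(t(chol(A)) %*% rnorm(150)) + rnorm(150)
  perm <- sample(150)
  f1 <- reml(y, random = list(u = A))
  f2 <- reml(y[perm], random = list(u = A[perm, perm]))
  expect_equal(f1$sigma2, f2$sigma2, tolerance = 1e-5)
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-6)
})

test_that("GLS reduces to OLS without a genetic term and scales correctly", {
  set.seed(107)
  n <- 300
  y <- rnorm(n)
  w <- rbinom(n, 2, 0.4)
  ## sigma_u^2 = 0 case: G = I makes V proportional to I for any split
  fit <- reml(y, random = list(u = diag(n)))
  g <- gls_fixed_effect(fit, w)
  ols <- summary(lm(y ~ w))$coefficients["w", ]
  expect_equal(g$estimate, unname(ols["Estimate"]), tolerance = 1e-6)
  expect_equal(g$t, unname(ols["t value"]), tolerance = 1e-4)
  ## doubling y doubles the estimate but leaves t unchanged
  fit2 <- reml(2 * y, random = list(u = diag(n)))
  g2 <- gls_fixed_effect(fit2, w)
  expect_equal(g2$estimate, 2 * g$estimate, tolerance = 1e-6)
  expect_equal(g2$t, g$t, tolerance = 1e-4)
  ## monomorphic covariate is flagged
  expect_identical(gls_fixed_effect(fit, rep(1, n))$flag, "collinear")
})

test_that("the permutation null of the GLS t is standard normal", {
  set.seed(108)
  ped <- build_pedigree(pedigree_design("large_half_sib", 250, 6), seed = 5)
  A <- pedigree_nrm(ped)
  ids <- as.character(nonfounders(ped))
  A <- A[ids, ids]
  y <- drop(t(chol(A)) %*% rnorm(250)) + rnorm(250)
  fit <- reml(y, random = list(u = A))
  w <- rbinom(250, 2, 0.3)
  ts <- replicate(500, gls_fixed_effect(fit, sample(w))$t)
  expect_gt(ks.test(ts, "pnorm")$p.value, 0.01)
})
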