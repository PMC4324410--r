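# BayesC: Bayes-factor identities, chain behavior under null and signal.

test_that("Bayes factor is the prior-to-posterior odds ratio", {
  expect_equal(bayes_factor(0.5, 1 / 1000), 999)
  expect_equal(bayes_factor(1 / 1000, 1 / 1000), 1)
  expect_equal(bayes_factor(0.9, 1 / 1000), 8991)
  expect_identical(bayes_factor(1, 1 / 1000), Inf)
  expect_equal(bayes_factor(0, 0.01), 0)
  ## monotone increasing in d_hat for fixed pi
  d <- seq(0, 0.99, by = 0.01)
  expect_true(all(diff(bayes_factor(d, 1 / 1000)) > 0))
  expect_error(bayes_factor(0.5, 0), "pi")
  expect_error(bayes_factor(1.5, 0.5), "d_hat")
})

test_that("two chains with the same seed are identical, different seeds are not", {
  pop <- strong_qtl_pop()
  cfg <- bayesc_config(n_iter = 2000L, seed = 5)
  s1 <- bayesc_scan(pop$phen$y, pop$masked, cfg)
  s2 <- bayesc_scan(pop$phen$y, pop$masked, cfg)
  expect_identical(s1$details$d_hat, s2$details$d_hat)
  s3 <- bayesc_scan(pop$phen$y, pop$masked, bayesc_config(n_iter = 2000L, seed = 6))
  expect_false(identical(s1$details$d_hat, s3$details$d_hat))
})

test_that("a strong planted QTL drives inclusion near the masked position", {
  pop <- strong_qtl_pop()   # QTL explains 40% x 50% = 20% of phenotypic variance
  scan <- bayesc_scan(pop$phen$y, pop$masked, bayesc_config(n_iter = 10000L, seed = 7))
  tb <- scan$table
  expect_lt(abs(tb$pos_cM[which.max(tb$score)] - pop$qtl$pos_cM), 2)
  ## posterior inclusion concentrates on the correlated flanking markers
  ## (mass can split between neighbours in strong LD, so test the window)
  near <- abs(tb$pos_cM - pop$qtl$pos_cM) <= 1
  expect_gt(max(scan$details$d_hat[near], na.rm = TRUE), 0.8)
  wide <- abs(tb$pos_cM - pop$qtl$pos_cM) <= 2
  expect_gt(sum(scan$details$d_hat[wide], na.rm = TRUE), 0.9)
})

test_that("under the global null inclusion matches the prior and nothing clears BF 150", {
  pop <- strong_qtl_pop()
  m <- sum(panel_maf(pop$masked) > 0)
  pi <- 1 / 100   # a denser prior gives a sharper Monte-Carlo check of sum(d_hat)
  tot <- bf150 <- numeric(6)
  eff_null <- numeric(0)
  ids <- names(pop$phen$y)
  for (r in seq_len(6)) {
    ## pure i.i.d. noise: no genetic signal of any kind for markers to tag
    set.seed(300 + r)
    yn <- setNames(rnorm(length(ids)), ids)
    sc <- bayesc_scan(yn, pop$masked, bayesc_config(pi = pi, n_iter = 4000L, seed = r))
    tot[r] <- sum(sc$details$d_hat, na.rm = TRUE)
    bf150[r] <- sum(sc$table$score > 150, na.rm = TRUE)
    eff_null <- c(eff_null, abs(sc$details$effect[!is.na(sc$details$d_hat)]))
  }
  expect_equal(bf150, rep(0, 6))
  ## with a data-informed effect prior, noise suppresses inclusion below the
  ## prior mean (E[d_hat] <= pi under the null by Jensen's inequality)
  expect_lt(mean(tot), pi * m)
  ## prior recovery: in the weak-effect-prior limit the marginal likelihood
  ## ratio is 1, so the indicators are drawn from the prior and
  ## sum(d_hat) = pi * m up to Monte-Carlo error
  tot0 <- sapply(1:6, function(r) {
    set.seed(400 + r)
    yn <- setNames(rnorm(length(ids)), ids)
    sc <- bayesc_scan(yn, pop$masked,
                      bayesc_config(pi = pi, n_iter = 4000L, seed = 40 + r,
                                    genetic_variance_fraction = 1e-8))
    sum(sc$details$d_hat, na.rm = TRUE)
  })
  mc_se <- sd(tot0) / sqrt(length(tot0))
  expect_lt(abs(mean(tot0) - pi * m), 3 * mc_se)

  ## posterior effect shrinkage: null mean |effect| at the QTL flanks is
  ## below the planted-QTL mean |effect| there
  scan_q <- bayesc_scan(pop$phen$y, pop$masked, bayesc_config(n_iter = 4000L, seed = 8))
  near <- abs(pop$masked$map$cM - pop$qtl$pos_cM) <= 1
  expect_gt(mean(abs(scan_q$details$effect[near]), na.rm = TRUE), mean(eff_null))
})

test_that("the prior inclusion rate does not qualitatively move the top signal", {
  pop <- strong_qtl_pop()
  tops <- sapply(c(1 / 100, 1 / 1000, 1 / 10000), function(pi) {
    sc <- bayesc_scan(pop$phen$y, pop$masked,
                      bayesc_config(pi = pi, n_iter = 5000L, seed = 9))
    sc$table$pos_cM[which.max(sc$table$score)]
  })
  expect_lt(max(tops) - min(tops), 2)
})
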