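# Thresholds, detection, scoring, effective number of tests, factorial grid.

mock_scan <- function(pos, score, method = "emma", p = 10^(-score)) {
  qtlscan:::new_qtl_scan(method = method, pos = pos, stat = score, p = p,
                         score = score, flag = rep("ok", length(pos)))
}

test_that("the Bonferroni threshold divides the level by the number of positions", {
  th <- bonferroni_threshold(0.05, 2854)
  expect_equal(th$provenance$p_cutoff, 0.05 / 2854)   # 1.7519e-05
  expect_equal(th$cutoff, -log10(0.05 / 2854))
  expect_equal(bonferroni_threshold(0.05, 1)$provenance$p_cutoff, 0.05)
  expect_equal(bonferroni_threshold(0.025, 100)$provenance$p_cutoff,
               bonferroni_threshold(0.05, 100)$provenance$p_cutoff / 2)
})

test_that("pseudo-null thresholds follow the type-7 quantile bookkeeping", {
  ## 20 replicates x 1000 non-QTL positions pool to 20000 samples
  set.seed(9)
  pooled <- rnorm(20 * 1000)
  th <- pseudo_null_thresholds(pooled)
  expect_equal(th$pseudo_null_5pct$provenance$n_pooled, 20000)
  expect_equal(th$pseudo_null_5pct$cutoff,
               quantile(pooled, 0.95, type = 7, names = FALSE))
  ## degenerate pool
  expect_equal(pseudo_null_thresholds(rep(3, 100))$pseudo_null_5pct$cutoff, 3)
  ## per-replicate extremes: scores 1..100 -> the threshold crossed by only
  ## 10% of replicate maxima is the 90% score quantile, mirroring the 10%
  ## quantile 10.9 on the P-value scale
  th2 <- pseudo_null_thresholds(pooled, per_replicate_maxima = 1:100)
  expect_equal(th2$max_quantile_10$cutoff,
               quantile(1:100, 0.90, type = 7, names = FALSE))  # 90.1
  expect_equal(th2$max_quantile_20$cutoff,
               quantile(1:100, 0.80, type = 7, names = FALSE))
  ## and on a P-like (negated) scale the mirrored quantile is 10.9
  expect_equal(-quantile(-(1:100), 0.90, type = 7, names = FALSE), 10.9)
  expect_error(pseudo_null_thresholds(pooled, per_replicate_maxima = 1:9),
               "at least 10")
})

test_that("top_signal declares at most one QTL with deterministic tie-breaking", {
  th <- threshold_spec("pseudo_null_5pct", 3)
  ## all scores below the cutoff: no declaration
  d0 <- top_signal(mock_scan(1:5, c(1, 2, 2.5, 1, 0.5)), th)
  expect_false(d0$declared)
  expect_true(is.na(d0$pos_cM))
  ## a single crossing is declared at its position
  d1 <- top_signal(mock_scan(1:5, c(1, 2, 3.5, 1, 0.5)), th)
  expect_true(d1$declared)
  expect_equal(d1$pos_cM, 3)
  ## two tied maxima: leftmost declared
  d2 <- top_signal(mock_scan(1:5, c(1, 4, 2, 4, 0.5)), th)
  expect_equal(d2$pos_cM, 2)
  ## an infinite score (saturated Bayes factor) is a valid extreme
  d3 <- top_signal(mock_scan(1:3, c(1, Inf, 2), method = "bayesc", p = NA), th)
  expect_true(d3$declared)
  expect_equal(d3$pos_cM, 2)
})

test_that("score_replicates counts power, FDR and MSE per the declared windows", {
  mk <- function(pos, declared) structure(list(declared = declared, pos_cM = pos,
                                               score = 5, threshold = NULL),
                                          class = "detection_result")
  truth <- 50
  ## 10 replicates: 6 in-window (+-2), 2 out, 2 undeclared
  dets <- c(lapply(c(49, 50, 51, 50.5, 48.5, 51.5), mk, declared = TRUE),
            lapply(c(70, 20), mk, declared = TRUE),
            lapply(c(NA, NA), mk, declared = FALSE))
  s <- score_replicates(dets, truth, half_width = 2)
  expect_equal(s$power, 0.6)
  expect_equal(s$fdr, 0.2)
  expect_equal(s$mse, mean(c(1, 0, 1, 0.25, 2.25, 2.25)))
  ## declarations exactly at the truth: MSE 0
  s0 <- score_replicates(lapply(rep(50, 5), mk, declared = TRUE), truth, 1)
  expect_equal(s0$mse, 0)
  expect_equal(s0$power, 1)
  ## widening the window never decreases power
  for (hw in c(0.5, 1, 2)) {
    s_hw <- score_replicates(dets, truth, hw)
    if (hw > 0.5) expect_gte(s_hw$power, s_prev$power)
    s_prev <- s_hw
  }
  ## zero declarations: power 0, FDR 0, MSE missing
  sz <- score_replicates(lapply(1:3, function(i) mk(NA, FALSE)), truth, 1)
  expect_equal(sz$power, 0)
  expect_equal(sz$fdr, 0)
  expect_true(is.na(sz$mse))
  ## two-QTL truth: declaration matched to the nearest
  s2 <- score_replicates(list(mk(81, TRUE)), c(20, 80), 2)
  expect_equal(s2$power, 1)
  expect_equal(s2$mse, 1)
})

test_that("the effective number of tests follows the autocorrelation structure", {
  set.seed(77)
  ## i.i.d. white noise: ESS close to N
  x <- rnorm(2000)
  expect_equal(effective_tests(x), 2000, tolerance = 0.1)
  ## AR(1), rho = 0.9: ESS -> N (1-rho)/(1+rho)
  rho <- 0.9
  n <- 5000
  ar <- as.numeric(arima.sim(list(ar = rho), n))
  expect_equal(effective_tests(ar), n * (1 - rho) / (1 + rho), tolerance = 0.2)
  ## bounded by N for any input, constant series collapses to 1
  for (xx in list(rnorm(50), cumsum(rnorm(200)), rep(1:2, 25)))
    expect_lte(effective_tests(xx), length(xx))
  expect_equal(effective_tests(rep(4, 100)), 1)
  expect_error(effective_tests(rnorm(5)), "at least 10")
})

test_that("the factorial grid enumerates 675 cells and averages correctly", {
  fixtures <- c("dairy", "beef", "sheep", "horse", "pig")
  cells <- expand.grid(fixture = fixtures, scenario = 1:5,
                       method = c("ldla", "emma", "bayesc"),
                       threshold = c("pseudo_null_5pct", "max_quantile_10",
                                     "max_quantile_20"),
                       half_width = c(0.5, 1, 2),
                       indicator = "power",
                       stringsAsFactors = FALSE)
  set.seed(1)
  cells$value <- runif(nrow(cells))
  grid <- aggregate_grid(cells)
  expect_equal(nrow(grid), 675)
  expect_equal(attr(grid, "missing_cells"), 0)
  ## all replicates identical -> the cell mean is the common value
  rep_cells <- cells[rep(1, 4), ]
  rep_cells$value <- 0.4
  expect_equal(aggregate_grid(rep_cells)$value, 0.4)
  ## balanced grid: marginal method mean = plain mean over that method's cells
  mm <- method_means(grid, "power")
  expect_equal(unname(mm["emma"]),
               mean(grid$value[grid$method == "emma"]))
  expect_length(mm, 3)
})
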