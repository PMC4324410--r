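# LDLA: phasing, windows, transmission tracing, founder clustering, scan.

test_that("phasing passes the simulator's truth through unchanged", {
  pop <- strong_qtl_pop()
  ph <- phase_panel(pop$panel, pop$ped)
  expect_identical(ph$hap1, pop$panel$hap1)
  expect_identical(ph$hap2, pop$panel$hap2)
})

test_that("heuristic phasing resolves transmissions and has a low switch-error rate", {
  pop <- strong_qtl_pop()
  truth <- pop$panel
  unphased <- genotype_panel(truth$dosage, truth$map, ids = truth$ids)
  ph <- phase_panel(unphased, pop$ped)
  expect_true(all(ph$hap1 + ph$hap2 == truth$dosage))

  ## individual with both parents homozygous everywhere recovers phase exactly:
  ## build such a case directly
  map <- genetic_map(6, 10)
  ped <- hand_pedigree()[1:4, ]
  class(ped) <- c("pedigree", "data.frame")
  h_s <- c(1L, 0L, 1L, 0L, 1L, 0L)   # sire homozygous haplotype
  h_d <- c(0L, 0L, 1L, 1L, 0L, 0L)   # dam homozygous haplotype
  dos <- rbind(2L * h_s, 2L * h_d, h_s + h_d, h_s + h_d)
  unph <- genotype_panel(dos, map, ids = as.character(1:4))
  phh <- phase_panel(unph, ped)
  expect_equal(unname(phh$hap1[3, ]), h_s)
  expect_equal(unname(phh$hap2[3, ]), h_d)
  expect_false(any(attr(phh, "unresolved")[3, ]))

  ## switch-error rate vs truth: fraction of consecutive heterozygous sites
  ## where the phase orientation flips (absolute orientation is arbitrary)
  switches <- vapply(seq_len(nrow(truth$dosage)), function(i) {
    hs <- which(truth$dosage[i, ] == 1L)
    if (length(hs) < 2) return(c(0, 0))
    o <- ph$hap1[i, hs] == truth$hap1[i, hs]
    c(sum(o[-1] != o[-length(o)]), length(hs) - 1)
  }, c(0, 0))
  expect_lt(sum(switches[1, ]) / sum(switches[2, ]), 0.05)
})

test_that("windows are built from consecutive polymorphic markers", {
  pop <- strong_qtl_pop()
  w <- make_windows(pop$panel)
  npoly <- sum(panel_maf(pop$panel) > 0)
  expect_equal(nrow(w), npoly - 3)
  expect_equal(w$pos_cM,
               rowMeans(matrix(pop$panel$map$cM[as.matrix(w[, c("m1", "m2", "m3", "m4")])],
                               ncol = 4)))

  ## monomorphic marker inside a stretch is skipped when choosing the four
  map <- genetic_map(6, 10)
  dos <- cbind(c(0L, 1L, 2L), c(2L, 2L, 2L), c(0L, 2L, 1L),
               c(1L, 1L, 0L), c(2L, 0L, 1L), c(0L, 1L, 1L))
  pan <- genotype_panel(dos, map, ids = c("a", "b", "c"))
  w2 <- make_windows(pan)
  expect_equal(nrow(w2), 2)                   # 5 polymorphic markers -> 2 windows
  expect_equal(unname(unlist(w2[1, c("m1", "m2", "m3", "m4")])), c(1L, 3L, 4L, 5L))

  ## exactly 4 polymorphic markers -> a single window
  pan3 <- genotype_panel(dos[, c(1, 3, 4, 5)], genetic_map(4, 10), ids = c("a", "b", "c"))
  expect_equal(nrow(make_windows(pan3)), 1)
  expect_error(make_windows(genotype_panel(dos[, 1:3], genetic_map(3, 10),
                                           ids = c("a", "b", "c"))),
               "at least 4")
})

test_that("transmission tracing groups gametes identical in state with the parental gamete", {
  ## 6-individual pedigree built by hand: founders 1, 2, 5; full sibs 3, 4
  ped <- hand_pedigree()
  map <- genetic_map(4, 4)
  ## sire 1 haplotypes: 1010 / 0000 ; dam 2: 1111 / 0110 ; founder 5: 1100/1100
  h1 <- rbind(c(1,0,1,0), c(1,1,1,1), c(1,0,1,0), c(1,0,1,0), c(1,1,0,0), c(1,0,1,0))
  h2 <- rbind(c(0,0,0,0), c(0,1,1,0), c(0,1,1,0), c(0,1,1,0), c(1,1,0,0), c(0,1,1,0))
  storage.mode(h1) <- storage.mode(h2) <- "integer"
  pan <- genotype_panel(h1 + h2, map, ids = as.character(1:6), hap1 = h1, hap2 = h2)
  win <- make_windows(pan)[1, ]
  gr <- trace_transmission(win, pan, ped)
  ## both full sibs carry the sire's 1010 gamete -> same group
  expect_equal(gr$g1[3], gr$g1[4])
  ## and the dam's 0110 gamete -> same group
  expect_equal(gr$g2[3], gr$g2[4])
  ## individual 6's sire-gamete (1010 from individual 3) joins the chain
  expect_equal(gr$g1[6], gr$g1[3])
  ## a recombinant gamete matching neither parental haplotype founds a new group
  h1b <- h1; h1b[6, ] <- c(1L, 0L, 0L, 0L)   # matches neither 1010 nor 0110
  panb <- genotype_panel(h1b + h2, map, ids = as.character(1:6), hap1 = h1b, hap2 = h2)
  grb <- trace_transmission(make_windows(panb)[1, ], panb, ped)
  expect_false(grb$g1[6] %in% c(grb$g1[3], grb$g2[3]))
  expect_equal(grb$group_code[grb$g1[6]], 8L)  # 1000
})

test_that("founder clustering merges identical states and carries similarity in H", {
  ## two identical founder haplotypes merge into one cluster
  gr <- list(g1 = c(1L, 2L), g2 = c(3L, 4L),
             group_code = c(5L, 5L, 5L, 5L))
  cl <- cluster_founders(gr)
  expect_equal(cl$n_clusters, 1)
  expect_equal(unname(cl$T[, 1]), c(2, 2))

  ## pairwise <= 2/4-identical states never merge at the 3/4 cut; H carries
  ## the pairwise similarities (brute-force reference computed inline)
  codes <- c(0L, 3L, 13L, 14L)   # 0000, 0011, 1101, 1110: pairwise Hamming >= 2
  gr2 <- list(g1 = 1:4, g2 = 5:8, group_code = rep(codes, 2))
  cl2 <- cluster_founders(gr2, similarity_threshold = 0.75)
  expect_equal(cl2$n_clusters, 4)
  ham <- function(a, b) sum(bitwAnd(bitwShiftR(bitwXor(a, b), 0:3), 1L))
  ref <- outer(codes, codes, Vectorize(function(a, b) (4 - ham(a, b)) / 4))
  diag(ref) <- 1
  ## H was PSD-floored; compare against the floored reference
  eg <- eigen(ref, symmetric = TRUE)
  ref_psd <- eg$vectors %*% (pmax(eg$values, 0) * t(eg$vectors))
  expect_equal(cl2$H, ref_psd, tolerance = 1e-10)

  ## H diagonal is 1 for every cluster (before any flooring applies)
  pop <- strong_qtl_pop()
  win <- make_windows(pop$panel)[10, ]
  gr3 <- trace_transmission(win, pop$panel, pop$ped)
  cl3 <- cluster_founders(gr3)
  expect_true(all(abs(diag(cl3$H) - 1) < 1e-8 | diag(cl3$H) <= 1))
  expect_gte(min(eigen(cl3$H, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  ## every gamete maps to exactly one cluster: rows of T sum to 2
  expect_true(all(rowSums(cl3$T) == 2))
})

test_that("the LDLA scan localizes a strong planted QTL and reacts to permutation", {
  pop <- strong_qtl_pop()
  A <- pedigree_nrm(pop$ped)
  scan <- ldla_scan(pop$phen$y, pop$masked, pop$ped, A)
  tb <- scan$table
  top <- tb$pos_cM[which.max(tb$score)]
  expect_lt(abs(top - pop$qtl$pos_cM), 2)
  ## the null fit reused at every window is the plain polygenic REML fit
  ids <- names(pop$phen$y)
  plain <- reml(pop$phen$y, random = list(u = A[ids, ids]))
  expect_equal(scan$details$null_fit$logLik, plain$logLik, tolerance = 1e-8)
  ## permuting y destroys the signal
  set.seed(77)
  yperm <- setNames(sample(pop$phen$y), names(pop$phen$y))
  scan_p <- ldla_scan(yperm, pop$masked, pop$ped, A)
  expect_gt(min(scan_p$table$p, na.rm = TRUE), min(tb$p, na.rm = TRUE) * 1e3)
  ## LRT series on planted-QTL data is positively autocorrelated (redundancy)
  s <- tb$stat[tb$flag == "ok"]
  expect_gt(cor(s[-1], s[-length(s)]), 0)
})
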