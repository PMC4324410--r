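# Generator: pedigree designs, founder LD, gene dropping, QTL assignment,
# phenotype variance bookkeeping.

test_that("pedigree designs produce the intended family structures", {
  ped <- build_pedigree(pedigree_design("large_half_sib", 1221, 30), seed = 1)
  off <- ped[ped$generation > 0, ]
  expect_equal(nrow(off), 1221)
  expect_true(all(ped$generation == 0 | (ped$sire > 0 & ped$dam > 0)))
  expect_equal(mean(table(off$sire)), 1221 / 30, tolerance = 0.01)

  ped2 <- build_pedigree(pedigree_design("many_small_families", 627, 102), seed = 2)
  off2 <- ped2[ped2$generation > 0, ]
  expect_equal(length(unique(off2$sire)), 102)       # every sire founds a family
  expect_equal(nrow(off2), 627 - 102)

  ped3 <- build_pedigree(pedigree_design("backcross_3gen", 300, 5), seed = 3)
  expect_setequal(unique(ped3$generation[ped3$generation > 0]), 1:3)
  expect_setequal(unique(attr(ped3, "founder_pop")), c("A", "B"))

  ped4 <- build_pedigree(pedigree_design("multi_subpop", 300, 60), seed = 4)
  expect_equal(length(unique(attr(ped4, "founder_pop"))), 3)

  expect_error(pedigree_design("large_half_sib", 10, 10), "n_individuals > n_sires")
})

test_that("pedigrees are valid and seed-deterministic", {
  for (kind in c("large_half_sib", "small_half_sib", "backcross_3gen",
                 "many_small_families", "multi_subpop")) {
    d <- pedigree_design(kind, 200, 20)
    p1 <- build_pedigree(d, seed = 42)
    p2 <- build_pedigree(d, seed = 42)
    expect_identical(p1, p2)
    expect_false(anyDuplicated(p1$id) > 0)
    ## parents precede offspring
    pos <- match(p1$id, p1$id)
    for (col in c("sire", "dam")) {
      known <- p1[[col]] > 0
      expect_true(all(match(p1[[col]][known], p1$id) < which(known)))
    }
  }
})

test_that("founder haplotypes hit target frequencies and LD", {
  map <- genetic_map(120, 60)
  ## independence case
  H0 <- draw_founder_haplotypes(1000, map, ld_strength = 0, seed = 5)
  r0 <- sapply(2:40, function(j) cor(H0[, j - 1], H0[, j]))
  expect_lt(max(abs(r0)), 0.12)
  expect_lt(mean(abs(r0)), 0.04)
  ## calibration: realized adjacent allelic correlation vs requested
  for (target in c(0.4, 0.8)) {
    H <- draw_founder_haplotypes(2000, map, ld_strength = target, seed = 6)
    r <- sapply(2:120, function(j) cor(H[, j - 1], H[, j]))
    expect_lt(abs(mean(r) - target), 0.05)
  }
  ## frequency profile respected
  p <- rep(0.3, 120)
  H <- draw_founder_haplotypes(2000, map, maf_profile = p, ld_strength = 0.5, seed = 7)
  expect_lt(max(abs(colMeans(H) - 0.3)), 0.05)
})

test_that("gene dropping transmits and recombines per the Haldane model", {
  ## zero distance: never a recombination between the two markers
  map0 <- genetic_map(2, 1e-9, positions = c(0, 0))
  ped <- build_pedigree(pedigree_design("large_half_sib", 3000, 2), seed = 8)
  H <- draw_founder_haplotypes(sum(ped$generation == 0), map0,
                               maf_profile = c(0.5, 0.5), ld_strength = 0, seed = 9)
  pan0 <- gene_drop(ped, H, map0, seed = 10)
  ## at zero distance every transmitted gamete is one parental haplotype
  ## intact: a recombination would decouple the two co-located loci
  off <- which(ped$generation > 0)
  sire_rows <- match(ped$sire[off], ped$id)
  ok <- (pan0$hap1[off, 1] == pan0$hap1[sire_rows, 1] & pan0$hap1[off, 2] == pan0$hap1[sire_rows, 2]) |
        (pan0$hap1[off, 1] == pan0$hap2[sire_rows, 1] & pan0$hap1[off, 2] == pan0$hap2[sire_rows, 2])
  expect_true(all(ok))

  ## homozygous parent: offspring gamete equals the parent haplotype
  map2 <- genetic_map(5, 40)
  ped_small <- build_pedigree(pedigree_design("large_half_sib", 10, 2), seed = 1)
  nf <- sum(ped_small$generation == 0)
  Hall1 <- matrix(1L, 2 * nf, 5)          # all founders homozygous 1/1
  pan <- gene_drop(ped_small, Hall1, map2, seed = 2)
  expect_true(all(pan$dosage[ped_small$generation > 0, ] == 2))

  ## Haldane recombination fraction at 10 cM: (1 - exp(-0.2))/2
  mapH <- genetic_map(2, 10, positions = c(0, 10))
  pedH <- build_pedigree(pedigree_design("many_small_families", 25001, 1), seed = 3)
  nfH <- sum(pedH$generation == 0)
  ## founders: haplotype pairs 11/00 so recombination is observable in every meiosis
  HH <- matrix(0L, 2 * nfH, 2)
  HH[seq(1, nrow(HH), 2), ] <- 1L
  panH <- gene_drop(pedH, HH, mapH, seed = 4)
  off <- which(pedH$generation > 0)
  rec_sire <- panH$hap1[off, 1] != panH$hap1[off, 2]
  rec_dam <- panH$hap2[off, 1] != panH$hap2[off, 2]
  rate <- mean(c(rec_sire, rec_dam))      # 50000 meioses
  expect_equal(rate, (1 - exp(-0.2)) / 2, tolerance = 0.05)

  ## dosage/phase consistency and determinism
  pop <- strong_qtl_pop()
  expect_true(all(pop$panel$hap1 + pop$panel$hap2 == pop$panel$dosage))
  again <- sim_panel(pop$ped, pop$map, ld_strength = 0.8, seed = 12)
  expect_identical(again$dosage, pop$panel$dosage)
})

test_that("QTL assignment respects scenario targets and is scenario-stable", {
  pop <- strong_qtl_pop()
  sc3 <- simulation_scenario(3)           # MAF 0.1, LD 0.8
  panel3 <- sim_panel(pop$ped, pop$map, ld_strength = 0.8, seed = 21)
  q3 <- assign_qtl(panel3, sc3, seed = 22)
  expect_gte(q3$realized_maf, 0.05)
  expect_lte(q3$realized_maf, 0.15)
  expect_lt(abs(q3$realized_ld - 0.8), 0.05 + 1e-12)

  sc5 <- simulation_scenario(5)           # two QTL
  q5 <- assign_qtl(pop$panel, sc5, seed = 23)
  expect_length(q5$marker_index, 2)
  expect_false(q5$marker_index[1] == q5$marker_index[2])

  ## same scenario seed -> same marker, across phenotype replicates
  qa <- assign_qtl(pop$panel, pop$scenario, seed = 13)
  expect_identical(qa$marker_index, pop$qtl$marker_index)
})

test_that("phenotype components satisfy the exact decomposition and variance targets", {
  pop <- strong_qtl_pop()
  ph <- pop$phen
  expect_equal(unname(ph$y),
               ph$mu + ph$components$qtl + ph$components$polygenic + ph$components$residual)
  expect_equal(ph$realized_qtl_share, 0.4, tolerance = 0.05)
  expect_equal(ph$realized_h2, 0.5, tolerance = 0.05)

  ## null effect: no covariance with the causal dosage in expectation
  covs <- sapply(1:20, function(r) {
    p <- simulate_phenotypes(pop$panel, pop$ped, pop$qtl, pop$scenario,
                             seed = 100 + r, effect_size = 0)
    dos <- pop$panel$dosage[match(names(p$y), pop$panel$ids), pop$qtl$marker_index]
    cov(p$y, dos)
  })
  expect_lt(abs(mean(covs)), 0.05)

  ## seeded determinism
  p1 <- simulate_phenotypes(pop$panel, pop$ped, pop$qtl, pop$scenario, seed = 77)
  p2 <- simulate_phenotypes(pop$panel, pop$ped, pop$qtl, pop$scenario, seed = 77)
  expect_identical(p1$y, p2$y)
})

test_that("masking removes exactly the causal columns and is not repeatable", {
  pop <- strong_qtl_pop()
  expect_equal(ncol(pop$masked$dosage), ncol(pop$panel$dosage) - 1)
  expect_false(pop$qtl$marker_id %in% pop$masked$map$id)
  ## map positions of the remaining markers unchanged
  expect_equal(pop$masked$map$cM,
               pop$panel$map$cM[-pop$qtl$marker_index])
  expect_error(mask_qtl(pop$masked, pop$qtl), "absent")

  sc5 <- simulation_scenario(5)
  q5 <- assign_qtl(pop$panel, sc5, seed = 23)
  m5 <- mask_qtl(pop$panel, q5)
  expect_equal(ncol(m5$dosage), ncol(pop$panel$dosage) - 2)
})
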