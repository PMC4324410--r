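# Small populations rebuilt in code for the unit tests; nothing is stored on
# disk.  The cache avoids re-simulating the same population across tests in
# one file.

.fix_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fix_cache)) assign(key, force(expr), envir = .fix_cache)
  get(key, envir = .fix_cache)
}

## a small half-sib population with a planted strong QTL (fast, clear signal)
strong_qtl_pop <- function() cached("strong_qtl_pop", {
  ped <- build_pedigree(pedigree_design("large_half_sib", 400, 10), seed = 11)
  map <- genetic_map(160, 80)
  panel <- sim_panel(ped, map, ld_strength = 0.8, seed = 12)
  sc <- simulation_scenario(NULL, n_qtl = 1, effect_type = "additive",
                            maf_target = 0.3, ld_target = 0.8,
                            qtl_genetic_variance_fraction = 0.4,
                            broad_sense_h2 = 0.5)
  qtl <- assign_qtl(panel, sc, seed = 13)
  phen <- simulate_phenotypes(panel, ped, qtl, sc, seed = 14)
  list(ped = ped, map = map, panel = panel, scenario = sc, qtl = qtl,
       phen = phen, masked = mask_qtl(panel, qtl))
})

## hand-built 6-individual pedigree: two founder couples, two full sibs, and
## an offspring of the full sibs (inbred)
hand_pedigree <- function() {
  ped <- data.frame(id = 1:6,
                    sire = c(0L, 0L, 1L, 1L, 0L, 3L),
                    dam = c(0L, 0L, 2L, 2L, 0L, 4L),
                    generation = c(0L, 0L, 1L, 1L, 0L, 2L),
                    sex = c("M", "F", "M", "F", "F", "M"))
  class(ped) <- c("pedigree", "data.frame")
  attr(ped, "founder_pop") <- rep("P", 3)
  ped
}
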