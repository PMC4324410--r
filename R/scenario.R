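#' Simulation scenarios for planted QTL
#'
#' A scenario fixes the number of QTL, the gene action, the target minor
#' allele frequency of the causal SNP, and the target linkage disequilibrium
#' (correlation between the causal SNP and the neighbouring marker in
#' strongest LD with it).  In every scenario the QTL explains 5% of the
#' total genetic variance and the broad-sense heritability is 0.30.
#'
#' The five stock scenarios (`simulation_scenario(1)` .. `(5)`) are:
#' \tabular{lllll}{
#'   scenario \tab n QTL \tab effect \tab MAF \tab LD \cr
#'   1 \tab 1 \tab additive \tab 0.3 \tab 0.8 \cr
#'   2 \tab 1 \tab additive \tab 0.3 \tab 0.4 \cr
#'   3 \tab 1 \tab additive \tab 0.1 \tab 0.8 \cr
#'   4 \tab 1 \tab dominant \tab 0.3 \tab 0.8 \cr
#'   5 \tab 2 \tab additive \tab 0.3 \tab 0.8 \cr
#' }
#'
#' @param id stock scenario number 1..5, or `NULL` to build a custom one.
#' @param n_qtl 1 or 2 causal SNPs.
#' @param effect_type `"additive"` (genotypic values -a, 0, a) or
#'   `"dominant"` (-a, d, a with complete dominance d = a).
#' @param maf_target target minor allele frequency of the causal SNP(s).
#' @param ld_target target dosage correlation with the strongest neighbour.
#' @param qtl_genetic_variance_fraction share of total genetic variance due
#'   to the QTL (jointly, for two QTL).
#' @param broad_sense_h2 broad-sense heritability, (QTL + polygenic
#'   variance) / phenotypic variance.
#' @param n_replicates default replicate count for studies built on this
#'   scenario.
#' @return a list of class `"simulation_scenario"`.
#' @export
simulation_scenario <- function(id = NULL, n_qtl = 1L,
                                effect_type = c("additive", "dominant"),
                                maf_target = 0.3, ld_target = 0.8,
                                qtl_genetic_variance_fraction = 0.05,
                                broad_sense_h2 = 0.30,
                                n_replicates = 100L) {
  if (!is.null(id)) {
    stopifnot(id %in% 1:5)
    preset <- list(
      list(n_qtl = 1L, effect_type = "additive", maf_target = 0.3, ld_target = 0.8),
      list(n_qtl = 1L, effect_type = "additive", maf_target = 0.3, ld_target = 0.4),
      list(n_qtl = 1L, effect_type = "additive", maf_target = 0.1, ld_target = 0.8),
      list(n_qtl = 1L, effect_type = "dominant", maf_target = 0.3, ld_target = 0.8),
      list(n_qtl = 2L, effect_type = "additive", maf_target = 0.3, ld_target = 0.8))[[id]]
    n_qtl <- preset$n_qtl; effect_type <- preset$effect_type
    maf_target <- preset$maf_target; ld_target <- preset$ld_target
  } else {
    effect_type <- match.arg(effect_type)
  }
  stopifnot(n_qtl %in% 1:2,
            maf_target > 0, maf_target <= 0.5,
            ld_target > 0, ld_target <= 1,
            qtl_genetic_variance_fraction > 0, qtl_genetic_variance_fraction < 1,
            broad_sense_h2 > 0, broad_sense_h2 < 1)
  structure(list(id = id, n_qtl = as.integer(n_qtl), effect_type = effect_type,
                 maf_target = maf_target, ld_target = ld_target,
                 qtl_genetic_variance_fraction = qtl_genetic_variance_fraction,
                 broad_sense_h2 = broad_sense_h2,
                 n_replicates = as.integer(n_replicates)),
            class = "simulation_scenario")
}

#' Simulate a genotype panel down a pedigree
#'
#' Convenience wrapper: draws founder haplotypes (per founder subpopulation,
#' with diverged frequency profiles when the pedigree has several founder
#' lines) and gene-drops them through the pedigree.
#'
#' @param pedigree a [build_pedigree()] result.
#' @param map a [genetic_map()].
#' @param ld_strength adjacent-marker allelic correlation at mean spacing
#'   (see [draw_founder_haplotypes()]).
#' @param maf_profile optional per-marker target frequencies.
#' @param maf_anchors frequencies that stretches of the chromosome are
#'   anchored at (so causal-marker candidates exist at these MAFs); ignored
#'   when `maf_profile` is given.
#' @param divergence drift intensity between founder subpopulations.
#' @param seed integer seed.
#' @return a phased [genotype_panel()] over all pedigree individuals.
#' @export
sim_panel <- function(pedigree, map, ld_strength = 0.8, maf_profile = NULL,
                      maf_anchors = c(0.1, 0.3), divergence = 0.1, seed = NULL) {
  with_seed(seed, {
    fpop <- attr(pedigree, "founder_pop") %||% rep("P", sum(pedigree$generation == 0L))
    pops <- unique(fpop)
    base_p <- maf_profile %||% block_freq_profile(nrow(map), anchors = maf_anchors)
    pools <- lapply(seq_along(pops), function(k) {
      p <- if (k == 1L) base_p else diverge_freq_profile(base_p, divergence)
      draw_founder_haplotypes(sum(fpop == pops[k]), map, maf_profile = p,
                              ld_strength = ld_strength)
    })
    names(pools) <- pops
    gene_drop(pedigree, pools, map)
  })
}

## strongest neighbouring-marker dosage correlation for given marker columns
neighbour_ld <- function(dosage, j, flank = 10L) {
  m <- ncol(dosage)
  nb <- setdiff(max(1L, j - flank):min(m, j + flank), j)
  x <- dosage[, j]
  if (stats::var(x) == 0) return(NA_real_)
  rr <- suppressWarnings(abs(stats::cor(x, dosage[, nb, drop = FALSE])))
  max(rr, na.rm = TRUE)
}

#' Pick causal SNPs for a scenario
#'
#' Chooses `n_qtl` distinct markers uniformly at random among the candidates
#' whose realized minor allele frequency and strongest-neighbour dosage
#' correlation are both within `tolerance` of the scenario targets.  Fixing
#' the seed at the scenario level keeps the causal marker(s) identical
#' across the replicates of one scenario.
#'
#' @param panel a [genotype_panel()].
#' @param scenario a [simulation_scenario()].
#' @param seed integer seed (use one seed per scenario).
#' @param tolerance allowed deviation from `maf_target` and `ld_target`.
#' @param flank how many markers on each side count as neighbours for the
#'   LD criterion.
#' @return a list of class `"qtl_assignment"`: marker indices and ids, true
#'   cM positions, effect type, realized MAF and realized neighbour LD.
#' @export
assign_qtl <- function(panel, scenario, seed = NULL, tolerance = 0.05, flank = 10L) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  maf <- panel_maf(panel)
  with_seed(seed, {
    ok_maf <- which(abs(maf - scenario$maf_target) <= tolerance & maf > 0)
    ld <- vapply(ok_maf, function(j) neighbour_ld(panel$dosage, j, flank), 0)
    cand <- ok_maf[!is.na(ld) & abs(ld - scenario$ld_target) <= tolerance]
    if (length(cand) < scenario$n_qtl)
      stop_config(paste0("only %d candidate marker(s) match MAF %.2f and LD %.2f ",
                         "(tolerance %.2f); regenerate the panel with recalibrated founders"),
                  length(cand), scenario$maf_target, scenario$ld_target, tolerance)
    idx <- if (length(cand) == scenario$n_qtl) cand else
      sort(cand[sample.int(length(cand), scenario$n_qtl)])
    structure(list(marker_index = idx,
                   marker_id = panel$map$id[idx],
                   pos_cM = panel$map$cM[idx],
                   effect_type = scenario$effect_type,
                   realized_maf = maf[idx],
                   realized_ld = vapply(idx, function(j) neighbour_ld(panel$dosage, j, flank), 0),
                   scenario = scenario),
              class = "qtl_assignment")
  })
}

#' Simulate phenotypes with a planted QTL, a polygenic term and noise
#'
#' Phenotypes decompose exactly as `y = mu + qtl + polygenic + residual`.
#' QTL genotypic values use the coding (-a, 0, a) by dosage for additive
#' action and (-a, a, a) for complete dominance.  The effect size `a` is
#' solved against the realized genotype frequencies so that the empirical
#' QTL variance equals `qtl_genetic_variance_fraction` of the total genetic
#' variance; the residual scale is solved so that the empirical broad-sense
#' heritability Var(qtl + polygenic)/Var(y) matches `broad_sense_h2`.  The
#' polygenic term is simulated by gene flow down the pedigree (founders
#' N(0, 1), Mendelian sampling variance 1/2 for non-inbred parents), which
#' realizes covariance equal to the pedigree relationship matrix.
#'
#' @param panel phased or unphased [genotype_panel()] containing the causal
#'   marker(s) (masking happens afterwards, see [mask_qtl()]).
#' @param pedigree the pedigree the panel was dropped on.
#' @param qtl a [assign_qtl()] result.
#' @param scenario the [simulation_scenario()].
#' @param seed integer seed (vary per replicate).
#' @param phenotyped ids of phenotyped individuals; defaults to all
#'   non-founders.
#' @param effect_size optional forced allele effect `a` (e.g. 0 for a global
#'   null with the same polygenic/residual structure); `NULL` solves `a`
#'   from the scenario's variance targets.
#' @return a list of class `"phenotype_set"`: `y` (named numeric),
#'   `components` (data.frame id/qtl/polygenic/residual), `effect_size`,
#'   and realized variance shares.
#' @export
simulate_phenotypes <- function(panel, pedigree, qtl, scenario, seed = NULL,
                                phenotyped = NULL, effect_size = NULL) {
  stopifnot(inherits(qtl, "qtl_assignment"))
  if (!all(qtl$marker_index <= ncol(panel$dosage)) ||
      !all(panel$map$id[qtl$marker_index] == qtl$marker_id))
    stop_config("causal marker(s) not present in the panel (already masked?)")
  phenotyped <- phenotyped %||% as.character(nonfounders(pedigree))
  rows <- match(phenotyped, panel$ids)
  if (anyNA(rows)) stop_config("phenotyped ids missing from the panel")
  with_seed(seed, {
    ## unit-effect genotypic coding per causal marker
    g0 <- rep(0, length(rows))
    for (j in qtl$marker_index) {
      dos <- panel$dosage[rows, j]
      if (stats::var(dos) == 0) stop_config("causal marker is monomorphic among phenotyped individuals")
      code <- if (scenario$effect_type == "dominant") c(-1, 1, 1) else c(-1, 0, 1)
      g0 <- g0 + code[dos + 1L]
    }
    ## polygenic values by gene flow (sigma_u^2 = 1); designs are non-inbred
    u_all <- gene_flow_polygenic(pedigree)
    u <- u_all[match(phenotyped, as.character(pedigree$id))]
    v_u <- stats::var(u)
    frac <- scenario$qtl_genetic_variance_fraction
    a <- effect_size %||% (sqrt(v_u * frac / (1 - frac)) / stats::sd(g0))
    g <- a * g0
    vg_tot <- stats::var(g + u)
    h2 <- scenario$broad_sense_h2
    e <- stats::rnorm(length(rows))
    e <- e / stats::sd(e) * sqrt(vg_tot * (1 - h2) / h2)
    mu <- 0
    y <- mu + g + u + e
    names(y) <- phenotyped
    structure(list(
      y = y, mu = mu,
      components = data.frame(id = phenotyped, qtl = g, polygenic = u, residual = e,
                              stringsAsFactors = FALSE),
      effect_size = a,
      realized_h2 = vg_tot / stats::var(y),
      realized_qtl_share = stats::var(g) / vg_tot,
      scenario = scenario),
      class = "phenotype_set")
  })
}

## additive polygenic values down the pedigree: u_i = (u_s + u_d)/2 + m_i,
## m_i ~ N(0, 1/2) when both parents known (designs here are non-inbred),
## N(0, 3/4) with one unknown parent, founders N(0, 1).
gene_flow_polygenic <- function(pedigree) {
  n <- nrow(pedigree)
  u <- numeric(n)
  row_of <- match(seq_len(max(pedigree$id)), pedigree$id)
  z <- stats::rnorm(n)
  for (i in seq_len(n)) {
    s <- pedigree$sire[i]; d <- pedigree$dam[i]
    if (s == 0L && d == 0L) {
      u[i] <- z[i]
    } else if (s > 0L && d > 0L) {
      u[i] <- 0.5 * (u[row_of[s]] + u[row_of[d]]) + z[i] * sqrt(0.5)
    } else {
      p <- if (s > 0L) s else d
      u[i] <- 0.5 * u[row_of[p]] + z[i] * sqrt(0.75)
    }
  }
  stats::setNames(u, as.character(pedigree$id))
}

#' Mask the causal marker(s) out of a panel
#'
#' Removes the QTL column(s) from the panel, emulating an unobserved causal
#' variant; the map positions of the remaining markers are unchanged and the
#' true causal positions stay recorded in the assignment for scoring.
#'
#' @param panel a [genotype_panel()].
#' @param qtl a [assign_qtl()] result.
#' @return the panel without the causal column(s).
#' @export
mask_qtl <- function(panel, qtl) {
  idx <- match(qtl$marker_id, panel$map$id)
  if (anyNA(idx))
    stop_config("marker(s) %s absent from the panel (already masked?)",
                paste(qtl$marker_id[is.na(idx)], collapse = ", "))
  subset_panel(panel, markers = setdiff(seq_len(ncol(panel$dosage)), idx))
}
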