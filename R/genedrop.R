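#' Drop founder haplotypes through a pedigree
#'
#' Standard gene dropping: each founder receives two haplotypes from the
#' founder pool; each non-founder inherits one recombined gamete per parent.
#' Recombination between adjacent markers occurs independently with the
#' Haldane probability `r = (1 - exp(-2 d / 100)) / 2` for an interval of
#' `d` cM (Poisson crossovers, no interference), so the recombination
#' fraction between any two loci follows the Haldane map function of their
#' cM distance.  Phase is retained: `hap1` is the sire-transmitted and
#' `hap2` the dam-transmitted gamete.
#'
#' If an individual has one known and one unknown parent, the missing gamete
#' is drawn as a recombined pair of haplotypes sampled from the founder pool
#' (a message notes how often this happened).
#'
#' @param pedigree a [build_pedigree()] result (topologically ordered).
#' @param founders founder haplotype matrix from [draw_founder_haplotypes()]
#'   (or a list of such matrices named by founder subpopulation, see
#'   `attr(pedigree, "founder_pop")`).
#' @param map the [genetic_map()] the haplotypes were drawn on.
#' @param seed integer seed.
#' @return a [genotype_panel()] covering every pedigree individual, with
#'   phase.
#' @export
gene_drop <- function(pedigree, founders, map, seed = NULL) {
  stopifnot(inherits(pedigree, "pedigree"))
  with_seed(seed, {
    m <- nrow(map)
    n <- nrow(pedigree)
    founder_rows <- which(pedigree$generation == 0L)
    fpop <- attr(pedigree, "founder_pop") %||% rep("P", length(founder_rows))
    pools <- if (is.list(founders)) founders else
      stats::setNames(list(founders), unique(fpop)[1])
    if (!all(fpop %in% names(pools)))
      stop_config("founder pool missing for subpopulation(s): %s",
                  paste(setdiff(fpop, names(pools)), collapse = ", "))
    if (any(vapply(pools, ncol, 1L) != m))
      stop_config("founder haplotypes and map disagree on marker count")
    needed <- table(fpop)
    for (nm in names(needed))
      if (nrow(pools[[nm]]) < 2 * needed[[nm]])
        stop_config("founder pool '%s' has %d haplotypes but %d founders need %d",
                    nm, nrow(pools[[nm]]), needed[[nm]], 2 * needed[[nm]])

    hap1 <- matrix(0L, n, m)  # sire-side gamete
    hap2 <- matrix(0L, n, m)  # dam-side gamete
    row_of <- match(seq_len(max(pedigree$id)), pedigree$id)
    r <- if (m > 1) 0.5 * (1 - exp(-2 * diff(map$cM) / 100)) else numeric(0)

    ## assign founder haplotypes (consumed in order within each pool)
    used <- stats::setNames(rep(0L, length(pools)), names(pools))
    for (k in seq_along(founder_rows)) {
      i <- founder_rows[k]
      pool <- fpop[k]
      hap1[i, ] <- pools[[pool]][used[[pool]] + 1L, ]
      hap2[i, ] <- pools[[pool]][used[[pool]] + 2L, ]
      used[[pool]] <- used[[pool]] + 2L
    }

    meiosis <- function(h_a, h_b) {
      ## gamete from a parent with haplotypes h_a, h_b
      if (m == 1L) {
        if (stats::runif(1) < 0.5) h_a else h_b
      } else {
        start <- stats::runif(1) < 0.5
        switches <- stats::runif(m - 1L) < r
        strand <- cumsum(c(start, switches)) %% 2L   # 0 -> h_a, 1 -> h_b
        ifelse(strand == 0L, h_a, h_b)
      }
    }
    random_founder_gamete <- function(pool) {
      P <- pools[[pool]]
      meiosis(P[sample.int(nrow(P), 1L), ], P[sample.int(nrow(P), 1L), ])
    }

    n_unknown <- 0L
    nonf <- which(pedigree$generation > 0L)
    for (i in nonf) {
      s <- pedigree$sire[i]; d <- pedigree$dam[i]
      if (s > 0L) {
        sr <- row_of[s]
        hap1[i, ] <- meiosis(hap1[sr, ], hap2[sr, ])
      } else {
        n_unknown <- n_unknown + 1L
        hap1[i, ] <- random_founder_gamete(fpop[1])
      }
      if (d > 0L) {
        dr <- row_of[d]
        hap2[i, ] <- meiosis(hap1[dr, ], hap2[dr, ])
      } else {
        n_unknown <- n_unknown + 1L
        hap2[i, ] <- random_founder_gamete(fpop[1])
      }
    }
    if (n_unknown > 0L)
      message(sprintf("gene_drop: %d gametes drawn from the founder pool for unknown parents",
                      n_unknown))
    genotype_panel(hap1 + hap2, map, ids = as.character(pedigree$id),
                   hap1 = hap1, hap2 = hap2)
  })
}
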