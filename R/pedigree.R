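#' Describe a pedigree design
#'
#' The five design kinds emulate the family structures found in livestock
#' QTL-mapping panels: a few very large paternal half-sib families
#' (dairy-cattle style), many moderate half-sib families (beef style), a
#' three-generation F1 / backcross / backcross-x-backcross cross between two
#' divergent founder lines (sheep style), very many small sire families
#' (horse style), and several diverged subpopulations ("breeds", pig style).
#'
#' @param kind design kind, one of `"large_half_sib"`, `"small_half_sib"`,
#'   `"backcross_3gen"`, `"many_small_families"`, `"multi_subpop"`.
#' @param n_individuals number of individuals in the genotyped panel.  For
#'   `many_small_families` this counts sires plus their offspring (sires are
#'   genotyped founders); for the other kinds it counts non-founders.
#' @param n_sires number of sires used per generation of matings.
#' @param generations total number of generation labels including founders
#'   (generation 0).  `backcross_3gen` always has 4 (founders, F1, BC,
#'   BC x BC).
#' @param subpop_props proportions of individuals per subpopulation
#'   (`multi_subpop` only).
#' @return a list of class `"pedigree_design"`.
#' @export
pedigree_design <- function(kind = c("large_half_sib", "small_half_sib",
                                     "backcross_3gen", "many_small_families",
                                     "multi_subpop"),
                            n_individuals, n_sires,
                            generations = NULL,
                            subpop_props = c(0.65, 0.17, 0.18)) {
  kind <- match.arg(kind)
  n_individuals <- as.integer(n_individuals)
  n_sires <- as.integer(n_sires)
  if (n_sires < 1L || n_individuals <= n_sires)
    stop_config("need n_individuals > n_sires >= 1 (got %d, %d)", n_individuals, n_sires)
  if (kind == "backcross_3gen") {
    generations <- 4L                      # founders + F1 + BC + BCxBC
  } else if (is.null(generations)) {
    generations <- 2L
  }
  generations <- as.integer(generations)
  if (generations < 2L) stop_config("generations must be >= 2 (founders + offspring)")
  structure(list(kind = kind, n_individuals = n_individuals, n_sires = n_sires,
                 generations = generations,
                 subpop_props = subpop_props / sum(subpop_props)),
            class = "pedigree_design")
}

## split n into k near-equal parts, every part >= 1 when n >= k
split_counts <- function(n, k) {
  base <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
  base
}

#' Build a pedigree from a design
#'
#' Generates a topologically ordered pedigree (parents always precede
#' offspring).  Founders have unknown parents (coded 0) and generation 0.
#' Dams are always fresh founders, so none of the designs produce inbreeding;
#' relatedness enters through shared sires (and, for the backcross, shared
#' line ancestry).
#'
#' @param design a [pedigree_design()].
#' @param seed integer seed; identical seeds give identical pedigrees.
#' @return a `data.frame` of class `"pedigree"` with columns `id`, `sire`,
#'   `dam` (0 = unknown), `generation` (0 = founder) and `sex` (`"M"`/`"F"`).
#'   Attribute `founder_pop` labels each founder's subpopulation/line
#'   (`"A"`/`"B"` for the backcross, `"P1"..` for multi_subpop, `"P"`
#'   otherwise).
#' @examples
#' d <- pedigree_design("large_half_sib", n_individuals = 120, n_sires = 4)
#' ped <- build_pedigree(d, seed = 1)
#' table(ped$generation)
#' @export
build_pedigree <- function(design, seed = NULL) {
  stopifnot(inherits(design, "pedigree_design"))
  with_seed(seed, {
    ped <- switch(design$kind,
      large_half_sib      = build_half_sib(design),
      small_half_sib      = build_half_sib(design),
      many_small_families = build_small_families(design),
      backcross_3gen      = build_backcross(design),
      multi_subpop        = build_multi_subpop(design))
    validate_pedigree(ped)
    ped
  })
}

new_pedigree <- function(id, sire, dam, generation, sex, founder_pop) {
  out <- data.frame(id = as.integer(id), sire = as.integer(sire),
                    dam = as.integer(dam), generation = as.integer(generation),
                    sex = sex, stringsAsFactors = FALSE)
  attr(out, "founder_pop") <- founder_pop
  class(out) <- c("pedigree", "data.frame")
  out
}

## half-sib designs: founder sires mate founder dams; later cohorts (if
## generations > 2) are sired by males sampled from the previous cohort,
## which gives the overlapping "complex pedigree" structure.
build_half_sib <- function(design) {
  cohorts <- design$generations - 1L
  sizes <- split_counts(design$n_individuals, cohorts)
  n_sires <- design$n_sires
  id <- sire <- dam <- gen <- sex <- integer(0)
  sires_now <- seq_len(n_sires)                  # founder sires: ids 1..n_sires
  next_id <- n_sires + 1L
  founder_sex <- rep("M", n_sires)
  for (g in seq_len(cohorts)) {
    n_off <- sizes[g]
    s <- sires_now[sample.int(length(sires_now), n_off, replace = TRUE)]
    dams <- seq.int(next_id, length.out = n_off)  # fresh founder dams
    next_id <- next_id + n_off
    kids <- seq.int(next_id, length.out = n_off)
    next_id <- next_id + n_off
    ksex <- sample(c("M", "F"), n_off, replace = TRUE)
    id <- c(id, dams, kids); sire <- c(sire, rep(0L, n_off), s)
    dam <- c(dam, rep(0L, n_off), dams)
    gen <- c(gen, rep(0L, n_off), rep(g, n_off))
    sex <- c(sex, rep("F", n_off), ksex)
    males <- kids[ksex == "M"]
    if (g < cohorts) {
      sires_now <- if (length(males) >= n_sires)
        sort(males[sample.int(length(males), n_sires)]) else c(males, seq_len(n_sires))
    }
  }
  ped <- new_pedigree(c(seq_len(n_sires), id), c(rep(0L, n_sires), sire),
                      c(rep(0L, n_sires), dam), c(rep(0L, n_sires), gen),
                      c(founder_sex, sex), founder_pop = NULL)
  ped <- ped[order(ped$generation, ped$id), ]
  rownames(ped) <- NULL
  attr(ped, "founder_pop") <- rep("P", sum(ped$generation == 0L))
  ped
}

## many small families: n_individuals counts the (genotyped) founder sires
## plus offspring; every sire gets at least one offspring so the number of
## sire families equals n_sires exactly.
build_small_families <- function(design) {
  n_sires <- design$n_sires
  n_off <- design$n_individuals - n_sires
  fam <- split_counts(n_off, n_sires)
  s <- rep(seq_len(n_sires), fam)
  dams <- seq.int(n_sires + 1L, length.out = n_off)
  kids <- seq.int(n_sires + n_off + 1L, length.out = n_off)
  ped <- new_pedigree(
    c(seq_len(n_sires), dams, kids),
    c(rep(0L, n_sires + n_off), s),
    c(rep(0L, n_sires + n_off), dams),
    c(rep(0L, n_sires + n_off), rep(1L, n_off)),
    c(rep("M", n_sires), rep("F", n_off), sample(c("M", "F"), n_off, replace = TRUE)),
    founder_pop = NULL)
  attr(ped, "founder_pop") <- rep("P", n_sires + n_off)
  ped
}

## F1, backcross, backcross x backcross between divergent lines A and B.
## Line-A founder sires mate line-B founder dams to give F1; F1 males are
## backcrossed to fresh B dams, and BC males again to fresh B dams.
build_backcross <- function(design) {
  sizes <- round(design$n_individuals * c(0.10, 0.45, 0.45))
  sizes[3] <- design$n_individuals - sizes[1] - sizes[2]
  if (any(sizes < 1)) stop_config("backcross design needs n_individuals >= 20")
  nA <- design$n_sires
  id <- sire <- dam <- gen <- integer(0); sex <- character(0); fpop <- character(0)
  next_id <- nA + 1L
  id <- seq_len(nA); sire <- dam <- gen <- rep(0L, nA); sex <- rep("M", nA)
  fpop <- rep("A", nA)
  sires_now <- seq_len(nA)
  for (g in 1:3) {
    n_off <- sizes[g]
    s <- sires_now[sample.int(length(sires_now), n_off, replace = TRUE)]
    dams <- seq.int(next_id, length.out = n_off); next_id <- next_id + n_off
    kids <- seq.int(next_id, length.out = n_off); next_id <- next_id + n_off
    ksex <- sample(c("M", "F"), n_off, replace = TRUE)
    id <- c(id, dams, kids); sire <- c(sire, rep(0L, n_off), s)
    dam <- c(dam, rep(0L, n_off), dams); gen <- c(gen, rep(0L, n_off), rep(g, n_off))
    sex <- c(sex, rep("F", n_off), ksex); fpop <- c(fpop, rep("B", n_off))
    males <- kids[ksex == "M"]
    if (g < 3 && length(males) == 0) stop_config("no males in generation %d; enlarge design", g)
    sires_now <- males
  }
  ped <- new_pedigree(id, sire, dam, gen, sex, founder_pop = NULL)
  ord <- order(ped$generation, ped$id)
  fp <- fpop[ped$generation[ord] == 0L]  # founder_pop follows founder order
  ped <- ped[ord, ]; rownames(ped) <- NULL
  attr(ped, "founder_pop") <- fpop[order(ped$id[ped$generation == 0L])][seq_len(sum(ped$generation == 0L))]
  ## founder_pop must align with founder rows in pedigree order:
  founders <- ped$id[ped$generation == 0L]
  attr(ped, "founder_pop") <- ifelse(founders <= nA, "A", "B")
  ped
}

## several diverged subpopulations, each with its own small sire families
build_multi_subpop <- function(design) {
  props <- design$subpop_props
  k <- length(props)
  n_per <- split_counts(design$n_individuals, k)
  n_per <- round(design$n_individuals * props)
  n_per[k] <- design$n_individuals - sum(n_per[-k])
  s_per <- pmax(1L, round(design$n_sires * props))
  parts <- vector("list", k)
  offset <- 0L
  fpop <- character(0)
  for (j in seq_len(k)) {
    sub <- pedigree_design("small_half_sib", n_individuals = n_per[j],
                           n_sires = s_per[j], generations = 2L)
    p <- build_half_sib(sub)
    p$id <- p$id + offset
    p$sire[p$sire > 0] <- p$sire[p$sire > 0] + offset
    p$dam[p$dam > 0] <- p$dam[p$dam > 0] + offset
    offset <- max(p$id)
    fpop <- c(fpop, rep(paste0("P", j), sum(p$generation == 0L)))
    p$subpop <- paste0("P", j)
    parts[[j]] <- p
  }
  ped <- do.call(rbind, parts)
  ped <- ped[order(ped$generation, ped$id), ]
  rownames(ped) <- NULL
  class(ped) <- c("pedigree", "data.frame")
  attr(ped, "founder_pop") <- fpop[order(ped$id[ped$generation == 0L])]
  ## fpop built in id order already matches sorted founder ids within blocks
  founders <- ped[ped$generation == 0L, ]
  attr(ped, "founder_pop") <- ped$subpop[ped$generation == 0L]
  ped
}

validate_pedigree <- function(ped) {
  if (anyDuplicated(ped$id)) stop_config("pedigree ids are not unique")
  pos <- match(ped$id, ped$id)
  idx <- seq_len(nrow(ped))
  for (col in c("sire", "dam")) {
    par <- ped[[col]]
    known <- par != 0L
    where <- match(par[known], ped$id)
    if (anyNA(where)) stop_config("%s refers to an id absent from the pedigree", col)
    if (any(where >= idx[known])) stop_config("parents must precede offspring in record order")
  }
  invisible(ped)
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("pedigree: %d individuals (%d founders, %d generations)\n",
              nrow(x), sum(x$generation == 0L), max(x$generation)))
  invisible(x)
}

#' Non-founder individuals of a pedigree
#' @param ped a [build_pedigree()] result.
#' @return integer ids of all non-founders, in pedigree order.
#' @export
nonfounders <- function(ped) ped$id[ped$generation > 0L]
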