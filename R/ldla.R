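#' Phase a genotype panel
#'
#' When the panel already carries phased haplotypes (e.g. the simulator's
#' true phase), they are passed through unchanged.  Otherwise heterozygous
#' sites are resolved first by Mendelian transmission rules from the parents'
#' genotypes, then by a greedy most-frequent-flanking-haplotype rule; sites
#' that stay ambiguous (or are Mendelian-inconsistent) are marked unresolved
#' for that individual.
#'
#' @param panel a [genotype_panel()].
#' @param pedigree the pedigree (used for the Mendelian rules).
#' @return a phased `genotype_panel` with attribute `"unresolved"` (logical
#'   individuals-by-markers matrix; `NULL` when the true phase was passed
#'   through).
#' @export
phase_panel <- function(panel, pedigree) {
  if (!is.null(panel$hap1)) return(panel)
  M <- panel$dosage
  n <- nrow(M); m <- ncol(M)
  h1 <- h2 <- matrix(NA_integer_, n, m)
  homo <- M != 1L
  h1[homo] <- (M[homo] == 2L) * 1L
  h2[homo] <- h1[homo]
  row_of <- match(seq_len(max(pedigree$id)), pedigree$id)
  prow <- match(panel$ids, as.character(pedigree$id))
  unresolved <- matrix(FALSE, n, m)
  ## Mendelian resolution at heterozygous sites
  for (i in seq_len(n)) {
    pr <- prow[i]
    if (is.na(pr)) next
    s <- pedigree$sire[pr]; d <- pedigree$dam[pr]
    si <- if (s > 0L) match(as.character(s), panel$ids) else NA_integer_
    di <- if (d > 0L) match(as.character(d), panel$ids) else NA_integer_
    het <- which(M[i, ] == 1L)
    for (j in het) {
      sa <- if (!is.na(si) && M[si, j] != 1L) (M[si, j] == 2L) * 1L else NA_integer_
      da <- if (!is.na(di) && M[di, j] != 1L) (M[di, j] == 2L) * 1L else NA_integer_
      if (!is.na(sa) && !is.na(da) && sa + da != 1L) {  # Mendelian inconsistency
        unresolved[i, j] <- TRUE
        next
      }
      if (!is.na(sa)) { h1[i, j] <- sa; h2[i, j] <- 1L - sa }
      else if (!is.na(da)) { h2[i, j] <- da; h1[i, j] <- 1L - da }
    }
  }
  ## family rule for founders (no genotyped parents): the gamete transmitted
  ## to the first genotyped offspring can be recovered from the offspring's
  ## genotype and the mate's genotype; by convention hap1 of such a founder
  ## is the transmitted gamete (a recombination in that meiosis introduces
  ## at most a rare spurious switch)
  child_of <- rep(NA_integer_, n)   # first offspring row per panel row
  mate_of <- rep(NA_integer_, n)
  for (k in seq_len(nrow(pedigree))) {
    s <- pedigree$sire[k]; d <- pedigree$dam[k]
    kid <- match(as.character(pedigree$id[k]), panel$ids)
    if (is.na(kid)) next
    for (pp in c(s, d)) {
      if (pp == 0L) next
      pi_ <- match(as.character(pp), panel$ids)
      if (!is.na(pi_) && is.na(child_of[pi_])) {
        child_of[pi_] <- kid
        other <- if (pp == s) d else s
        mate_of[pi_] <- if (other > 0L) match(as.character(other), panel$ids) else NA_integer_
      }
    }
  }
  for (i in which(!is.na(child_of))) {
    pr <- prow[i]
    if (is.na(pr) || pedigree$generation[pr] != 0L) next
    o <- child_of[i]; mt <- mate_of[i]
    het <- which(M[i, ] == 1L & is.na(h1[i, ]))
    for (j in het) {
      a <- NA_integer_
      if (M[o, j] == 0L) a <- 0L
      else if (M[o, j] == 2L) a <- 1L
      else if (!is.na(mt) && M[mt, j] != 1L) a <- 1L - (M[mt, j] == 2L) * 1L
      if (!is.na(a)) { h1[i, j] <- a; h2[i, j] <- 1L - a }
    }
  }

  ## greedy LD rule, left to right: orient each remaining heterozygous site
  ## against the individual's most recent *heterozygous* phased site (through
  ## a homozygous run both gametes are identical, so the previous marker
  ## carries no orientation information), choosing the orientation whose two
  ## flanking two-locus haplotypes are jointly most frequent among the
  ## gametes already phased at both markers
  last_het <- rep(NA_integer_, n)
  for (j in seq_len(m)) {
    todo <- which(M[, j] == 1L & is.na(h1[, j]) & !unresolved[, j])
    if (length(todo) > 0) {
      for (jp in unique(last_het[todo])) {
        ii <- todo[if (is.na(jp)) is.na(last_het[todo]) else
                     !is.na(last_het[todo]) & last_het[todo] == jp]
        if (is.na(jp)) {
          h1[ii, j] <- 1L; h2[ii, j] <- 0L    # no anchor: arbitrary, deterministic
          next
        }
        known <- !is.na(h1[, jp]) & !is.na(h1[, j])
        cnt <- matrix(1, 2, 2)   # add-one smoothing; cnt[a+1, b+1] = #(a -> b)
        if (any(known)) {
          for (g in list(cbind(h1[known, jp], h1[known, j]),
                         cbind(h2[known, jp], h2[known, j]))) {
            cnt <- cnt + as.matrix(table(factor(g[, 1], levels = 0:1),
                                         factor(g[, 2], levels = 0:1)))
          }
        }
        lcnt <- log(cnt)
        for (i in ii) {
          pa <- h1[i, jp]; pb <- h2[i, jp]
          la <- lcnt[pa + 1L, 2L] + lcnt[pb + 1L, 1L]  # hap1 carries the 1
          lb <- lcnt[pa + 1L, 1L] + lcnt[pb + 1L, 2L]  # hap2 carries the 1
          h1[i, j] <- as.integer(la >= lb)
          h2[i, j] <- 1L - h1[i, j]
        }
      }
    }
    het_now <- which(M[, j] == 1L & !is.na(h1[, j]) & h1[, j] != h2[, j])
    last_het[het_now] <- j
  }
  still <- is.na(h1)
  unresolved <- unresolved | still
  h1[still] <- 1L; h2[still] <- M[still] - 1L
  out <- genotype_panel(M, panel$map, ids = panel$ids, hap1 = h1, hap2 = h2)
  attr(out, "unresolved") <- unresolved
  out
}

#' Haplotype windows of four consecutive polymorphic SNPs
#'
#' One window starts at every polymorphic marker that is followed by three
#' more polymorphic markers; monomorphic markers are skipped when picking
#' the four.  The window position is the cM midpoint of its four markers.
#'
#' @param phased a phased [genotype_panel()].
#' @return data.frame with one row per window: `start` (index of the first
#'   of the four markers), `m1..m4` (marker column indices), `pos_cM`.
#' @export
make_windows <- function(phased) {
  poly <- which(panel_maf(phased) > 0)
  if (length(poly) < 4) stop_config("need at least 4 polymorphic markers")
  k <- length(poly) - 3L
  idx <- cbind(poly[1:k], poly[2:(k + 1)], poly[3:(k + 2)], poly[4:(k + 3)])
  data.frame(start = idx[, 1], m1 = idx[, 1], m2 = idx[, 2], m3 = idx[, 3],
             m4 = idx[, 4],
             pos_cM = rowMeans(matrix(phased$map$cM[idx], ncol = 4)))
}

popcount4 <- c(0L, 1L, 1L, 2L, 1L, 2L, 2L, 3L, 1L, 2L, 2L, 3L, 2L, 3L, 3L, 4L)

## integer code 0..15 of the 4-SNP haplotype carried by each gamete
window_codes <- function(phased, win) {
  cols <- c(win$m1, win$m2, win$m3, win$m4)
  unres <- attr(phased, "unresolved")
  code_of <- function(H) {
    v <- H[, cols[1]] * 8L + H[, cols[2]] * 4L + H[, cols[3]] * 2L + H[, cols[4]]
    if (!is.null(unres)) v[rowSums(unres[, cols, drop = FALSE]) > 0] <- NA_integer_
    v
  }
  list(c1 = code_of(phased$hap1), c2 = code_of(phased$hap2))
}

#' Trace haplotype transmissions down the pedigree
#'
#' Within a 4-SNP window, an offspring gamete that is identical in state to
#' the transmitting parent's gamete over the four SNPs is considered
#' identical by descent with it and joins that gamete's group; non-matching
#' (recombinant) gametes, gametes of unknown parents, and phase-unresolved
#' gametes found new founder-level groups.  When both parental gametes match
#' (parent homozygous over the window) the sire-side gamete's group is taken.
#'
#' @param window one row of [make_windows()].
#' @param phased a phased [genotype_panel()] covering the pedigree.
#' @param pedigree the pedigree.
#' @return list: `g1`, `g2` (group id per individual's sire/dam gamete),
#'   `group_code` (4-SNP code per group, `NA` for unresolved founders).
#' @export
trace_transmission <- function(window, phased, pedigree) {
  codes <- window_codes(phased, window)
  c1 <- codes$c1; c2 <- codes$c2
  n <- nrow(pedigree)
  prow <- match(as.character(pedigree$id), phased$ids)
  if (anyNA(prow)) stop_config("phased panel must cover every pedigree individual")
  c1 <- c1[prow]; c2 <- c2[prow]
  row_of <- match(seq_len(max(pedigree$id)), pedigree$id)
  g1 <- g2 <- integer(n)
  group_code <- integer(0)
  n_groups <- 0L
  new_groups <- function(codes_new) {
    ids <- n_groups + seq_along(codes_new)
    group_code <<- c(group_code, codes_new)
    n_groups <<- n_groups + length(codes_new)
    ids
  }
  for (g in sort(unique(pedigree$generation))) {
    I <- which(pedigree$generation == g)
    if (g == 0L) {
      g1[I] <- new_groups(c1[I])
      g2[I] <- new_groups(c2[I])
      next
    }
    for (side in 1:2) {
      par <- if (side == 1) pedigree$sire[I] else pedigree$dam[I]
      cg <- if (side == 1) c1[I] else c2[I]
      pr <- ifelse(par > 0L, row_of[pmax(par, 1L)], NA_integer_)
      m1 <- !is.na(cg) & !is.na(pr) & !is.na(c1[pr]) & cg == c1[pr]
      m2 <- !m1 & !is.na(cg) & !is.na(pr) & !is.na(c2[pr]) & cg == c2[pr]
      gid <- integer(length(I))
      gid[m1] <- g1[pr[m1]]
      gid[m2] <- g2[pr[m2]]
      fresh <- !(m1 | m2)
      gid[fresh] <- new_groups(cg[fresh])
      if (side == 1) g1[I] <- gid else g2[I] <- gid
    }
  }
  list(g1 = g1, g2 = g2, group_code = group_code)
}

## alikeness-in-state similarity between two 4-SNP codes
code_similarity <- function(a, b) (4L - popcount4[bitwXor(a, b) + 1L]) / 4

#' Cluster founder-level haplotypes and build the LDLA covariance
#'
#' Founder-level haplotype groups (which cannot have identity-by-descent
#' ascertained) are merged by single-linkage agglomeration on
#' alikeness-in-state similarity — the fraction of identical alleles among
#' the four SNPs, all positions weighted equally — cut at
#' `similarity_threshold`.  Groups with unresolved phase stay in singleton
#' clusters.  The cluster covariance `H` has unit diagonal and
#' between-cluster mean alikeness off the diagonal (a simple
#' coalescence-style resemblance), floored to positive semi-definiteness by
#' zeroing negative eigenvalues.  `T` maps each individual's two gametes to
#' cluster columns.
#'
#' @param groups a [trace_transmission()] result.
#' @param similarity_threshold merge clusters at or above this similarity
#'   (default 1: merge exactly identical haplotypes; the resemblance between
#'   non-identical haplotypes is carried by `H` instead).
#' @return list: `T` (individuals x clusters gamete counts), `H` (cluster
#'   covariance), `n_clusters`, `cluster_of` (cluster per group id).
#' @export
cluster_founders <- function(groups, similarity_threshold = 1) {
  gc <- groups$group_code
  n_groups <- length(gc)
  codes <- sort(unique(gc[!is.na(gc)]))
  k <- length(codes)
  ## cluster the distinct states (identical states always merge first)
  if (k > 1 && similarity_threshold < 1) {
    sim <- outer(codes, codes, code_similarity)
    hc <- stats::hclust(stats::as.dist(1 - sim), method = "single")
    memb <- stats::cutree(hc, h = 1 - similarity_threshold + 1e-9)
  } else {
    memb <- seq_len(k)
  }
  cluster_of_code <- memb
  n_state_clusters <- if (k > 0) max(memb) else 0L
  ## unresolved groups: one singleton cluster each
  cluster_of <- integer(n_groups)
  known <- !is.na(gc)
  cluster_of[known] <- cluster_of_code[match(gc[known], codes)]
  if (any(!known))
    cluster_of[!known] <- n_state_clusters + seq_len(sum(!known))
  n_clusters <- n_state_clusters + sum(!known)
  ## H: mean alikeness between the member states of two clusters, weighted
  ## by how many founder-level groups carry each state
  H <- diag(n_clusters)
  if (n_state_clusters >= 1) {
    wts <- as.numeric(table(factor(gc[known], levels = codes)))
    simc <- outer(codes, codes, code_similarity)
    for (aa in seq_len(n_state_clusters)) for (bb in seq_len(n_state_clusters)) {
      if (aa == bb) next
      ia <- which(cluster_of_code == aa); ib <- which(cluster_of_code == bb)
      wa <- wts[ia]; wb <- wts[ib]
      H[aa, bb] <- sum(outer(wa, wb) * simc[ia, ib, drop = FALSE]) / (sum(wa) * sum(wb))
    }
  }
  ## PSD floor
  if (n_clusters > 1) {
    eg <- eigen(H, symmetric = TRUE)
    if (min(eg$values) < 0)
      H <- eg$vectors %*% (pmax(eg$values, 0) * t(eg$vectors))
  }
  n <- length(groups$g1)
  TT <- matrix(0, n, n_clusters)
  i1 <- cbind(seq_len(n), cluster_of[groups$g1])
  i2 <- cbind(seq_len(n), cluster_of[groups$g2])
  TT[i1] <- TT[i1] + 1
  TT[i2] <- TT[i2] + 1
  list(T = TT, H = H, n_clusters = n_clusters, cluster_of = cluster_of)
}

#' LDLA scan: haplotype-cluster variance component per locus
#'
#' At every 4-SNP window the variance-component model
#' `y = 1 mu + u + T h + e` with `Var(u) = A s2u` (pedigree polygenic) and
#' `Var(h) = H s2h` (haplotype clusters) is fitted by REML and compared with
#' the no-haplotype null by a likelihood ratio test.  Because one variance
#' component is tested on its boundary, P values use the standard 50:50
#' mixture of chi-squared(0) and chi-squared(1).  The null model is fitted
#' once (it does not involve the window) and reused at every window.
#'
#' @param y named phenotype vector.
#' @param phased phased [genotype_panel()] covering the whole pedigree.
#' @param pedigree the pedigree.
#' @param A pedigree relationship matrix from [pedigree_nrm()].
#' @param similarity_threshold see [cluster_founders()].
#' @param tol,max_iter REML controls for the per-window alternative fit.
#' @return a `qtl_scan` object with per-window `stat` (LRT), `p`, `score`.
#' @export
ldla_scan <- function(y, phased, pedigree, A,
                      similarity_threshold = 1, tol = 1e-6, max_iter = 200L) {
  ids <- names(y)
  if (is.null(ids)) stop_config("y must be named by individual id")
  ai <- match(ids, rownames(A))
  if (anyNA(ai)) stop_config("A does not cover all phenotyped individuals")
  A <- A[ai, ai]
  null_fit <- reml(y, random = list(polygenic = A))
  U <- null_fit$eigen$U; d <- null_fit$eigen$d
  yt <- null_fit$yt; Xt <- null_fit$Xt
  ll0 <- null_fit$logLik
  s2 <- null_fit$sigma2
  wins <- make_windows(phased)
  rows <- match(ids, phased$ids)
  nw <- nrow(wins)
  stat <- p <- rep(NA_real_, nw)
  flag <- rep("ok", nw)
  vy <- stats::var(y)
  for (wdx in seq_len(nw)) {
    grp <- trace_transmission(wins[wdx, ], phased, pedigree)
    cl <- cluster_founders(grp, similarity_threshold)
    Tp <- cl$T[match(ids, as.character(pedigree$id)), , drop = FALSE]
    keep <- colSums(Tp) > 0
    Tp <- Tp[, keep, drop = FALSE]
    Hp <- cl$H[keep, keep, drop = FALSE]
    if (ncol(Tp) < 2) { stat[wdx] <- 0; p[wdx] <- 1; flag[wdx] <- "degenerate"; next }
    B <- crossprod(U, Tp)
    init <- c(max(s2[1], 1e-4 * vy), 0.1 * max(s2[2], 1e-4 * vy), max(s2[2], 1e-4 * vy))
    fit <- reml_two_lowrank(yt, Xt, d, B, Hp, init, tol = tol, max_iter = max_iter)
    if (!fit$converged && fit$logLik < ll0) {
      stat[wdx] <- 0; p[wdx] <- 1; flag[wdx] <- "nonconverged"
      next
    }
    lrt <- max(0, 2 * (fit$logLik - ll0))
    stat[wdx] <- lrt
    p[wdx] <- if (lrt > 0) 0.5 * stats::pchisq(lrt, 1, lower.tail = FALSE) else 1
  }
  new_qtl_scan(method = "ldla", pos = wins$pos_cM, stat = stat, p = p,
               score = -log10(p), flag = flag,
               details = list(null_fit = null_fit, windows = wins,
                              similarity_threshold = similarity_threshold))
}
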