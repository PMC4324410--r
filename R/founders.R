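#' Draw founder haplotypes with calibrated linkage disequilibrium
#'
#' Founder haplotypes are drawn from a first-order Markov copying process
#' along the map: the allele at marker j is correlated with the allele at
#' marker j-1 with target correlation `r_j = ld_strength^(d_j / mean(d))`,
#' where `d_j` is the inter-marker distance in cM — i.e. LD decays
#' geometrically with map distance and equals `ld_strength` exactly at the
#' average spacing.  Transition probabilities are solved from the target
#' allele frequencies and the target covariance (and clipped into \[0,1\]
#' when the correlation is unattainable for very different frequencies, the
#' usual constraint on correlated binary variables).
#'
#' The default allele-frequency profile is a smooth reflected random walk in
#' \[0.08, 0.5\], so neighbouring markers have similar frequencies and high
#' pairwise LD is attainable along the whole chromosome.
#'
#' @param n_founders number of founder individuals (2 haplotypes each).
#' @param map a [genetic_map()].
#' @param maf_profile optional vector of per-marker target allele
#'   frequencies in (0, 1); drawn smoothly if `NULL`.
#' @param ld_strength target adjacent-marker allelic correlation at the mean
#'   marker spacing, in \[0, 1).
#' @param seed integer seed.
#' @return a 0/1 matrix with `2 * n_founders` rows (haplotypes) and one
#'   column per marker; attribute `"p_target"` holds the frequency profile.
#' @examples
#' m <- genetic_map(50, 40)
#' H <- draw_founder_haplotypes(100, m, ld_strength = 0.8, seed = 1)
#' cor(H[, 1], H[, 2])
#' @export
draw_founder_haplotypes <- function(n_founders, map, maf_profile = NULL,
                                    ld_strength = 0.8, seed = NULL) {
  stopifnot(nrow(map) >= 1, n_founders >= 1)
  if (ld_strength < 0 || ld_strength >= 1)
    stop_config("ld_strength must be in [0, 1)")
  with_seed(seed, {
    m <- nrow(map)
    if (is.null(maf_profile)) maf_profile <- smooth_freq_profile(m)
    if (length(maf_profile) != m || any(maf_profile <= 0) || any(maf_profile >= 1))
      stop_config("maf_profile must give one frequency in (0,1) per marker")
    n_hap <- 2L * n_founders
    H <- matrix(0L, n_hap, m)
    p <- maf_profile
    H[, 1] <- stats::rbinom(n_hap, 1L, p[1])
    if (m > 1L) {
      d <- diff(map$cM)
      dbar <- mean(d)
      r <- if (ld_strength == 0) rep(0, m - 1L) else {
        ex <- if (dbar > 0) d / dbar else rep(1, m - 1L)
        ld_strength^ex
      }
      for (j in 2:m) {
        cov_t <- r[j - 1L] * sqrt(p[j - 1L] * (1 - p[j - 1L]) * p[j] * (1 - p[j]))
        p11 <- clamp(p[j] + cov_t / p[j - 1L], 0, 1)          # P(1 | previous = 1)
        p10 <- clamp(p[j] - cov_t / (1 - p[j - 1L]), 0, 1)    # P(1 | previous = 0)
        prev <- H[, j - 1L] == 1L
        H[, j] <- stats::rbinom(n_hap, 1L, ifelse(prev, p11, p10))
      }
    }
    attr(H, "p_target") <- p
    H
  })
}

## reflected Gaussian random walk for allele frequencies
smooth_freq_profile <- function(m, lo = 0.08, hi = 0.5, step = 0.02) {
  p <- numeric(m)
  p[1] <- stats::runif(1, 0.15, 0.45)
  if (m > 1) for (j in 2:m) {
    x <- p[j - 1] + stats::rnorm(1, 0, step)
    while (x < lo || x > hi) x <- ifelse(x < lo, 2 * lo - x, 2 * hi - x)
    p[j] <- x
  }
  p
}

## block frequency profile: the chromosome is cut into blocks whose mean
## frequencies include the requested anchor values (so markers near every
## anchor MAF exist, with similar-frequency neighbours -> high LD pairs are
## attainable there); within a block the profile mean-reverts around the
## block mean
block_freq_profile <- function(m, anchors = c(0.1, 0.3), lo = 0.05, hi = 0.5,
                               step = 0.015) {
  nb <- max(4L, min(10L, m %/% 15L))
  means <- stats::runif(nb, 0.12, 0.45)
  slots <- sample.int(nb, min(2L * length(anchors), nb))
  means[slots] <- rep(anchors, length.out = length(slots))
  sizes <- split_counts(m, nb)
  p <- numeric(0)
  for (b in seq_len(nb)) {
    x <- numeric(sizes[b])
    x[1] <- clamp(means[b] + stats::rnorm(1, 0, step), lo, hi)
    if (sizes[b] > 1) for (j in 2:sizes[b])
      x[j] <- clamp(x[j - 1] + stats::rnorm(1, 0, step) +
                      0.1 * (means[b] - x[j - 1]), lo, hi)
    p <- c(p, x)
  }
  p
}

## perturb a base frequency profile to mimic a diverged line/breed;
## amount plays the role of a drift (Fst-like) parameter
diverge_freq_profile <- function(p, amount = 0.1) {
  clamp(p + stats::rnorm(length(p), 0, amount * sqrt(p * (1 - p)) * 2), 0.02, 0.98)
}
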