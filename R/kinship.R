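#' Pedigree numerator relationship matrix (tabular method)
#'
#' Computes the additive (numerator) relationship matrix A over all pedigree
#' individuals by the tabular method: founders are unrelated and non-inbred,
#' `A[i,i] = 1 + A[s,d]/2` and `A[j,i] = (A[j,s] + A[j,d])/2` with unknown
#' parents contributing zero.
#'
#' @param pedigree a topologically ordered [build_pedigree()] result.
#' @return a symmetric matrix with dimnames set to the individual ids, of
#'   class `"kinship_matrix"` with attribute `kind = "pedigree_A"`.
#' @examples
#' ped <- build_pedigree(pedigree_design("large_half_sib", 20, 2), seed = 1)
#' A <- pedigree_nrm(ped)
#' range(diag(A))
#' @export
pedigree_nrm <- function(pedigree) {
  validate_pedigree(pedigree)
  n <- nrow(pedigree)
  row_of <- match(seq_len(max(pedigree$id)), pedigree$id)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- pedigree$sire[i]; d <- pedigree$dam[i]
    sr <- if (s > 0L) row_of[s] else NA_integer_
    dr <- if (d > 0L) row_of[d] else NA_integer_
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (is.na(sr)) 0 else A[j, sr]
      ad_ <- if (is.na(dr)) 0 else A[j, dr]
      aji <- 0.5 * (as_ + ad_)
      A[j, i] <- aji
      A[i, j] <- aji
    }
    A[i, i] <- 1 + if (is.na(sr) || is.na(dr)) 0 else 0.5 * A[sr, dr]
  }
  dimnames(A) <- list(pedigree$id, pedigree$id)
  structure(A, kind = "pedigree_A", class = c("kinship_matrix", "matrix", "array"))
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = Z Z' / (2 * sum p_j (1 - p_j))` with `Z` the dosage matrix centered
#' by twice the observed allele frequencies.  Monomorphic markers are
#' dropped; a small ridge (1e-6) is added to the diagonal so G is always
#' invertible.
#'
#' @param panel a [genotype_panel()] with at least two polymorphic markers.
#' @param ridge diagonal ridge added for numerical invertibility.
#' @return a symmetric matrix over the panel individuals, class
#'   `"kinship_matrix"` with attribute `kind = "genomic_G"`.
#' @export
genomic_relationship <- function(panel, ridge = 1e-6) {
  M <- panel$dosage
  p <- colMeans(M) / 2
  poly <- colMeans(M^2) - colMeans(M)^2 > 0   # truly segregating markers
  if (sum(poly) < 2) stop_config("need at least 2 polymorphic markers for G")
  M <- M[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(M, 2, 2 * p)
  G <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  diag(G) <- diag(G) + ridge
  dimnames(G) <- list(panel$ids, panel$ids)
  structure(G, kind = "genomic_G", class = c("kinship_matrix", "matrix", "array"))
}

#' Write a kinship matrix as lower-triangle text
#'
#' @param K a `kinship_matrix`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_kinship <- function(K, file) {
  ids <- rownames(K)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste(ids, collapse = " "), con)
  for (i in seq_len(nrow(K)))
    writeLines(paste(format(K[i, seq_len(i)], digits = 10), collapse = " "), con)
  invisible(file)
}
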