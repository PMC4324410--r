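#' Create a genetic map for one chromosome
#'
#' A genetic map gives marker positions in centimorgans (cM) along a single
#' chromosome.  Positions must be nondecreasing; all downstream machinery
#' (recombination in gene dropping, window positions, localization scoring)
#' works in cM, never base pairs.
#'
#' @param n_markers number of markers.
#' @param length_cM chromosome length in cM (the last marker sits at
#'   `length_cM`, the first at 0).
#' @param chrom chromosome label.
#' @param positions optional explicit cM positions (overrides the default
#'   equally-spaced layout); must be nondecreasing.
#' @param marker_ids optional marker names; defaults to `M1..Mn`.
#' @return a `data.frame` of class `"genetic_map"` with columns
#'   `chrom`, `id`, `cM`.
#' @examples
#' genetic_map(10, length_cM = 90)
#' @export
genetic_map <- function(n_markers, length_cM, chrom = "1",
                        positions = NULL, marker_ids = NULL) {
  stopifnot(n_markers >= 1, length_cM > 0)
  if (is.null(positions)) {
    positions <- if (n_markers == 1L) 0 else seq(0, length_cM, length.out = n_markers)
  }
  if (length(positions) != n_markers)
    stop_config("map has %d positions for %d markers", length(positions), n_markers)
  if (is.unsorted(positions))
    stop_config("map positions must be nondecreasing")
  if (is.null(marker_ids)) marker_ids <- paste0("M", seq_len(n_markers))
  out <- data.frame(chrom = as.character(chrom), id = marker_ids, cM = as.numeric(positions),
                    stringsAsFactors = FALSE)
  class(out) <- c("genetic_map", "data.frame")
  out
}

#' Construct a genotype panel
#'
#' The container consumed by every scan: an individuals-by-markers dosage
#' matrix coded 0/1/2 (copies of the reference-counted allele), a genetic map,
#' and optionally the two phased haplotype matrices (0/1) whose sum must equal
#' the dosage at every cell.
#'
#' @param dosage integer matrix, individuals in rows, markers in columns,
#'   values in {0,1,2}.
#' @param map a [genetic_map()] with one row per marker column.
#' @param ids individual identifiers (defaults to rownames or 1..n).
#' @param hap1,hap2 optional phased haplotype matrices ({0,1}); by convention
#'   `hap1` is the sire-transmitted gamete and `hap2` the dam-transmitted
#'   gamete where the origin is known.
#' @return an object of class `"genotype_panel"`.
#' @export
genotype_panel <- function(dosage, map, ids = NULL, hap1 = NULL, hap2 = NULL) {
  dosage <- as.matrix(dosage)
  if (!all(dosage %in% 0:2)) stop_config("dosage values must be in {0,1,2}")
  if (nrow(map) != ncol(dosage))
    stop_config("map has %d markers but dosage has %d columns", nrow(map), ncol(dosage))
  if (is.null(ids)) ids <- rownames(dosage) %||% as.character(seq_len(nrow(dosage)))
  if (anyDuplicated(ids)) stop_config("individual ids must be unique")
  if (!is.null(hap1)) {
    stopifnot(!is.null(hap2), all(dim(hap1) == dim(dosage)), all(dim(hap2) == dim(dosage)))
    if (!all(hap1 + hap2 == dosage))
      stop_config("hap1 + hap2 must equal dosage at every cell")
  }
  rownames(dosage) <- ids
  structure(list(dosage = dosage, hap1 = hap1, hap2 = hap2,
                 map = map, ids = as.character(ids)),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d individuals x %d markers (chr %s, %.1f cM)%s\n",
              nrow(x$dosage), ncol(x$dosage), x$map$chrom[1],
              max(x$map$cM) - min(x$map$cM),
              if (is.null(x$hap1)) ", unphased" else ", phased"))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosage)

#' Minor allele frequencies of a panel
#' @param panel a [genotype_panel()].
#' @return numeric vector of per-marker minor allele frequencies.
#' @export
panel_maf <- function(panel) {
  p <- colMeans(panel$dosage) / 2
  pmin(p, 1 - p)
}

#' Subset a genotype panel
#'
#' @param panel a [genotype_panel()].
#' @param individuals ids (character) or row indices to keep.
#' @param markers marker column indices to keep.
#' @return a `genotype_panel` restricted to the selection.
#' @export
subset_panel <- function(panel, individuals = NULL, markers = NULL) {
  ri <- if (is.null(individuals)) seq_along(panel$ids) else {
    if (is.character(individuals)) match(individuals, panel$ids) else individuals
  }
  if (anyNA(ri)) stop_config("unknown individual id in subset")
  ci <- markers %||% seq_len(ncol(panel$dosage))
  genotype_panel(panel$dosage[ri, ci, drop = FALSE],
                 structure(panel$map[ci, , drop = FALSE],
                           class = class(panel$map)),
                 ids = panel$ids[ri],
                 hap1 = if (!is.null(panel$hap1)) panel$hap1[ri, ci, drop = FALSE],
                 hap2 = if (!is.null(panel$hap2)) panel$hap2[ri, ci, drop = FALSE])
}
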