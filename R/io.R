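# Readers and writers for the package's plain-text interchange formats.
# All coordinates are cM; dosage files carry marker ids in the header and
# one row per individual.  Every writer's output is re-parseable by the
# matching reader.

#' Write / read a genetic map (TSV: chrom, id, cM)
#' @param map a [genetic_map()].
#' @param file path.
#' @return `file` (writer) / a `genetic_map` (reader).
#' @export
write_map <- function(map, file) {
  utils::write.table(map, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_map
#' @export
read_map <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          colClasses = c("character", "character", "numeric"))
  genetic_map(nrow(df), length_cM = max(max(df$cM), 1e-9), chrom = df$chrom[1],
              positions = df$cM, marker_ids = df$id)
}

#' Write / read genotype dosages (TSV)
#'
#' Header: `id` then one column per marker id; one row per individual,
#' dosages in {0,1,2}.
#'
#' @param panel a [genotype_panel()].
#' @param file path.
#' @param map the [genetic_map()] of the markers in the file (reader).
#' @return `file` (writer) / a `genotype_panel` (reader; unphased).
#' @export
write_genotypes <- function(panel, file) {
  df <- data.frame(id = panel$ids, panel$dosage, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("id", panel$map$id)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(file, map) {
  df <- utils::read.table(file, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character")
  if (!identical(colnames(df)[-1], map$id))
    stop_config("marker columns of %s do not match the map (strict order check)", file)
  M <- suppressWarnings(matrix(as.integer(as.matrix(df[, -1, drop = FALSE])),
                               nrow = nrow(df)))
  bad <- which(is.na(M) | M < 0L | M > 2L, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_config("invalid dosage at line %d (individual %s), marker %s",
                bad[1, 1] + 1L, df$id[bad[1, 1]], map$id[bad[1, 2]])
  genotype_panel(M, map, ids = df$id)
}

#' Write / read a pedigree (CSV: id, sire, dam, generation; 0 = unknown)
#' @param pedigree a [build_pedigree()] result.
#' @param file path.
#' @return `file` (writer) / a `pedigree` (reader).
#' @export
write_pedigree <- function(pedigree, file) {
  utils::write.csv(pedigree[, c("id", "sire", "dam", "generation")], file,
                   quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(file) {
  df <- utils::read.csv(file, colClasses = "integer")
  ped <- new_pedigree(df$id, df$sire, df$dam, df$generation,
                      sex = rep(NA_character_, nrow(df)), founder_pop = NULL)
  validate_pedigree(ped)
  ped
}

#' Write / read phenotypes (TSV: id, value)
#' @param y named phenotype vector (or a `phenotype_set`).
#' @param file path.
#' @return `file` (writer) / a named numeric vector (reader).
#' @export
write_phenotypes <- function(y, file) {
  if (inherits(y, "phenotype_set")) y <- y$y
  utils::write.table(data.frame(id = names(y), value = as.numeric(y)), file,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          colClasses = c("character", "numeric"))
  stats::setNames(df$value, df$id)
}

#' Write / read a scan result (TSV: position_cM, statistic, P, score, flag)
#' @param scan a `qtl_scan`.
#' @param file path.
#' @param method method tag to attach on reading.
#' @return `file` (writer) / a `qtl_scan` (reader; details are not
#'   round-tripped).
#' @export
write_scan <- function(scan, file) {
  tb <- scan$table
  utils::write.table(data.frame(position_cM = tb$pos_cM, statistic = tb$stat,
                                P = tb$p, score = tb$score, flag = tb$flag),
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_scan
#' @export
read_scan <- function(file, method = "unknown") {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  new_qtl_scan(method = method, pos = df$position_cM, stat = df$statistic,
               p = df$P, score = df$score, flag = df$flag)
}

#' Write genotypes as a minimal VCF (GT field only)
#'
#' Dosages 0/1/2 become unphased GT calls `0/0`, `0/1`, `1/1`; when the
#' panel is phased, `0|1` vs `1|0` preserves the gamete of origin.  POS is
#' the cM position times `1 / pos_scale`, rounded; alleles are written as
#' placeholder A/G.
#'
#' @param panel a [genotype_panel()].
#' @param file output path.
#' @param pos_scale multiplier from POS units to cM (matches
#'   [read_vcf_genotypes()]).
#' @return `file`, invisibly.
#' @export
write_vcf_genotypes <- function(panel, file, pos_scale = 0.01) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel$ids), collapse = "\t")), con)
  phased <- !is.null(panel$hap1)
  for (j in seq_len(ncol(panel$dosage))) {
    gt <- if (phased) paste0(panel$hap1[, j], "|", panel$hap2[, j]) else
      c("0/0", "0/1", "1/1")[panel$dosage[, j] + 1L]
    writeLines(paste(c(panel$map$chrom[j],
                       max(1L, round(panel$map$cM[j] / pos_scale)),
                       panel$map$id[j], "A", "G", ".", ".", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(file)
}

#' Read genotypes from a minimal VCF (GT field only)
#'
#' Converts diploid GT calls (`0/0`, `0/1`, `1/1`, phased or unphased) to
#' dosages 0/1/2.  Positions are taken from the `POS` column and interpreted
#' on the scale given by `pos_scale` (defaults to treating POS as
#' centimorgan hundredths).  Requires the `vcfR` package.
#'
#' @param file VCF path.
#' @param pos_scale multiplier from POS units to cM.
#' @return an unphased [genotype_panel()].
#' @export
read_vcf_genotypes <- function(file, pos_scale = 0.01) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop_config("read_vcf_genotypes needs the 'vcfR' package")
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_integer_)
    sum(as.integer(strsplit(g, "[/|]")[[1]]))
  })
  if (anyNA(dos)) stop_config("missing GT calls are not supported")
  fix <- vcfR::getFIX(v)
  map <- genetic_map(nrow(fix), length_cM = max(as.numeric(fix[, "POS"]) * pos_scale, 1e-9),
                     chrom = fix[1, "CHROM"],
                     positions = as.numeric(fix[, "POS"]) * pos_scale,
                     marker_ids = fix[, "ID"])
  genotype_panel(t(dos), map, ids = colnames(gt))
}
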