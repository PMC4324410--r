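#' Dataset-shaped fixture presets
#'
#' Five population fixtures whose sizes, pedigree shapes, marker densities
#' and chromosome lengths mirror typical dense-SNP livestock mapping panels:
#' large half-sib dairy-cattle families, smaller beef-cattle families, a
#' three-generation sheep backcross between two lines, many small horse
#' families, and a three-breed pig panel.
#'
#' @param name one of `"dairy"`, `"beef"`, `"sheep"`, `"horse"`, `"pig"`.
#' @param scale multiplier applied to individual and marker counts (use
#'   e.g. 0.25 for desk-scale runs); chromosome length is kept.
#' @return list with `design` (a [pedigree_design()]), `n_markers`,
#'   `length_cM`, `chrom`, `phenotype_founders` (whether genotyped founder
#'   sires are phenotyped, horse-style).
#' @export
fixture_preset <- function(name = c("dairy", "beef", "sheep", "horse", "pig"),
                           scale = 1) {
  name <- match.arg(name)
  spec <- switch(name,
    dairy = list(kind = "large_half_sib", n = 1221L, sires = 30L, gens = 2L,
                 markers = 2854L, len = 161, chrom = "1", pf = FALSE),
    beef  = list(kind = "small_half_sib", n = 936L, sires = 187L, gens = 2L,
                 markers = 1889L, len = 112, chrom = "7", pf = FALSE),
    sheep = list(kind = "backcross_3gen", n = 1067L, sires = 8L, gens = 4L,
                 markers = 1424L, len = 79, chrom = "12", pf = FALSE),
    horse = list(kind = "many_small_families", n = 627L, sires = 102L, gens = 2L,
                 markers = 2267L, len = 119, chrom = "3", pf = TRUE),
    pig   = list(kind = "multi_subpop", n = 764L, sires = 327L, gens = 2L,
                 markers = 1672L, len = 60, chrom = "17", pf = FALSE))
  n <- max(20L, as.integer(round(spec$n * scale)))
  sires <- max(2L, as.integer(round(spec$sires * scale)))
  if (sires >= n) sires <- max(2L, n %/% 4L)
  list(name = name,
       design = pedigree_design(spec$kind, n_individuals = n, n_sires = sires,
                                generations = spec$gens),
       n_markers = max(20L, as.integer(round(spec$markers * scale))),
       length_cM = spec$len, chrom = spec$chrom,
       phenotype_founders = spec$pf)
}

#' Configuration for a simulation-and-scan pipeline run
#'
#' @param fixture fixture name, see [fixture_preset()].
#' @param scenario scenario id 1..5 or a [simulation_scenario()].
#' @param methods which scans to run.
#' @param n_replicates phenotype replicates (the genotype panel and causal
#'   marker are fixed per scenario, as when simulating on real genotypes).
#' @param seed master seed; all per-replicate seeds are derived from it.
#' @param out_dir output directory.
#' @param scale fixture down-scaling factor.
#' @param thresholds threshold kinds to evaluate.
#' @param half_widths QTL-region half-widths in cM.
#' @param bayesc_iter Gibbs chain length for the BayesC scans.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(fixture, scenario = 1, methods = c("emma", "ldla", "bayesc"),
                       n_replicates = 5L, seed = 1L, out_dir = tempfile("qtlscan_run_"),
                       scale = 0.25,
                       thresholds = c("bonferroni", "pseudo_null_5pct"),
                       half_widths = c(0.5, 1, 2),
                       bayesc_iter = 10000L) {
  if (!fixture %in% c("dairy", "beef", "sheep", "horse", "pig"))
    stop_config("unknown fixture '%s'", fixture)
  if (!is.list(scenario)) scenario <- simulation_scenario(scenario)
  methods <- match.arg(methods, several.ok = TRUE)
  structure(list(fixture = fixture, scenario = scenario, methods = methods,
                 n_replicates = as.integer(n_replicates), seed = as.integer(seed),
                 out_dir = out_dir, scale = scale, thresholds = thresholds,
                 half_widths = half_widths, bayesc_iter = as.integer(bayesc_iter)),
            class = "run_config")
}

#' Run the simulate / scan / threshold / evaluate pipeline
#'
#' Builds the fixture population once per scenario (pedigree, LD-structured
#' panel, causal marker — fixed across replicates, emulating repeated
#' phenotype simulation on one real genotype panel), then per replicate
#' simulates phenotypes, runs the requested scans on the masked panel, and
#' finally derives thresholds (Bonferroni per method; pseudo-null from the
#' non-QTL positions — those beyond 2 cM of every true QTL — pooled over
#' replicates), declares at most one QTL per replicate and method, and
#' scores MSE/power/FDR per window half-width.  All artifacts are written
#' under `config$out_dir` as plain text along with a manifest.
#'
#' @param config a [run_config()].
#' @return list with `grid` (long-format quality indicators), `thresholds`,
#'   `scans` (file paths), `qtl` (the truth), `manifest_file`; replicate
#'   failures are caught, reported in the manifest and excluded from the
#'   grid.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  fx <- fixture_preset(config$fixture, scale = config$scale)
  sc <- config$scenario
  map <- genetic_map(fx$n_markers, fx$length_cM, chrom = fx$chrom)
  ped <- build_pedigree(fx$design, seed = child_seed(config$seed, "ped"))
  panel <- sim_panel(ped, map, ld_strength = sc$ld_target,
                     seed = child_seed(config$seed, "panel"))
  qtl <- assign_qtl(panel, sc, seed = child_seed(config$seed, "qtl"))
  masked <- mask_qtl(panel, qtl)
  phen_ids <- as.character(nonfounders(ped))
  if (fx$phenotype_founders)
    phen_ids <- as.character(ped$id)
  A <- if ("ldla" %in% config$methods) pedigree_nrm(ped) else NULL
  G <- if ("emma" %in% config$methods)
    genomic_relationship(subset_panel(masked, individuals = phen_ids)) else NULL

  write_map(map, file.path(config$out_dir, "map.tsv"))
  write_pedigree(ped, file.path(config$out_dir, "pedigree.csv"))
  write_genotypes(masked, file.path(config$out_dir, "genotypes.tsv"))

  non_qtl <- function(scan) {
    tb <- scan$table
    keep <- tb$flag == "ok" &
      vapply(tb$pos_cM, function(x) min(abs(x - qtl$pos_cM)) > 2, TRUE)
    tb$score[keep]
  }

  scans <- list()
  scan_files <- character(0)
  failures <- character(0)
  for (r in seq_len(config$n_replicates)) {
    res <- tryCatch({
      phen <- simulate_phenotypes(panel, ped, qtl, sc,
                                  seed = child_seed(config$seed, "phen", r),
                                  phenotyped = intersect(phen_ids, panel$ids))
      write_phenotypes(phen, file.path(config$out_dir, sprintf("phenotypes_rep%03d.tsv", r)))
      out <- list()
      for (mth in config$methods) {
        scan <- switch(mth,
          emma = emma_scan(phen$y, masked, G),
          ldla = ldla_scan(phen$y, phase_panel(masked, ped), ped, A),
          bayesc = bayesc_scan(phen$y, masked,
                               bayesc_config(n_iter = config$bayesc_iter,
                                             seed = child_seed(config$seed, "bayesc", r))))
        f <- file.path(config$out_dir, sprintf("scan_%s_rep%03d.tsv", mth, r))
        write_scan(scan, f)
        scan_files <- c(scan_files, f)
        out[[mth]] <- scan
      }
      out
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("replicate %d: %s", r, conditionMessage(res)))
    } else {
      scans[[length(scans) + 1L]] <- res
    }
  }
  if (length(scans) == 0) stop_config("all replicates failed:\n%s",
                                      paste(failures, collapse = "\n"))

  ## thresholds per method
  ths <- list()
  rows <- list()
  for (mth in config$methods) {
    per <- lapply(scans, `[[`, mth)
    pooled <- unlist(lapply(per, non_qtl))
    maxima <- vapply(per, function(s) max(non_qtl(s)), 0)
    mth_ths <- list()
    if ("bonferroni" %in% config$thresholds) {
      mth_ths$bonferroni <- if (mth == "bayesc") bf_threshold() else
        bonferroni_threshold(0.05, sum(per[[1]]$table$flag == "ok"))
    }
    pn <- pseudo_null_thresholds(pooled,
                                 if (length(maxima) >= 10) maxima else NULL)
    for (k in intersect(config$thresholds, names(pn))) mth_ths[[k]] <- pn[[k]]
    ths[[mth]] <- mth_ths
    for (tk in names(mth_ths)) {
      dets <- lapply(per, top_signal, threshold = mth_ths[[tk]])
      for (hw in config$half_widths) {
        s <- score_replicates(dets, qtl, hw)
        for (ind in c("mse", "power", "fdr"))
          rows[[length(rows) + 1L]] <- data.frame(
            fixture = config$fixture, scenario = sc$id %||% 0L, method = mth,
            threshold = tk, half_width = hw, indicator = ind,
            value = s[[ind]], n = s$n_replicates, stringsAsFactors = FALSE)
      }
    }
  }
  grid <- do.call(rbind, rows)
  utils::write.table(grid, file.path(config$out_dir, "quality_grid.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  th_df <- do.call(rbind, lapply(names(ths), function(mth)
    do.call(rbind, lapply(names(ths[[mth]]), function(tk)
      data.frame(method = mth, kind = tk, cutoff = ths[[mth]][[tk]]$cutoff,
                 stringsAsFactors = FALSE)))))
  utils::write.table(th_df, file.path(config$out_dir, "thresholds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest_file <- file.path(config$out_dir, "manifest.txt")
  writeLines(c(
    sprintf("package_version\t%s", as.character(utils::packageVersion("qtlscan"))),
    sprintf("fixture\t%s", config$fixture),
    sprintf("scenario\t%s", sc$id %||% "custom"),
    sprintf("seed\t%d", config$seed),
    sprintf("n_replicates_requested\t%d", config$n_replicates),
    sprintf("n_replicates_completed\t%d", length(scans)),
    sprintf("methods\t%s", paste(config$methods, collapse = ",")),
    sprintf("scan_files\t%s", paste(basename(scan_files), collapse = ",")),
    if (length(failures)) paste0("failure\t", failures) else character(0)),
    manifest_file)
  if (length(failures) > 0)
    warning(sprintf("%d replicate(s) failed; see manifest", length(failures)))

  list(grid = grid, thresholds = ths, scans = scan_files, qtl = qtl,
       manifest_file = manifest_file, failures = failures)
}
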