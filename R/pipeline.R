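#' A built-in RFX-like position weight matrix
#'
#' A synthetic stand-in for an RFX-family X-box motif: a strong palindromic
#' 14-bp consensus (GTTGCCATGGCAAC) with 85% weight on the consensus base
#' at every position. Used as the default motif for synthetic runs; real
#' analyses should load a curated PWM via [readJasparPfm()] or
#' [readMemeMotifs()].
#'
#' @param dominance Probability of the consensus base per column
#'   (default 0.85).
#' @return A [PositionWeightMatrix-class].
#' @export
rfxLikePwm <- function(dominance = 0.85) {
  consensus <- strsplit("GTTGCCATGGCAAC", "")[[1]]
  rest <- (1 - dominance) / 3
  m <- matrix(rest, 4, length(consensus),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(consensus)) m[consensus[j], j] <- dominance
  PositionWeightMatrix(m, motif_id = "RFX_like_synthetic",
                       pseudocount = 0.01)
}

#' Default end-to-end run configuration
#'
#' All tunables for a fully synthetic pipeline run: genome size, catalog
#' composition, planting parameters, analysis thresholds, and cilium group
#' parameters. Values mirror the study conditions: a ~92-gene
#' motile/ciliogenic catalog, 1,000-gene negative sets, +/- 500 bp motif
#' windows, +/- 10 kb ChIP windows, and two cilium genotypes with a length
#' shift and a curvature difference.
#'
#' @param outdir Output directory.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return A nested list (class `"RunConfig"`).
#' @export
defaultRunConfig <- function(outdir = tempfile("mitoCilia_run_"),
                             seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    outdir = outdir,
    stages = c("simulate", "de_programs", "motif", "peaks", "cilia"),
    simulate = list(
      n_genes = 3000L, n_chroms = 3L, chrom_len = 2e6,
      catalog = list(motile = 40L, primary = 26L, pan = 26L),
      planted_fraction = 0.6, effect_mean = 2, effect_sd = 0.5,
      promoter_offset_sd = 50, peak_background_density = 5e-5,
      peak_excess_rate = 2, peak_offset_sd = 2000,
      cilia = list(
        ctrl = list(length_mean = 3.2, length_sd = 0.8, curvature = 0.05),
        mutant = list(length_mean = 4.8, length_sd = 1.2,
                      curvature = 0.6)),
      n_cilia_per_group = 150L),
    de = list(lfc_min = 0.3, q_max = 0.1, top_n = 1000L),
    motif = list(p_adj_max = 0.05, half_width = 500L, n_negative = 1000L,
                 w_grid = c(50, 100, 150, 250), bin_width = 50L),
    peaks = list(p_adj_max = 0.01, half_width = 10000L, n_negative = 1000L,
                 resamples = 999L, bin_width = 500L,
                 negative_mode = "genome_random"),
    cilia = list(t1 = 1.05, t2 = 1.5, loop_radius = 0.2),
    log_level = "info"), class = "RunConfig")
}

#' Read a run configuration from YAML, merged over the defaults
#'
#' @param path YAML file; keys mirror [defaultRunConfig()].
#' @param seed,outdir Optional overrides (e.g. from CLI flags; flags win).
#' @return A `"RunConfig"` list.
#' @export
readRunConfig <- function(path = NULL, seed = NULL, outdir = NULL) {
  cfg <- defaultRunConfig()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(outdir)) cfg$outdir <- outdir
  class(cfg) <- "RunConfig"
  cfg
}

.log <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message("[mitoCilia] ", ...)
}

#' Validate declared pipeline inputs
#'
#' Schema/format checks for externally supplied input files named in
#' `config$inputs` (any of `de_table`, `peaks_bed`, `tss_tsv`,
#' `promoters_fasta`, `traces_csv`), plus chromosome-name consistency
#' between the TSS annotation, the peak file and the genome FASTA when
#' several are present. Never raises on content problems: every failure
#' becomes one row of the report.
#'
#' @param config A `"RunConfig"` list with an `inputs` element.
#' @return `data.frame` with columns `input`, `check`, `message`
#'   (zero rows = all checks passed).
#' @export
validateInputs <- function(config) {
  fails <- list()
  add <- function(input, check, msg)
    fails[[length(fails) + 1L]] <<- data.frame(
      input = input, check = check, message = msg,
      stringsAsFactors = FALSE)
  ins <- config$inputs
  chrom_sets <- list()
  for (nm in names(ins)) {
    p <- ins[[nm]]
    if (!file.exists(p)) { add(nm, "exists", paste("missing file:", p));
      next }
    if (nm == "peaks_bed") {
      lines <- readLines(p)
      lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
      fld <- strsplit(lines, "\t")
      for (i in seq_along(fld)) {
        if (length(fld[[i]]) < 3) {
          add(nm, "bed_fields", sprintf("line %d: fewer than 3 fields", i))
        } else {
          st <- suppressWarnings(as.numeric(fld[[i]][2]))
          en <- suppressWarnings(as.numeric(fld[[i]][3]))
          if (is.na(st) || is.na(en))
            add(nm, "bed_numeric", sprintf("line %d: non-numeric bounds", i))
          else if (st >= en)
            add(nm, "bed_interval",
                sprintf("line %d: start >= end (%s >= %s)", i, st, en))
        }
      }
      chrom_sets[[nm]] <- unique(vapply(fld, `[`, "", 1L))
    } else if (nm == "tss_tsv") {
      ok <- tryCatch({ tss <- readTssTsv(p); TRUE },
                     error = function(e) { add(nm, "schema",
                                               conditionMessage(e)); FALSE })
      if (ok) chrom_sets[[nm]] <- unique(as.character(seqnames(tss)))
    } else if (nm == "de_table") {
      tryCatch(readDifferentialTable(p),
               error = function(e) add(nm, "schema", conditionMessage(e)))
    } else if (nm == "promoters_fasta") {
      tryCatch(readPromoterFasta(p),
               error = function(e) add(nm, "fasta", conditionMessage(e)))
    } else if (nm == "traces_csv") {
      tryCatch(readCiliaTraces(p),
               error = function(e) add(nm, "schema", conditionMessage(e)))
    } else if (nm == "genome_fasta") {
      ok <- tryCatch({ gs <- readPromoterFasta(p); TRUE },
                     error = function(e) { add(nm, "fasta",
                                               conditionMessage(e)); FALSE })
      if (ok) chrom_sets[[nm]] <- names(gs)
    }
  }
  if (length(chrom_sets) >= 2) {
    common <- Reduce(intersect, chrom_sets)
    for (nm in names(chrom_sets)) {
      extra <- setdiff(chrom_sets[[nm]], common)
      if (length(extra))
        add(nm, "chrom_consistency",
            paste0("chromosome names not shared by all inputs: ",
                   paste(utils::head(extra, 5), collapse = ", ")))
    }
  }
  if (length(fails)) do.call(rbind, fails) else
    data.frame(input = character(), check = character(),
               message = character())
}

#' Run the full synthetic-to-report pipeline
#'
#' Executes the stages in dependency order (simulate, then DE program
#' scoring, motif enrichment, peak enrichment, cilia morphometry) and
#' writes every intermediate and result file under `config$outdir`,
#' finishing with a machine-readable JSON run report carrying the
#' parameter echo, per-stage outputs, file checksums, package version and
#' seed. Identical config and seed give identical outputs.
#'
#' @param config A `"RunConfig"` (see [defaultRunConfig()]).
#' @return The run report, invisibly (a list; also written as
#'   `report.json`).
#' @export
runPipeline <- function(config = defaultRunConfig()) {
  cfg <- config
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed
  outputs <- list(); results <- list(); warns <- character()
  out <- function(f) file.path(cfg$outdir, f)

  ## --- simulate -----------------------------------------------------
  .log(cfg, "simulate: genome, DE table, promoters, peaks, cilia")
  sim <- cfg$simulate
  genome <- makeGenome(sim$n_genes, sim$n_chroms, sim$chrom_len,
                       seed = seed)
  ids <- geneIds(genome)
  ncat <- sim$catalog
  cat_ids <- ids[seq_len(ncat$motile + ncat$primary + ncat$pan)]
  catalog <- GeneCatalog(
    cat_ids,
    rep(c("motile-specific", "primary-specific", "pan-ciliary"),
        times = c(ncat$motile, ncat$primary, ncat$pan)),
    name = "synthetic_ciliary",
    source = "mitoCilia synthetic generator",
    category_levels = c("motile-specific", "primary-specific",
                        "pan-ciliary"))
  de <- makeDifferentialTable(genome, catalog,
                              planted_fraction = sim$planted_fraction,
                              effect_mean = sim$effect_mean,
                              effect_sd = sim$effect_sd, seed = seed + 1L)
  planted <- attr(deRecords(de), "planted")
  pwm <- rfxLikePwm()
  promo_planted <- makePromoters(genome, pwm, genes = planted,
                                 plant_fraction = 1,
                                 offset_sd = sim$promoter_offset_sd,
                                 seed = seed + 2L)
  promo_bg <- makePromoters(genome, pwm,
                            genes = setdiff(ids, planted),
                            plant_fraction = 0, seed = seed + 3L)
  promoters <- c(promo_planted$sequences, promo_bg$sequences)
  peaks <- makePeaks(genome, target_genes = planted,
                     background_density = sim$peak_background_density,
                     excess_rate = sim$peak_excess_rate,
                     offset_sd = sim$peak_offset_sd, seed = seed + 4L)
  traces <- makeCilia(sim$n_cilia_per_group, sim$cilia, seed = seed + 5L)
  writeTssTsv(genome, out("tss.tsv"))
  writeTssGff3(genome, out("tss.gff3"))
  writeCatalogTsv(catalog, out("catalog.tsv"))
  writeDifferentialTable(de, out("de_table.tsv"))
  writePromoterFasta(promoters, out("promoters.fasta"))
  writePeaksBed(peaks, out("peaks.bed"))
  writeCiliaTraces(traces, out("cilia_traces.csv"))
  writeMemeMotif(pwm, out("motif.meme"))
  outputs$simulate <- c("tss.tsv", "tss.gff3", "catalog.tsv",
                        "de_table.tsv", "promoters.fasta", "peaks.bed",
                        "cilia_traces.csv", "motif.meme")

  ## --- de_programs --------------------------------------------------
  .log(cfg, "de_programs: gene lists and catalog scores")
  pol <- thresholdPolicy(lfc_min = cfg$de$lfc_min, q_max = cfg$de$q_max,
                         top_n = cfg$de$top_n)
  lists <- buildGeneLists(de, pol)
  score <- scoreCatalog(lists, de, catalog, pol)
  de_null <- makeDifferentialTable(genome, catalog, planted_fraction = 0,
                                   seed = seed + 6L)
  xmat <- crossDatasetMatrix(list(stressed = de, unstressed = de_null),
                             catalog, q_max = cfg$de$q_max,
                             lfc_min = cfg$de$lfc_min)
  writeLines(lists$up, out("genes_up.txt"))
  writeLines(lists$down, out("genes_down.txt"))
  utils::write.table(score, out("catalog_score.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(xmat, out("cross_dataset_matrix.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  outputs$de_programs <- c("genes_up.txt", "genes_down.txt",
                           "catalog_score.tsv",
                           "cross_dataset_matrix.tsv")
  results$de_programs <- list(
    n_up = length(lists$up), n_down = length(lists$down),
    catalog_overall = as.list(score[score$category == "overall", -1]))

  ## --- motif --------------------------------------------------------
  .log(cfg, "motif: promoter scan and central enrichment")
  mpol <- thresholdPolicy(lfc_min = cfg$de$lfc_min, q_max = NULL,
                          p_adj_max = cfg$motif$p_adj_max)
  mlists <- buildGeneLists(de, mpol)
  neg_genes <- sampleNegativeGenes("genome_random", genome,
                                   n = cfg$motif$n_negative,
                                   exclude = mlists$up, seed = seed + 7L)
  target_hits <- scanPwm(promoters[mlists$up], pwm,
                         half_width = cfg$motif$half_width)
  neg_hits <- scanPwm(promoters[neg_genes], pwm,
                      half_width = cfg$motif$half_width)
  enr <- centralEnrichment(target_hits, neg_hits,
                           w_grid = cfg$motif$w_grid,
                           motif_id = motifId(pwm))
  curve <- motifProbabilityCurve(target_hits,
                                 bin_width = cfg$motif$bin_width,
                                 half_width = cfg$motif$half_width)
  utils::write.table(bestHits(target_hits), out("motif_hits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(enr, out("central_enrichment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(curve, out("motif_probability_curve.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  outputs$motif <- c("motif_hits.tsv", "central_enrichment.tsv",
                     "motif_probability_curve.tsv")
  results$motif <- as.list(enr)

  ## --- peaks --------------------------------------------------------
  .log(cfg, "peaks: TSS-proximal positional enrichment")
  ppol <- thresholdPolicy(lfc_min = cfg$de$lfc_min, q_max = NULL,
                          p_adj_max = cfg$peaks$p_adj_max)
  plists <- buildGeneLists(de, ppol)
  pool <- if (cfg$peaks$negative_mode == "expressed_unchanged")
    sampleNegativeGenes("expressed_unchanged", table = de,
                        n = cfg$peaks$n_negative, exclude = plists$up,
                        seed = seed + 8L)
  else
    sampleNegativeGenes("genome_random", genome,
                        n = cfg$peaks$n_negative, exclude = plists$up,
                        seed = seed + 8L)
  pe <- positionalEnrichmentTest(plists$up, pool, peaks, genome,
                                 B = cfg$peaks$resamples,
                                 seed = seed + 9L,
                                 half_width = cfg$peaks$half_width)
  tssr <- tssRanges(genome)
  d_target <- signedDistances(tssr[tssr$gene_id %in% plists$up], peaks,
                              half_width = cfg$peaks$half_width)
  d_neg <- signedDistances(tssr[tssr$gene_id %in% pool], peaks,
                           half_width = cfg$peaks$half_width)
  prof_t <- distanceProfile(d_target, cfg$peaks$bin_width,
                            cfg$peaks$half_width, label = "upregulated")
  prof_n <- distanceProfile(d_neg, cfg$peaks$bin_width,
                            cfg$peaks$half_width,
                            label = cfg$peaks$negative_mode)
  utils::write.table(prof_t, out("distance_profile_target.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(prof_n, out("distance_profile_negative.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(pe), out("peak_enrichment.json"),
                       auto_unbox = TRUE, digits = NA)
  outputs$peaks <- c("distance_profile_target.tsv",
                     "distance_profile_negative.tsv",
                     "peak_enrichment.json")
  results$peaks <- unclass(pe)

  ## --- cilia --------------------------------------------------------
  .log(cfg, "cilia: morphometry and group comparison")
  meas <- measureCilia(traces)
  meas <- classifyMorphology(meas, t1 = cfg$cilia$t1, t2 = cfg$cilia$t2,
                             loop_radius = cfg$cilia$loop_radius)
  cmp <- compareCiliaGroups(meas)
  utils::write.csv(meas, out("cilia_measures.csv"), row.names = FALSE)
  cmp_out <- list(ks = cmp$ks, anova_cilium = cmp$anova_cilium,
                  anova_mouse = cmp$anova_mouse,
                  n_per_group = as.list(cmp$n_per_group),
                  class_proportions = if (!is.null(cmp$class_proportions))
                    as.data.frame.matrix(cmp$class_proportions) else NULL)
  jsonlite::write_json(cmp_out, out("cilia_comparison.json"),
                       auto_unbox = TRUE, digits = NA)
  outputs$cilia <- c("cilia_measures.csv", "cilia_comparison.json")
  results$cilia <- cmp_out

  ## --- report -------------------------------------------------------
  files <- unlist(outputs, use.names = FALSE)
  sums <- tools::md5sum(file.path(cfg$outdir, files))
  report <- list(
    package = "mitoCilia",
    version = as.character(utils::packageVersion("mitoCilia")),
    seed = seed,
    config = unclass(cfg),
    outputs = outputs,
    checksums = as.list(stats::setNames(unname(sums), files)),
    results = results,
    warnings = warns)
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  .log(cfg, "done: report at ", out("report.json"))
  invisible(report)
}
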