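#' Generate a synthetic differential-expression table with planted signal
#'
#' Emulates a bulk case/control DE result: every gene in the genome gets a
#' log2 fold change and a p-value; a configurable fraction of catalog genes
#' is "planted" as truly up-regulated (effect drawn from a normal
#' distribution, p-value from a Beta(a, 1) with a << 1 so planted genes are
#' strongly significant), all other genes are null (effect around zero,
#' p ~ Uniform(0, 1)). q-values are Benjamini-Hochberg-adjusted p-values
#' computed over the whole table.
#'
#' @param genome A [GenomeModel-class].
#' @param catalog A [GeneCatalog-class]; catalog genes must be a subset of
#'   the genome's genes.
#' @param planted_fraction Fraction of catalog genes forced up-regulated
#'   (in `[0, 1]`).
#' @param effect_mean,effect_sd Mean/sd of the planted log2 fold change
#'   (defaults 2 and 0.5).
#' @param null_sd Sd of null log2 fold changes around 0 (default 0.15).
#' @param planted_beta_a Beta(a, 1) shape for planted p-values
#'   (default 0.001; smaller = stronger significance).
#' @param seed Integer seed.
#' @return A [DifferentialTable-class] (modality `"rna"`); the planted gene
#'   ids are recorded in `attr(deRecords(x), "planted")` and the seed in
#'   `attr(deRecords(x), "seed")`.
#' @export
makeDifferentialTable <- function(genome, catalog, planted_fraction = 0.6,
                                  effect_mean = 2, effect_sd = 0.5,
                                  null_sd = 0.15, planted_beta_a = 0.001,
                                  seed = 1L) {
  stopifnot(is(genome, "GenomeModel"), is(catalog, "GeneCatalog"))
  if (planted_fraction < 0 || planted_fraction > 1)
    stop("planted_fraction must be in [0, 1]")
  ids <- geneIds(genome)
  cat_ids <- geneIds(catalog)
  if (!all(cat_ids %in% ids))
    stop("catalog genes must be a subset of genome genes")
  if (length(cat_ids) == 0L && planted_fraction > 0)
    stop("cannot plant signal into an empty catalog")
  set.seed(as.integer(seed))
  n <- length(ids)
  n_plant <- round(planted_fraction * length(cat_ids))
  planted <- if (n_plant > 0) sample(cat_ids, n_plant) else character()
  is_planted <- ids %in% planted
  log2fc <- stats::rnorm(n, 0, null_sd)
  log2fc[is_planted] <- stats::rnorm(sum(is_planted), effect_mean, effect_sd)
  pvalue <- stats::runif(n)
  if (any(is_planted))
    pvalue[is_planted] <- stats::rbeta(sum(is_planted), planted_beta_a, 1)
  qvalue <- stats::p.adjust(pvalue, method = "BH")
  mean_expression <- exp(stats::rnorm(n, 3, 1))
  rec <- data.frame(feature_id = ids, log2fc = log2fc, pvalue = pvalue,
                    qvalue = qvalue, mean_expression = mean_expression,
                    stringsAsFactors = FALSE)
  attr(rec, "planted") <- sort(planted)
  attr(rec, "seed") <- as.integer(seed)
  new("DifferentialTable", records = rec, modality = "rna")
}
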