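#' Generate a synthetic ChIP-seq peak set with planted TSS-proximal excess
#'
#' Background peaks are placed uniformly along every chromosome at
#' `background_density` peaks per bp. On top of that, each target gene
#' receives `rpois(1, excess_rate)` extra peaks whose *centers* sit at
#' signed TSS-relative offsets drawn Normal(0, `offset_sd`) in gene
#' orientation (negative = upstream). This is the planted signal the
#' TSS-proximal positional-enrichment test is expected to recover.
#'
#' @param genome A [GenomeModel-class].
#' @param target_genes Gene ids receiving excess peaks (subset of genome
#'   genes); may be empty.
#' @param background_density Background peaks per bp (e.g. 5e-5 = one peak
#'   per 20 kb). Must be >= 0.
#' @param excess_rate Mean number of extra peaks per target gene (>= 0).
#' @param offset_sd Sd (bp) of planted peak-center offsets from the TSS
#'   (default 2000).
#' @param peak_width Width of every peak in bp (default 200).
#' @param tf_label TF name stored on each peak (default "RFX").
#' @param seed Integer seed.
#' @return A sorted [GenomicRanges::GRanges] with metadata columns `name`
#'   and `tf`; coordinates 1-based (use [writePeaksBed()] for 0-based
#'   half-open BED output).
#' @export
makePeaks <- function(genome, target_genes = character(),
                      background_density = 5e-5, excess_rate = 2,
                      offset_sd = 2000, peak_width = 200L,
                      tf_label = "RFX", seed = 1L) {
  stopifnot(is(genome, "GenomeModel"))
  if (background_density < 0) stop("background_density must be >= 0")
  if (excess_rate < 0) stop("excess_rate must be >= 0")
  if (!all(target_genes %in% geneIds(genome)))
    stop("target_genes must be a subset of genome genes")
  tss <- tssRanges(genome)
  sl <- seqlengths(tss)
  set.seed(as.integer(seed))
  centers <- numeric(); chrom <- character()
  for (ch in names(sl)) {
    k <- stats::rpois(1, background_density * sl[[ch]])
    if (k > 0) {
      centers <- c(centers, floor(stats::runif(k, 1, sl[[ch]])))
      chrom <- c(chrom, rep(ch, k))
    }
  }
  if (length(target_genes)) {
    tgt <- tss[tss$gene_id %in% target_genes]
    for (i in seq_along(tgt)) {
      k <- stats::rpois(1, excess_rate)
      if (k == 0) next
      off <- round(stats::rnorm(k, 0, offset_sd))
      sgn <- if (as.character(strand(tgt)[i]) == "+") 1 else -1
      ctr <- start(tgt)[i] + sgn * off
      ch <- as.character(seqnames(tgt)[i])
      keep <- ctr > peak_width & ctr < sl[[ch]] - peak_width
      centers <- c(centers, ctr[keep])
      chrom <- c(chrom, rep(ch, sum(keep)))
    }
  }
  if (!length(centers)) {
    gr <- GRanges(seqinfo = Seqinfo(names(sl), unname(sl)))
    gr$name <- character(0); gr$tf <- character(0)
    return(gr)
  }
  half <- floor(peak_width / 2)
  st <- pmax(1, pmin(centers - half, sl[chrom] - peak_width + 1))
  gr <- GRanges(chrom, IRanges(start = st, width = peak_width),
                seqinfo = Seqinfo(names(sl), unname(sl)))
  gr <- BiocGenerics::sort(gr)
  gr$name <- sprintf("peak%06d", seq_along(gr))
  gr$tf <- tf_label
  S4Vectors::metadata(gr)$seed <- as.integer(seed)
  gr
}
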