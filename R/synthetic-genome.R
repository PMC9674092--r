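#' Generate a synthetic genome model
#'
#' Places `n_genes` oriented TSSs on `n_chroms` chromosomes of length
#' `chrom_len`, keeping a margin of `margin` bp from chromosome ends (so
#' every +/- 10 kb TSS window fits) and at least `min_spacing` bp between
#' neighbouring TSSs (so +/- 500 bp promoter windows never overlap).
#' Strands are assigned independently with probability 1/2 each.
#'
#' @param n_genes Number of genes (>= 1).
#' @param n_chroms Number of chromosomes; genes are distributed as evenly as
#'   possible.
#' @param chrom_len Chromosome length in bp (all chromosomes equal).
#' @param seed Integer seed; the same call with the same seed is
#'   byte-identical.
#' @param margin Distance (bp) every TSS keeps from chromosome ends
#'   (default 10000).
#' @param min_spacing Minimum TSS-to-TSS distance in bp (default 1500).
#' @return A [GenomeModel-class].
#' @examples
#' gm <- makeGenome(10, 1, 1e6, seed = 1)
#' length(gm)
#' @export
makeGenome <- function(n_genes, n_chroms = 1L, chrom_len = 1e6, seed = 1L,
                       margin = 10000L, min_spacing = 1500L) {
  n_genes <- as.integer(n_genes)
  n_chroms <- as.integer(n_chroms)
  chrom_len <- as.numeric(chrom_len)
  if (n_genes < 1L) stop("n_genes must be >= 1")
  per_chrom <- rep(n_genes %/% n_chroms, n_chroms)
  if (n_genes %% n_chroms > 0)
    per_chrom[seq_len(n_genes %% n_chroms)] <-
      per_chrom[seq_len(n_genes %% n_chroms)] + 1L
  usable <- chrom_len - 2 * margin
  n_slots <- if (usable < 0) 0L else floor(usable / min_spacing) + 1L
  if (max(per_chrom) > n_slots)
    stop("infeasible packing: ", max(per_chrom), " genes need more than ",
         n_slots, " slots of ", min_spacing, " bp on a ", chrom_len,
         " bp chromosome with ", margin, " bp margins")
  chroms <- paste0("chr", seq_len(n_chroms))
  set.seed(as.integer(seed))
  pieces <- vector("list", n_chroms)
  for (i in seq_len(n_chroms)) {
    k <- per_chrom[i]
    if (k == 0L) next
    slots <- sort(sample.int(n_slots, k))
    # slot anchor + jitter that cannot collide with the next slot
    jit <- floor(stats::runif(k) * (min_spacing / 2))
    pos <- (margin + 1) + (slots - 1L) * min_spacing + jit
    pos <- pmin(pos, chrom_len - margin)
    pieces[[i]] <- data.frame(chrom = chroms[i], pos = pos)
  }
  df <- do.call(rbind, pieces)
  strand <- sample(c("+", "-"), nrow(df), replace = TRUE)
  gene_id <- sprintf("gene%05d", seq_len(nrow(df)))
  si <- Seqinfo(seqnames = chroms, seqlengths = rep(chrom_len, n_chroms))
  gr <- GRanges(df$chrom, IRanges(start = df$pos, width = 1L),
                strand = strand, gene_id = gene_id, seqinfo = si)
  new("GenomeModel", tss = gr, seed = as.integer(seed))
}
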