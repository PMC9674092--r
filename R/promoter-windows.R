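#' Extract TSS-centered promoter windows from genome sequence
#'
#' For every gene the genomic interval `[tss - half_width, tss + half_width)`
#' (0-based half-open; identical for both strands) is extracted from the
#' genome FASTA; minus-strand windows are reverse-complemented so that all
#' returned sequences read in gene orientation with upstream sequence first.
#' Windows running off a chromosome end are clipped and flagged. Note the
#' discrete asymmetry of an even-length window: plus-strand windows cover
#' TSS-relative offsets `-half_width .. half_width - 1`, reverse-complemented
#' minus-strand windows cover `-(half_width - 1) .. half_width`.
#'
#' @param tss Width-1 [GenomicRanges::GRanges] with `gene_id` and strand
#'   (e.g. [tssRanges()] of a [GenomeModel-class], or [selectTss()] output).
#' @param genome_seq Named [Biostrings::DNAStringSet] of chromosome
#'   sequences.
#' @param half_width Half window size in bp (default 500).
#' @return A list: `sequences` (named `DNAStringSet`, gene orientation) and
#'   `windows` (a `GRanges` of the genomic intervals with `gene_id` and
#'   `clipped` columns).
#' @export
extractPromoterWindows <- function(tss, genome_seq, half_width = 500L) {
  if (is(tss, "GenomeModel")) tss <- tssRanges(tss)
  stopifnot(is(tss, "GRanges"), all(GenomicRanges::width(tss) == 1L))
  if (is.null(tss$gene_id)) stop("tss must carry a gene_id column")
  chroms <- as.character(seqnames(tss))
  missing_chr <- setdiff(unique(chroms), names(genome_seq))
  if (length(missing_chr))
    stop("chromosome(s) missing from genome sequence: ",
         paste(missing_chr, collapse = ", "))
  sl <- stats::setNames(Biostrings::width(genome_seq), names(genome_seq))
  # 1-based window [tss - hw, tss + hw - 1] == 0-based [tss0-hw, tss0+hw)
  want_start <- start(tss) - half_width
  want_end <- start(tss) + half_width - 1L
  st <- pmax(1L, want_start)
  en <- pmin(sl[chroms], want_end)
  clipped <- st != want_start | en != want_end
  win <- GRanges(chroms, IRanges(st, en), strand = strand(tss),
                 gene_id = tss$gene_id, clipped = clipped)
  seqs <- Biostrings::DNAStringSet(lapply(seq_along(win), function(i)
    Biostrings::subseq(genome_seq[[chroms[i]]], st[i], en[i])))
  minus <- as.character(strand(tss)) == "-"
  if (any(minus))
    seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
  names(seqs) <- tss$gene_id
  list(sequences = seqs, windows = win)
}
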