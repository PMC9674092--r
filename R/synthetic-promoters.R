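#' Generate synthetic promoter windows with optionally planted motifs
#'
#' Produces one TSS-centered window per requested gene: background bases
#' drawn i.i.d. from `background`, and (for planted genes) the PWM consensus
#' inserted on a random strand so that the motif *center* sits at a drawn
#' TSS-relative offset. Offsets are drawn Normal(offset_mean, offset_sd) and
#' redrawn until the whole motif fits inside the window, so the returned true
#' offsets are exact. The motif center is `floor(width/2)` bases from the
#' motif start (same convention as [scanPwm()]).
#'
#' Window coordinates are TSS-oriented: sequence position `i` (1-based)
#' corresponds to TSS-relative offset `i - half_width - 1`, i.e. offsets
#' `-half_width .. half_width - 1`.
#'
#' @param genome A [GenomeModel-class].
#' @param pwm A [PositionWeightMatrix-class]; its consensus is planted.
#' @param genes Gene ids to generate windows for (default: all).
#' @param half_width Half window width in bp (default 500).
#' @param plant_fraction Fraction of `genes` that receive a planted motif
#'   (default 1; use 0 for a pure-background negative set).
#' @param offset_mean,offset_sd Mean/sd (bp) of the planted center offset
#'   relative to the TSS (defaults 0 and 50).
#' @param background Named A/C/G/T frequencies (default uniform).
#' @param seed Integer seed.
#' @return A list with elements `sequences` (a named
#'   [Biostrings::DNAStringSet]), `offsets` (named numeric, NA where no motif
#'   was planted), `strands` (named character, NA where unplanted) and
#'   `seed`.
#' @export
makePromoters <- function(genome, pwm, genes = NULL, half_width = 500L,
                          plant_fraction = 1, offset_mean = 0,
                          offset_sd = 50, background = c(A = 0.25, C = 0.25,
                                                         G = 0.25, T = 0.25),
                          seed = 1L) {
  stopifnot(is(genome, "GenomeModel"), is(pwm, "PositionWeightMatrix"))
  if (is.null(genes)) genes <- geneIds(genome)
  if (!all(genes %in% geneIds(genome)))
    stop("unknown gene ids requested")
  w <- motifWidth(pwm)
  L <- 2L * as.integer(half_width)
  if (w > L) stop("motif wider than promoter window")
  background <- background[c("A", "C", "G", "T")] /
    sum(background[c("A", "C", "G", "T")])
  bases <- c("A", "C", "G", "T")
  set.seed(as.integer(seed))
  n <- length(genes)
  mat <- matrix(sample(bases, n * L, replace = TRUE, prob = background),
                nrow = n)
  n_plant <- round(plant_fraction * n)
  planted_idx <- if (n_plant > 0) sort(sample.int(n, n_plant)) else integer()
  offsets <- rep(NA_real_, n)
  strands <- rep(NA_character_, n)
  consensus <- strsplit(consensusSeq(pwm), "")[[1]]
  center_shift <- floor(w / 2)           # motif start -> motif center
  lo_start <- 1L
  hi_start <- L - w + 1L
  for (i in planted_idx) {
    repeat {
      off <- round(stats::rnorm(1, offset_mean, offset_sd))
      st <- off + half_width + 1L - center_shift
      if (st >= lo_start && st <= hi_start && abs(off) <= half_width) break
    }
    sgn <- sample(c("+", "-"), 1L)
    ins <- if (sgn == "+") consensus else rev(c(A = "T", C = "G", G = "C",
                                                T = "A")[consensus])
    mat[i, st:(st + w - 1L)] <- ins
    offsets[i] <- off
    strands[i] <- sgn
  }
  seqs <- Biostrings::DNAStringSet(apply(mat, 1, paste, collapse = ""))
  names(seqs) <- genes
  names(offsets) <- genes
  names(strands) <- genes
  list(sequences = seqs, offsets = offsets, strands = strands,
       seed = as.integer(seed))
}
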