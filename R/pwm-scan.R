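#' @useDynLib mitoCilia, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# A=0, C=1, G=2, T=3, anything else -1 (scored as background)
.dna_code_lut <- local({
  lut <- rep(-1L, 128L)
  lut[utf8ToInt("A") + 1L] <- 0L; lut[utf8ToInt("a") + 1L] <- 0L
  lut[utf8ToInt("C") + 1L] <- 1L; lut[utf8ToInt("c") + 1L] <- 1L
  lut[utf8ToInt("G") + 1L] <- 2L; lut[utf8ToInt("g") + 1L] <- 2L
  lut[utf8ToInt("T") + 1L] <- 3L; lut[utf8ToInt("t") + 1L] <- 3L
  lut
})

.encodeDNA <- function(s) .dna_code_lut[utf8ToInt(s) + 1L]

#' Maximum attainable log2-odds score of a PWM
#' @param pwm A [PositionWeightMatrix-class].
#' @return Numeric scalar (bits).
#' @export
maxPwmScore <- function(pwm) {
  sum(apply(logOddsMatrix(pwm), 2, max))
}

#' Scan promoter windows with a PWM on both strands
#'
#' Scores every position of every window as the sum of per-position
#' log2(p/background) terms (ambiguous bases contribute 0) and reports all
#' positions at or above `score_threshold` on either strand. Offsets are
#' TSS-relative motif-center positions: window position `i` (1-based) has
#' offset `i - half_width - 1`, and the motif center is `floor(width/2)`
#' bases downstream of the hit start in window coordinates (both strands,
#' so a hit's reported center does not depend on its strand).
#'
#' @param windows A named [Biostrings::DNAStringSet] (names = gene ids) of
#'   equal-length TSS-centered windows, or a named character vector.
#' @param pwm A [PositionWeightMatrix-class].
#' @param score_threshold Minimum score in bits; default 80% of
#'   [maxPwmScore()].
#' @param half_width Window half-width; default `width/2` of the first
#'   window.
#' @return `data.frame` with columns `gene_id`, `offset`, `strand`,
#'   `score`. Attribute `"n_genes"` records how many windows were scanned
#'   (genes may have zero hits).
#' @export
scanPwm <- function(windows, pwm, score_threshold = NULL,
                    half_width = NULL) {
  stopifnot(is(pwm, "PositionWeightMatrix"))
  seqs <- as.character(windows)
  if (is.null(names(seqs)))
    names(seqs) <- paste0("seq", seq_along(seqs))
  w <- motifWidth(pwm)
  if (is.null(score_threshold))
    score_threshold <- 0.8 * maxPwmScore(pwm)
  if (is.null(half_width)) half_width <- nchar(seqs[1]) %/% 2L
  lut_fwd <- logOddsMatrix(pwm)
  # reverse complement of the motif: scan the forward sequence with the
  # reversed, complemented score matrix
  lut_rev <- lut_fwd[4:1, w:1, drop = FALSE]
  ctr <- floor(w / 2)
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    codes <- .encodeDNA(seqs[[i]])
    if (length(codes) < w) next
    sf <- pwm_scan_scores(codes, lut_fwd)
    sr <- pwm_scan_scores(codes, lut_rev)
    hf <- which(sf >= score_threshold)
    hr <- which(sr >= score_threshold)
    if (!length(hf) && !length(hr)) next
    starts <- c(hf, hr)
    out[[i]] <- data.frame(
      gene_id = names(seqs)[i],
      offset = (starts + ctr) - half_width - 1L,
      strand = rep(c("+", "-"), c(length(hf), length(hr))),
      score = c(sf[hf], sr[hr]),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(gene_id = character(), offset = integer(),
                      strand = character(), score = numeric())
  rownames(res) <- NULL
  attr(res, "n_genes") <- length(seqs)
  attr(res, "score_threshold") <- score_threshold
  res
}

#' Best hit per gene
#'
#' Keeps, for each gene with at least one hit, the highest-scoring hit
#' (ties broken by smaller |offset|, then smaller offset, then + strand).
#'
#' @param hits Output of [scanPwm()].
#' @return Subset of `hits`, one row per gene; attributes preserved.
#' @export
bestHits <- function(hits) {
  if (!nrow(hits)) return(hits)
  ord <- order(hits$gene_id, -hits$score, abs(hits$offset), hits$offset,
               hits$strand)
  h <- hits[ord, ]
  h <- h[!duplicated(h$gene_id), ]
  rownames(h) <- NULL
  attr(h, "n_genes") <- attr(hits, "n_genes")
  h
}
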