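#' Read motifs in JASPAR PFM format
#'
#' Accepts the JASPAR position-frequency-matrix flavours: a `>`-header line
#' per motif followed by four base rows, with or without `A [ ... ]`
#' bracketed syntax, or four bare count rows in A/C/G/T order.
#'
#' @param path Path to a PFM file (one or more motifs).
#' @param pseudocount,background Passed to [PositionWeightMatrix()].
#' @return A named list of [PositionWeightMatrix-class] objects.
#' @export
readJasparPfm <- function(path, pseudocount = 0.01,
                          background = c(A = 0.25, C = 0.25,
                                         G = 0.25, T = 0.25)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (!length(hdr)) hdr <- 0L  # headerless single matrix
  out <- list()
  bounds <- c(hdr, length(lines) + 1L)
  for (i in seq_along(hdr)) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    id <- if (hdr[1] > 0) sub("^>\\s*", "", lines[hdr[i]]) else "motif"
    id <- strsplit(id, "\\s+")[[1]]
    id <- id[length(id)]  # prefer the motif name over the accession
    rows <- lapply(block[1:4], function(l) {
      l <- gsub("^[ACGTacgt]", "", l)
      l <- gsub("[][]", " ", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    if (length(unique(lengths(rows))) != 1)
      stop("malformed PFM block for motif '", id, "'")
    out[[id]] <- PositionWeightMatrix(do.call(rbind, rows), motif_id = id,
                                      pseudocount = pseudocount,
                                      background = background)
  }
  out
}

#' Read motifs in MEME minimal format
#'
#' Parses `MOTIF` blocks with their `letter-probability matrix` sections;
#' if the file declares background letter frequencies they become the PWM
#' background (unless overridden).
#'
#' @param path Path to a MEME minimal-format motif file.
#' @param pseudocount Per-cell pseudocount (default 0.01).
#' @param background Optional named A/C/G/T background; default: the
#'   file's declared frequencies, else uniform.
#' @return A named list of [PositionWeightMatrix-class] objects.
#' @export
readMemeMotifs <- function(path, pseudocount = 0.01, background = NULL) {
  lines <- readLines(path)
  if (is.null(background)) {
    bgl <- grep("^Background letter frequencies", lines)
    if (length(bgl) && bgl[1] < length(lines)) {
      tok <- strsplit(trimws(lines[bgl[1] + 1L]), "\\s+")[[1]]
      vals <- as.numeric(tok[seq(2, length(tok), 2)])
      names(vals) <- tok[seq(1, length(tok), 2)]
      background <- vals[c("A", "C", "G", "T")]
    } else background <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  }
  starts <- grep("^MOTIF\\b", lines)
  out <- list()
  for (s in starts) {
    id <- strsplit(trimws(sub("^MOTIF", "", lines[s])), "\\s+")[[1]][1]
    m <- grep("^letter-probability matrix", lines[s:length(lines)])[1] + s - 1L
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[m]))
    rows <- lines[(m + 1L):(m + w)]
    probs <- t(vapply(rows, function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:4]),
      numeric(4), USE.NAMES = FALSE))
    out[[id]] <- PositionWeightMatrix(t(probs), motif_id = id,
                                      pseudocount = pseudocount,
                                      background = background)
  }
  out
}

#' Write a PWM in MEME minimal format
#' @param pwm A [PositionWeightMatrix-class].
#' @param path Output path.
#' @export
writeMemeMotif <- function(pwm, path) {
  p <- pwm@probs
  bg <- pwm@background
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.6f", names(bg), bg), collapse = " "),
               "",
               paste("MOTIF", motifId(pwm)),
               sprintf("letter-probability matrix: alength= 4 w= %d",
                       ncol(p))), con)
  writeLines(apply(p, 2, function(col)
    paste(sprintf("%.6f", col), collapse = " ")), con)
  invisible(path)
}
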