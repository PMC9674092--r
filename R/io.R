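#' Read/write ChIP-seq peak intervals as BED
#'
#' BED is 0-based half-open on disk; in memory peaks are 1-based
#' [GenomicRanges::GRanges] (rtracklayer does the conversion).
#'
#' @param path BED file path.
#' @return `readPeaksBed`: a `GRanges` sorted by position.
#' @export
readPeaksBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  BiocGenerics::sort(gr)
}

#' @rdname readPeaksBed
#' @param peaks A `GRanges` of peaks.
#' @export
writePeaksBed <- function(peaks, path) {
  rtracklayer::export(peaks, path, format = "BED")
  invisible(path)
}

#' Read/write TSS annotations as TSV
#'
#' Columns: `gene_id`, `chrom`, `position` (1-based TSS coordinate),
#' `strand`. A `# seed:` comment line records provenance when present.
#'
#' @param path TSV path.
#' @return `readTssTsv`: width-1 `GRanges` with `gene_id`.
#' @export
readTssTsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  req <- c("gene_id", "chrom", "position", "strand")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("TSS table missing columns: ", paste(miss, collapse = ", "))
  GRanges(df$chrom, IRanges(df$position, width = 1L), strand = df$strand,
          gene_id = df$gene_id)
}

#' @rdname readTssTsv
#' @param tss Width-1 `GRanges` with `gene_id` (or a [GenomeModel-class]).
#' @param seed Optional seed recorded as a header comment.
#' @export
writeTssTsv <- function(tss, path, seed = NULL) {
  if (is(tss, "GenomeModel")) {
    if (is.null(seed)) seed <- tss@seed
    tss <- tssRanges(tss)
  }
  df <- data.frame(gene_id = tss$gene_id,
                   chrom = as.character(seqnames(tss)),
                   position = start(tss),
                   strand = as.character(strand(tss)))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a TSS annotation as GFF3 gene features
#' @param tss Width-1 `GRanges` with `gene_id` (or a [GenomeModel-class]).
#' @param path Output path.
#' @export
writeTssGff3 <- function(tss, path) {
  if (is(tss, "GenomeModel")) tss <- tssRanges(tss)
  gr <- tss
  gr$type <- "gene"
  gr$ID <- gr$gene_id
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Read/write gene catalogs as TSV (columns gene_id, category)
#' @param path TSV path.
#' @param name,source Catalog name and provenance tag for the reader.
#' @return `readCatalogTsv`: a [GeneCatalog-class].
#' @export
readCatalogTsv <- function(path, name = basename(path), source = path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!all(c("gene_id", "category") %in% names(df)))
    stop("catalog must have columns gene_id and category")
  GeneCatalog(df$gene_id, df$category, name = name, source = source)
}

#' @rdname readCatalogTsv
#' @param catalog A [GeneCatalog-class].
#' @export
writeCatalogTsv <- function(catalog, path) {
  utils::write.table(catalogEntries(catalog), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write cilium trace tables (CSV)
#'
#' Schema: `cilium_id`, `mouse_id`, `genotype`, `point_index`, `x`, `y`,
#' `z`, `unit` — coordinates in um, one row per trace point. Files
#' without a declared unit column, or with mixed units, are rejected.
#'
#' @param path CSV path.
#' @return `readCiliaTraces`: the trace `data.frame`.
#' @export
readCiliaTraces <- function(path) {
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  req <- c("cilium_id", "mouse_id", "genotype", "point_index",
           "x", "y", "z", "unit")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("trace table missing columns: ", paste(miss, collapse = ", "))
  if (length(unique(df$unit)) != 1)
    stop("mixed units in trace table")
  if (!all(df$unit %in% c("um", "µm")))
    stop("unsupported unit '", unique(df$unit), "'; expected um")
  df
}

#' @rdname readCiliaTraces
#' @param traces Trace `data.frame` (see [makeCilia()]).
#' @param seed Optional seed recorded as a header comment.
#' @export
writeCiliaTraces <- function(traces, path, seed = attr(traces, "seed")) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  utils::write.csv(traces, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write promoter windows as FASTA
#' @param sequences Named [Biostrings::DNAStringSet].
#' @param path Output path.
#' @export
writePromoterFasta <- function(sequences, path) {
  Biostrings::writeXStringSet(sequences, path)
  invisible(path)
}

#' Read promoter windows from FASTA
#' @param path FASTA path.
#' @return Named [Biostrings::DNAStringSet].
#' @export
readPromoterFasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}
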