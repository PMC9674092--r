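#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges start end strand seqnames
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlengths seqlevels Seqinfo
NULL

#' GenomeModel: a minimal gene/TSS model of a genome
#'
#' Holds chromosome names and lengths together with one oriented
#' transcription start site (TSS) per gene. TSS coordinates are 1-based
#' (standard R/Bioconductor convention); converters to/from 0-based BED
#' coordinates live in the IO layer.
#'
#' @slot tss A [GenomicRanges::GRanges] of width-1 ranges, one per gene, with
#'   a `gene_id` metadata column, strand `+` or `-`, and seqinfo carrying
#'   chromosome lengths.
#' @slot seed Integer seed used to generate the model (NA for imported
#'   annotations).
#' @export
setClass("GenomeModel",
  slots = c(tss = "GRanges", seed = "integer"))

setValidity("GenomeModel", function(object) {
  gr <- object@tss
  msg <- character()
  if (is.null(gr$gene_id)) {
    msg <- c(msg, "tss must carry a 'gene_id' metadata column")
  } else if (anyDuplicated(gr$gene_id)) {
    msg <- c(msg, "gene ids must be unique")
  }
  if (length(gr)) {
    if (!all(as.character(strand(gr)) %in% c("+", "-")))
      msg <- c(msg, "strand must be '+' or '-' for every gene")
    sl <- seqlengths(gr)
    if (any(is.na(sl)))
      msg <- c(msg, "seqinfo must carry chromosome lengths")
    else {
      lim <- sl[as.character(seqnames(gr))]
      if (any(start(gr) < 1L) || any(end(gr) > lim))
        msg <- c(msg, "TSS positions must lie within chromosome bounds")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn GenomeModel Number of genes in the model.
#' @param x A `GenomeModel`.
#' @export
setMethod("length", "GenomeModel", function(x) length(x@tss))

#' Accessors for GenomeModel
#'
#' `tssRanges()` returns the oriented width-1 TSS ranges; `geneIds()` the
#' gene identifiers.
#'
#' @param object A [GenomeModel-class] object.
#' @return `tssRanges`: a `GRanges`; `geneIds`: a character vector.
#' @export
setGeneric("tssRanges", function(object) standardGeneric("tssRanges"))

#' @rdname tssRanges
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' @rdname tssRanges
#' @export
setMethod("tssRanges", "GenomeModel", function(object) object@tss)

#' @rdname tssRanges
#' @export
setMethod("geneIds", "GenomeModel", function(object)
  as.character(object@tss$gene_id))

setMethod("show", "GenomeModel", function(object) {
  sl <- seqlengths(object@tss)
  cat("GenomeModel with", length(object), "genes on",
      length(sl), "chromosome(s)\n")
  cat("  seqlengths:", paste0(names(sl), "=", sl, collapse = ", "), "\n")
  cat("  seed:", object@seed, "\n")
})

#' DifferentialTable: one case/control comparison's differential statistics
#'
#' Each row is one feature's effect size and significance: `feature_id`,
#' `log2fc`, `pvalue`, `qvalue` (Benjamini-Hochberg adjusted), and
#' `mean_expression` (scaled reads per base for RNA, abundance otherwise).
#'
#' @slot records A `data.frame` with the columns above, one row per feature.
#' @slot modality One of `"rna"`, `"protein"`, `"metabolite"`.
#' @export
setClass("DifferentialTable",
  slots = c(records = "data.frame", modality = "character"))

.de_required_cols <- c("feature_id", "log2fc", "pvalue", "qvalue",
                       "mean_expression")

setValidity("DifferentialTable", function(object) {
  df <- object@records
  msg <- character()
  miss <- setdiff(.de_required_cols, names(df))
  if (length(miss))
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (!object@modality %in% c("rna", "protein", "metabolite"))
    msg <- c(msg, "modality must be 'rna', 'protein' or 'metabolite'")
  if (anyDuplicated(df$feature_id))
    msg <- c(msg, "duplicate feature_id")
  num <- c("log2fc", "pvalue", "qvalue", "mean_expression")
  for (cl in num) if (!is.numeric(df[[cl]]))
    msg <- c(msg, paste0("column '", cl, "' must be numeric"))
  if (is.numeric(df$pvalue) &&
      any(df$pvalue < 0 | df$pvalue > 1, na.rm = TRUE))
    msg <- c(msg, "pvalue outside [0,1]")
  if (is.numeric(df$qvalue) &&
      any(df$qvalue < 0 | df$qvalue > 1, na.rm = TRUE))
    msg <- c(msg, "qvalue outside [0,1]")
  if (length(msg)) msg else TRUE
})

#' Construct a DifferentialTable
#'
#' @param records data.frame with columns `feature_id`, `log2fc`, `pvalue`,
#'   `qvalue`, `mean_expression`.
#' @param modality `"rna"`, `"protein"` or `"metabolite"`.
#' @return A validated [DifferentialTable-class].
#' @export
DifferentialTable <- function(records, modality = "rna") {
  records <- as.data.frame(records)
  records$feature_id <- as.character(records$feature_id)
  rownames(records) <- NULL
  new("DifferentialTable", records = records, modality = modality)
}

#' @describeIn DifferentialTable Number of features.
#' @param x A `DifferentialTable`.
#' @export
setMethod("nrow", "DifferentialTable", function(x) nrow(x@records))

#' Extract the records of a DifferentialTable as a data.frame
#' @param object A [DifferentialTable-class].
#' @return A `data.frame`.
#' @export
setGeneric("deRecords", function(object) standardGeneric("deRecords"))

#' @rdname deRecords
#' @export
setMethod("deRecords", "DifferentialTable", function(object) object@records)

#' @rdname deRecords
#' @export
setGeneric("modality", function(object) standardGeneric("modality"))

#' @rdname deRecords
#' @export
setMethod("modality", "DifferentialTable", function(object) object@modality)

setMethod("show", "DifferentialTable", function(object) {
  cat("DifferentialTable (", object@modality, ") with ",
      nrow(object@records), " features\n", sep = "")
  print(utils::head(object@records, 4))
  if (nrow(object@records) > 4) cat("  ...\n")
})

#' GeneCatalog: a curated gene -> category map
#'
#' Curated catalogs drive program scoring: e.g. the ciliary catalogs
#' (SysCilia-style gold standards; motile-specific / primary-specific /
#' pan-ciliary structural catalogs) or astrogliosis marker lists. Categories
#' form a declared closed set so that typos cannot silently create classes.
#'
#' @slot name Catalog name.
#' @slot source Free-text provenance tag.
#' @slot entries `data.frame` with columns `gene_id`, `category`.
#' @slot categories Character vector: the closed set of legal categories.
#' @export
setClass("GeneCatalog",
  slots = c(name = "character", source = "character",
            entries = "data.frame", categories = "character"))

setValidity("GeneCatalog", function(object) {
  df <- object@entries
  msg <- character()
  if (!all(c("gene_id", "category") %in% names(df)))
    return("entries must have columns 'gene_id' and 'category'")
  if (anyDuplicated(df$gene_id))
    msg <- c(msg, "gene ids must be unique within a catalog")
  bad <- setdiff(unique(df$category), object@categories)
  if (length(bad))
    msg <- c(msg, paste("categories outside declared set:",
                        paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a GeneCatalog
#'
#' @param gene_ids Character vector of gene identifiers (unique).
#' @param categories Character vector, one category per gene (recycled if
#'   length 1).
#' @param name,source Name and provenance tag.
#' @param category_levels Closed set of legal categories; defaults to the
#'   categories present.
#' @return A [GeneCatalog-class].
#' @examples
#' cat <- GeneCatalog(c("Dnah5", "Ift88"), c("motile-specific", "pan-ciliary"),
#'                    name = "toy")
#' @export
GeneCatalog <- function(gene_ids, categories = "other", name = "catalog",
                        source = "", category_levels = NULL) {
  gene_ids <- as.character(gene_ids)
  categories <- rep_len(as.character(categories), length(gene_ids))
  if (is.null(category_levels)) category_levels <- unique(categories)
  new("GeneCatalog", name = name, source = source,
      entries = data.frame(gene_id = gene_ids, category = categories,
                           stringsAsFactors = FALSE),
      categories = category_levels)
}

#' @describeIn GeneCatalog Number of genes in the catalog.
#' @param x A `GeneCatalog`.
#' @export
setMethod("length", "GeneCatalog", function(x) nrow(x@entries))

#' @rdname tssRanges
#' @export
setMethod("geneIds", "GeneCatalog", function(object)
  object@entries$gene_id)

#' Catalog entries as a data.frame
#' @param object A [GeneCatalog-class].
#' @export
setGeneric("catalogEntries", function(object)
  standardGeneric("catalogEntries"))

#' @rdname catalogEntries
#' @export
setMethod("catalogEntries", "GeneCatalog", function(object) object@entries)

setMethod("show", "GeneCatalog", function(object) {
  cat("GeneCatalog '", object@name, "': ", nrow(object@entries),
      " genes in ", length(object@categories), " categories\n", sep = "")
  print(table(object@entries$category))
})

#' PositionWeightMatrix: a per-position base-probability motif model
#'
#' Column j gives the probability of each base A/C/G/T at motif position j.
#' Scanning scores are log2 odds against the background model, so a uniform
#' matrix against a uniform background scores exactly zero everywhere.
#'
#' @slot motifId Motif identifier (e.g. "RFX3").
#' @slot probs 4 x width numeric matrix, rownames A,C,G,T, columns summing
#'   to 1 (after pseudocount normalization).
#' @slot pseudocount Pseudocount added per cell before normalization.
#' @slot background Named numeric length 4 (A,C,G,T), summing to 1.
#' @export
setClass("PositionWeightMatrix",
  slots = c(motifId = "character", probs = "matrix",
            pseudocount = "numeric", background = "numeric"))

setValidity("PositionWeightMatrix", function(object) {
  p <- object@probs
  msg <- character()
  if (!identical(rownames(p), c("A", "C", "G", "T")))
    return("probs must have rownames A,C,G,T")
  if (ncol(p) < 1) msg <- c(msg, "width must be >= 1")
  if (any(abs(colSums(p) - 1) > 1e-9))
    msg <- c(msg, "each column must sum to 1 (tolerance 1e-9)")
  if (any(p < 0)) msg <- c(msg, "probabilities must be non-negative")
  bg <- object@background
  if (!identical(names(bg), c("A", "C", "G", "T")) ||
      abs(sum(bg) - 1) > 1e-9 || any(bg <= 0))
    msg <- c(msg, "background must be named A,C,G,T, positive, summing to 1")
  if (length(msg)) msg else TRUE
})

#' Construct a PositionWeightMatrix from counts or probabilities
#'
#' @param mat 4 x width matrix (rows A,C,G,T) of counts or probabilities;
#'   columns are renormalized after adding `pseudocount` per cell.
#' @param motif_id Identifier string.
#' @param pseudocount Added to every cell before column normalization
#'   (default 0.01, applied on the probability scale).
#' @param background Named base frequencies; default uniform.
#' @return A [PositionWeightMatrix-class].
#' @export
PositionWeightMatrix <- function(mat, motif_id = "motif", pseudocount = 0.01,
                                 background = c(A = 0.25, C = 0.25,
                                                G = 0.25, T = 0.25)) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4)
    stop("matrix must have 4 rows (A, C, G, T)")
  rownames(mat) <- c("A", "C", "G", "T")
  # normalize counts/probs columnwise, then apply pseudocount and renormalize
  cs <- colSums(mat)
  if (any(cs <= 0)) stop("every column needs positive mass")
  p <- sweep(mat, 2, cs, "/")
  p <- p + pseudocount
  p <- sweep(p, 2, colSums(p), "/")
  background <- background[c("A", "C", "G", "T")]
  names(background) <- c("A", "C", "G", "T")
  new("PositionWeightMatrix", motifId = motif_id, probs = p,
      pseudocount = pseudocount, background = background / sum(background))
}

#' @describeIn PositionWeightMatrix Motif width (number of columns).
#' @param x A `PositionWeightMatrix`.
#' @export
setMethod("ncol", "PositionWeightMatrix", function(x) ncol(x@probs))

#' Motif width
#' @param object A [PositionWeightMatrix-class].
#' @export
setGeneric("motifWidth", function(object) standardGeneric("motifWidth"))

#' @rdname motifWidth
#' @export
setMethod("motifWidth", "PositionWeightMatrix",
          function(object) ncol(object@probs))

#' @rdname motifWidth
#' @export
setGeneric("motifId", function(object) standardGeneric("motifId"))

#' @rdname motifWidth
#' @export
setMethod("motifId", "PositionWeightMatrix", function(object) object@motifId)

#' Log2-odds score matrix of a PWM against its background
#'
#' @param object A [PositionWeightMatrix-class].
#' @return 4 x width matrix of log2(p/bg) values.
#' @export
setGeneric("logOddsMatrix", function(object) standardGeneric("logOddsMatrix"))

#' @rdname logOddsMatrix
#' @export
setMethod("logOddsMatrix", "PositionWeightMatrix", function(object) {
  log2(object@probs / object@background)
})

#' Consensus sequence of a PWM (highest-probability base per column)
#' @param object A [PositionWeightMatrix-class].
#' @return Character scalar.
#' @export
setGeneric("consensusSeq", function(object) standardGeneric("consensusSeq"))

#' @rdname consensusSeq
#' @export
setMethod("consensusSeq", "PositionWeightMatrix", function(object) {
  paste(rownames(object@probs)[apply(object@probs, 2, which.max)],
        collapse = "")
})

setMethod("show", "PositionWeightMatrix", function(object) {
  cat("PositionWeightMatrix '", object@motifId, "', width ",
      ncol(object@probs), ", consensus ", consensusSeq(object), "\n",
      sep = "")
})
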