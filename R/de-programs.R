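#' Threshold policy for gene-list construction
#'
#' Encodes the selection rules used throughout the analysis: the main
#' up/down lists use `log2fc > 0.3` (resp. `< -0.3`) and `qvalue < 0.1`;
#' the motif-analysis gene list uses adjusted p < 0.05 and the ChIP-overlay
#' list adjusted p < 0.01 (in these tables the BH-adjusted p *is* the
#' q-value column). Exactly one of `q_max` / `p_adj_max` may be active.
#' All inequalities are strict.
#'
#' @param lfc_min Minimum |log2 fold change| (default 0.3, must be >= 0).
#' @param q_max q-value cutoff (default 0.1); set to `NULL` when using
#'   `p_adj_max`.
#' @param p_adj_max Adjusted-p cutoff (e.g. 0.05 or 0.01); default `NULL`.
#' @param top_n Optional truncation of the sorted lists (e.g. 1000 for the
#'   "top 1,000 genes" rule).
#' @param sort_key Sorting of the up list: `"log2fc"` (descending; the down
#'   list is sorted ascending). Ties broken by ascending q then gene id.
#' @return A named list of class `"ThresholdPolicy"`.
#' @export
thresholdPolicy <- function(lfc_min = 0.3, q_max = 0.1, p_adj_max = NULL,
                            top_n = NULL, sort_key = "log2fc") {
  if (lfc_min < 0) stop("lfc_min must be >= 0")
  if (is.null(q_max) && is.null(p_adj_max))
    stop("one of q_max or p_adj_max must be set")
  if (!is.null(q_max) && !is.null(p_adj_max))
    stop("exactly one of q_max / p_adj_max may be active")
  sort_key <- match.arg(sort_key, "log2fc")
  structure(list(lfc_min = lfc_min, q_max = q_max, p_adj_max = p_adj_max,
                 top_n = top_n, sort_key = sort_key),
            class = "ThresholdPolicy")
}

.sig_cutoff <- function(policy) {
  if (!is.null(policy$q_max)) policy$q_max else policy$p_adj_max
}

#' Read a differential-expression table from TSV
#'
#' Required columns: `feature_id`, `log2fc`, `pvalue`, `qvalue`,
#' `mean_expression`. Missing columns, non-numeric values, p/q outside
#' `[0, 1]` and duplicate feature ids are explicit errors.
#'
#' @param path Path to a tab-separated file with a header line.
#' @param modality `"rna"`, `"protein"` or `"metabolite"`.
#' @return A [DifferentialTable-class].
#' @export
readDifferentialTable <- function(path, modality = "rna") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  miss <- setdiff(.de_required_cols, names(df))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  for (cl in c("log2fc", "pvalue", "qvalue", "mean_expression")) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      v2 <- suppressWarnings(as.numeric(v))
      if (anyNA(v2) && !anyNA(v))
        stop("non-numeric values in column '", cl, "'")
      df[[cl]] <- v2
    }
  }
  DifferentialTable(df[, union(.de_required_cols, names(df))], modality)
}

#' Write a DifferentialTable to TSV
#' @param table A [DifferentialTable-class].
#' @param path Output path.
#' @export
writeDifferentialTable <- function(table, path) {
  stopifnot(is(table, "DifferentialTable"))
  utils::write.table(deRecords(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Recompute Benjamini-Hochberg q-values from the p-value column
#'
#' Ingested q-values are used as-is by default (they come from the upstream
#' DE fit); this helper rebuilds them from `pvalue` when needed.
#'
#' @param table A [DifferentialTable-class].
#' @return A [DifferentialTable-class] with `qvalue` replaced.
#' @export
recomputeQvalues <- function(table) {
  rec <- deRecords(table)
  rec$qvalue <- stats::p.adjust(rec$pvalue, method = "BH")
  DifferentialTable(rec, modality(table))
}

#' Build up/down-regulated gene lists under a threshold policy
#'
#' Up list: `log2fc > lfc_min` and significance below the active cutoff,
#' sorted by descending log2fc (ties: ascending q, then gene id), truncated
#' to `top_n` if set. Down list is symmetric (`log2fc < -lfc_min`, sorted
#' ascending).
#'
#' @param table A [DifferentialTable-class].
#' @param policy A [thresholdPolicy()].
#' @return A list with character vectors `up` and `down`.
#' @examples
#' rec <- data.frame(feature_id = c("a", "b", "c"),
#'                   log2fc = c(1, -1, 0.1), pvalue = c(.001, .001, .5),
#'                   qvalue = c(.01, .01, .6), mean_expression = 1)
#' buildGeneLists(DifferentialTable(rec), thresholdPolicy())
#' @export
buildGeneLists <- function(table, policy = thresholdPolicy()) {
  stopifnot(is(table, "DifferentialTable"),
            inherits(policy, "ThresholdPolicy"))
  rec <- deRecords(table)
  cut <- .sig_cutoff(policy)
  sig <- !is.na(rec$qvalue) & rec$qvalue < cut & !is.na(rec$log2fc)
  up <- rec[sig & rec$log2fc > policy$lfc_min, ]
  down <- rec[sig & rec$log2fc < -policy$lfc_min, ]
  ord_up <- order(-up$log2fc, up$qvalue, up$feature_id)
  ord_dn <- order(down$log2fc, down$qvalue, down$feature_id)
  up <- up$feature_id[ord_up]
  down <- down$feature_id[ord_dn]
  if (!is.null(policy$top_n)) {
    up <- utils::head(up, policy$top_n)
    down <- utils::head(down, policy$top_n)
  }
  list(up = up, down = down)
}

#' Score a curated gene catalog against a differential table
#'
#' Counts, per catalog category and overall, how many catalog genes are
#' detected in the table and how many are in the up/down lists, and tests
#' over-representation of catalog genes among up-regulated genes with a
#' hypergeometric upper tail (universe = features detected in the table).
#' Gene-id matching is case-insensitive exact match.
#'
#' @param lists Output of [buildGeneLists()] (list with `up`, `down`).
#' @param table The [DifferentialTable-class] the lists were built from.
#' @param catalog A [GeneCatalog-class].
#' @param policy The [thresholdPolicy()] used (recorded in the output).
#' @return A `data.frame` with one row per category plus `"overall"`:
#'   `category`, `n_total`, `n_detected`, `n_up`, `n_down`, `n_changed`,
#'   `p_hyper`.
#' @export
scoreCatalog <- function(lists, table, catalog,
                         policy = thresholdPolicy()) {
  stopifnot(is(table, "DifferentialTable"), is(catalog, "GeneCatalog"))
  rec <- deRecords(table)
  uni <- tolower(rec$feature_id)
  up <- tolower(lists$up)
  down <- tolower(lists$down)
  ent <- catalogEntries(catalog)
  key <- tolower(ent$gene_id)
  groups <- c(stats::setNames(as.list(unique(ent$category)),
                              unique(ent$category)),
              list(overall = unique(ent$category)))
  rows <- lapply(names(groups), function(g) {
    ids <- key[ent$category %in% groups[[g]]]
    n_total <- length(ids)
    det <- ids[ids %in% uni]
    n_up <- sum(det %in% up)
    n_down <- sum(det %in% down)
    # P(X >= n_up), X ~ Hypergeom(detected catalog genes among universe,
    # draws = size of up list)
    K <- length(det); N <- length(uni); n_draw <- sum(up %in% uni)
    p <- if (K == 0 || N == 0) 1 else
      stats::phyper(n_up - 1, K, N - K, n_draw, lower.tail = FALSE)
    data.frame(category = g, n_total = n_total, n_detected = length(det),
               n_up = n_up, n_down = n_down, n_changed = n_up + n_down,
               p_hyper = min(1, max(p, .Machine$double.xmin)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (out$n_detected[out$category == "overall"] == 0)
    warning("catalog and table do not overlap; all counts zero, p = 1")
  attr(out, "policy") <- policy
  attr(out, "catalog") <- catalog@name
  out
}

#' Count changed features per group (e.g. HMDB lipid classes)
#'
#' A feature counts as changed when `qvalue < q_max` and
#' `|log2fc| > lfc_min` (both strict); direction is recorded. Features
#' missing from the grouping are tallied under `"ungrouped"` with a
#' warning.
#'
#' @param table A [DifferentialTable-class].
#' @param grouping Named character vector mapping `feature_id` to a class
#'   label.
#' @param q_max,lfc_min Significance rule (defaults 0.1 and 0.3; set
#'   `lfc_min = 0` for a pure-q rule).
#' @return `data.frame` with one row per class plus `"overall"`: `class`,
#'   `n_total`, `n_changed`, `n_up`, `n_down`.
#' @export
countChangedFeatures <- function(table, grouping, q_max = 0.1,
                                 lfc_min = 0.3) {
  stopifnot(is(table, "DifferentialTable"))
  rec <- deRecords(table)
  cls <- unname(grouping[rec$feature_id])
  if (anyNA(cls)) {
    warning(sum(is.na(cls)), " features missing from grouping; ",
            "counted as 'ungrouped'")
    cls[is.na(cls)] <- "ungrouped"
  }
  changed_up <- rec$qvalue < q_max & rec$log2fc > lfc_min
  changed_dn <- rec$qvalue < q_max & rec$log2fc < -lfc_min
  per <- lapply(split(seq_len(nrow(rec)), cls), function(i) {
    data.frame(n_total = length(i), n_up = sum(changed_up[i]),
               n_down = sum(changed_dn[i]))
  })
  out <- do.call(rbind, per)
  out <- data.frame(class = rownames(out), n_total = out$n_total,
                    n_changed = out$n_up + out$n_down,
                    n_up = out$n_up, n_down = out$n_down,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  rbind(out, data.frame(class = "overall", n_total = nrow(rec),
                        n_changed = sum(changed_up) + sum(changed_dn),
                        n_up = sum(changed_up), n_down = sum(changed_dn)))
}

#' Cross-dataset program-activation matrix
#'
#' For each dataset and catalog category, the fractions of catalog genes
#' up-regulated, down-regulated, detected-but-unchanged, and not detected
#' (the four sum to 1), plus `frac_changed = frac_up + frac_down`. This is
#' the stacked-bar comparison used to ask whether a gene program (e.g. the
#' 92-gene motile-ciliogenesis catalog) is activated in one dataset but not
#' others.
#'
#' @param datasets Named list of [DifferentialTable-class] objects sharing
#'   a gene-id namespace.
#' @param catalog A [GeneCatalog-class].
#' @param q_max,lfc_min "Changed" rule (strict inequalities; defaults 0.1
#'   and 0.3).
#' @return Long `data.frame`: `dataset`, `category`, `n_genes`, `frac_up`,
#'   `frac_down`, `frac_unchanged`, `frac_not_detected`, `frac_changed`.
#' @export
crossDatasetMatrix <- function(datasets, catalog, q_max = 0.1,
                               lfc_min = 0.3) {
  stopifnot(length(datasets) >= 1, !is.null(names(datasets)),
            is(catalog, "GeneCatalog"))
  ent <- catalogEntries(catalog)
  cats <- c(as.list(stats::setNames(unique(ent$category),
                                    unique(ent$category))),
            list(overall = unique(ent$category)))
  rows <- list()
  for (ds in names(datasets)) {
    rec <- deRecords(datasets[[ds]])
    uni <- tolower(rec$feature_id)
    up <- tolower(rec$feature_id[rec$qvalue < q_max &
                                   rec$log2fc > lfc_min])
    dn <- tolower(rec$feature_id[rec$qvalue < q_max &
                                   rec$log2fc < -lfc_min])
    for (cg in names(cats)) {
      ids <- tolower(ent$gene_id[ent$category %in% cats[[cg]]])
      n <- length(ids)
      n_up <- sum(ids %in% up); n_dn <- sum(ids %in% dn)
      n_det <- sum(ids %in% uni)
      rows[[length(rows) + 1L]] <- data.frame(
        dataset = ds, category = cg, n_genes = n,
        frac_up = n_up / n, frac_down = n_dn / n,
        frac_unchanged = (n_det - n_up - n_dn) / n,
        frac_not_detected = (n - n_det) / n,
        frac_changed = (n_up + n_dn) / n,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Row-wise Z-scores of an expression matrix
#'
#' Each row is centered and scaled to unit sample sd (the transform behind
#' "Z-scores calculated from scaled reads per base" heatmaps).
#' Zero-variance rows map to all-zeros with a warning.
#'
#' @param mat Numeric matrix with >= 2 columns.
#' @return Matrix of the same shape; row means 0, row sds 1.
#' @export
zscoreRows <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("need at least 2 columns to Z-score rows")
  mu <- rowMeans(mat)
  sd <- apply(mat, 1, stats::sd)
  zero <- sd == 0 | !is.finite(sd)
  if (any(zero)) {
    warning(sum(zero), " zero-variance row(s) mapped to zeros")
    sd[zero] <- 1
  }
  z <- (mat - mu) / sd
  z[zero, ] <- 0
  z
}
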