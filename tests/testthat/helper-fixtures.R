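# Shared fixtures and independent oracles used across the suite.

toy_de_records <- function() {
  data.frame(
    feature_id = c("g1", "g2", "g3", "g4", "g5", "g6", "g7", "g8"),
    log2fc = c(2.0, 0.31, 0.3, -0.5, -0.31, 0.8, -2.0, 0.0),
    pvalue = c(1e-6, 1e-3, 1e-3, 1e-4, 2e-3, 0.5, 1e-5, 0.9),
    qvalue = c(1e-5, 0.05, 0.05, 0.01, 0.09, 0.6, 1e-4, 0.95),
    mean_expression = c(10, 5, 8, 2, 3, 7, 9, 1),
    stringsAsFactors = FALSE)
}

random_de_table <- function(n, seed) {
  set.seed(seed)
  p <- stats::runif(n)
  DifferentialTable(data.frame(
    feature_id = sprintf("f%03d", seq_len(n)),
    log2fc = stats::rnorm(n, 0, 1),
    pvalue = p,
    qvalue = stats::p.adjust(p, "BH"),
    mean_expression = stats::rexp(n),
    stringsAsFactors = FALSE))
}

# independent brute-force gene-list filter (no sorting tricks shared with
# the implementation)
oracle_gene_lists <- function(records, lfc_min, sig_max, top_n = NULL) {
  up <- character(); down <- character()
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (r$qvalue < sig_max && r$log2fc > lfc_min) up <- c(up, r$feature_id)
    if (r$qvalue < sig_max && r$log2fc < -lfc_min)
      down <- c(down, r$feature_id)
  }
  sub_u <- records[match(up, records$feature_id), ]
  sub_d <- records[match(down, records$feature_id), ]
  up <- up[order(-sub_u$log2fc, sub_u$qvalue, sub_u$feature_id)]
  down <- down[order(sub_d$log2fc, sub_d$qvalue, sub_d$feature_id)]
  if (!is.null(top_n)) {
    up <- head(up, top_n); down <- head(down, top_n)
  }
  list(up = up, down = down)
}

# exhaustive hypergeometric upper tail by subset enumeration
oracle_hyper_enum <- function(universe, catalog_in_table, up_set) {
  k_obs <- length(intersect(up_set, catalog_in_table))
  subs <- utils::combn(universe, length(up_set))
  hits <- apply(subs, 2, function(s) length(intersect(s, catalog_in_table)))
  mean(hits >= k_obs)
}

toy_pwm <- function(width = 6, seed = 42, dominance = 0.7) {
  set.seed(seed)
  cons <- sample(c("A", "C", "G", "T"), width, replace = TRUE)
  m <- matrix((1 - dominance) / 3, 4, width,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_len(width)) m[cons[j], j] <- dominance
  PositionWeightMatrix(m, motif_id = "toy")
}

revcomp_chr <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

# position-by-position rescan oracle; minus strand handled by scanning
# the reverse complement of the window with the forward matrix and
# mapping coordinates back
oracle_scan <- function(seq, pwm, thr, half_width) {
  lut <- logOddsMatrix(pwm)
  w <- ncol(lut)
  score_at <- function(chars, i) {
    s <- 0
    for (j in seq_len(w)) {
      b <- chars[i + j - 1]
      if (b %in% rownames(lut)) s <- s + lut[b, j]
    }
    s
  }
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  rc <- strsplit(revcomp_chr(seq), "")[[1]]
  out <- list()
  for (i in seq_len(L - w + 1)) {
    s <- score_at(chars, i)
    if (s >= thr)
      out[[length(out) + 1L]] <- data.frame(
        offset = i + floor(w / 2) - half_width - 1L, strand = "+",
        score = s)
  }
  for (i in seq_len(L - w + 1)) {
    s <- score_at(rc, i)
    if (s >= thr) {
      fwd_start <- L - i - w + 2L
      out[[length(out) + 1L]] <- data.frame(
        offset = fwd_start + floor(w / 2) - half_width - 1L,
        strand = "-", score = s)
    }
  }
  if (!length(out))
    return(data.frame(offset = integer(), strand = character(),
                      score = numeric()))
  do.call(rbind, out)
}

# exhaustive two-sample ECDF gap maximization
oracle_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  Fx <- vapply(pts, function(t) mean(x <= t), numeric(1))
  Fy <- vapply(pts, function(t) mean(y <= t), numeric(1))
  max(abs(Fx - Fy))
}

# minimal-box rotation-grid oracle for planar (z = 0) polylines:
# 0.1-degree sweep, minimal area with ties broken toward the smaller
# longest edge
oracle_planar_obb_edge <- function(pts2d) {
  thetas <- seq(0, pi / 2, by = 0.1 * pi / 180)
  area <- edge <- numeric(length(thetas))
  for (i in seq_along(thetas)) {
    th <- thetas[i]
    u <- c(cos(th), sin(th)); v <- c(-sin(th), cos(th))
    e1 <- diff(range(pts2d %*% u)); e2 <- diff(range(pts2d %*% v))
    area[i] <- e1 * e2
    edge[i] <- max(e1, e2)
  }
  amin <- min(area)
  min(edge[area <= amin + 1e-9 * max(amin, 1)])
}

rigid_motion <- function(pts, seed) {
  set.seed(seed)
  a <- stats::runif(3, 0, 2 * pi)
  rx <- matrix(c(1, 0, 0, 0, cos(a[1]), sin(a[1]),
                 0, -sin(a[1]), cos(a[1])), 3)
  ry <- matrix(c(cos(a[2]), 0, -sin(a[2]), 0, 1, 0,
                 sin(a[2]), 0, cos(a[2])), 3)
  rz <- matrix(c(cos(a[3]), sin(a[3]), 0, -sin(a[3]), cos(a[3]), 0,
                 0, 0, 1), 3)
  t(rx %*% ry %*% rz %*% t(pts)) +
    matrix(stats::runif(3, -10, 10), nrow(pts), 3, byrow = TRUE)
}

small_genome <- function(n = 40, seed = 1)
  makeGenome(n, n_chroms = 1, chrom_len = 1e6, seed = seed)
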