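test_that("uniform PWM against uniform background scores exactly zero", {
  u <- PositionWeightMatrix(matrix(0.25, 4, 6), pseudocount = 0)
  set.seed(1)
  seqs <- vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = ""),
    character(1))
  names(seqs) <- paste0("g", 1:5)
  hits <- scanPwm(seqs, u, score_threshold = 0, half_width = 40)
  # every position on both strands is a hit with score exactly 0
  expect_equal(nrow(hits), 5 * 2 * (80 - 6 + 1))
  expect_equal(hits$score, rep(0, nrow(hits)))
})

test_that("scan equals a position-by-position rescan oracle", {
  pwm <- toy_pwm(width = 7, seed = 2)
  thr <- 0.5 * maxPwmScore(pwm)
  set.seed(3)
  for (r in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 60,
                      prob = c(rep(0.24, 4), 0.04), TRUE), collapse = "")
    got <- scanPwm(stats::setNames(s, "g"), pwm, score_threshold = thr,
                   half_width = 30)
    want <- oracle_scan(s, pwm, thr, 30)
    key <- function(d) d[order(d$offset, d$strand), c("offset", "strand",
                                                      "score")]
    expect_equal(key(got), key(want), ignore_attr = TRUE,
                 tolerance = 1e-9)
  }
})

test_that("scan is strand-symmetric under window reverse complement", {
  pwm_even <- toy_pwm(width = 8, seed = 4)
  thr <- 0.4 * maxPwmScore(pwm_even)
  set.seed(5)
  s <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  h <- scanPwm(stats::setNames(s, "g"), pwm_even, thr, half_width = 50)
  h_rc <- scanPwm(stats::setNames(revcomp_chr(s), "g"), pwm_even, thr,
                  half_width = 50)
  # even-width motifs: offsets negate exactly, strands flip, scores match
  a <- h[order(h$offset, h$strand), ]
  b <- h_rc[order(-h_rc$offset, rev(h_rc$strand)), ]
  expect_equal(sort(-b$offset), sort(a$offset))
  expect_equal(sort(b$score), sort(a$score), tolerance = 1e-9)
  expect_equal(unname(table(a$strand)["+"]), unname(table(b$strand)["-"]))
})

test_that("ambiguous bases contribute background odds (score zero)", {
  pwm <- toy_pwm(width = 4, seed = 6)
  lut <- logOddsMatrix(pwm)
  s <- "ANNNNNNNNA"
  h <- scanPwm(stats::setNames(s, "g"), pwm, score_threshold = -100,
               half_width = 5)
  all_n <- h[h$offset == 0 & h$strand == "+", ]  # window of Ns only
  expect_equal(all_n$score, 0)
  # fully ambiguous window yields no hits at positive thresholds
  h2 <- scanPwm(stats::setNames("NNNNNNNNNN", "g"), pwm,
                score_threshold = 0.1, half_width = 5)
  expect_equal(nrow(h2), 0)
})

test_that("central enrichment matches closed-form binomial arithmetic", {
  mk_hits <- function(offsets, n_genes) {
    d <- data.frame(gene_id = sprintf("g%d", seq_along(offsets)),
                    offset = offsets,
                    strand = rep("+", length(offsets)),
                    score = rep(10, length(offsets)))
    attr(d, "n_genes") <- n_genes
    d
  }
  target <- mk_hits(c(-10, 5, 40, -480), 4)   # 3 of 4 within +/- 50
  negative <- mk_hits(c(200, -300, 30, 450), 4)  # 1 of 4 within +/- 50
  res <- centralEnrichment(target, negative, w_grid = 50)
  pi0 <- (1 + 1) / (4 + 2)
  p_hand <- sum(choose(4, 3:4) * pi0^(3:4) * (1 - pi0)^(4 - (3:4)))
  expect_equal(res$k_target, 3L)
  expect_equal(res$k_negative, 1L)
  expect_equal(res$pi_null, pi0)
  expect_equal(res$p_raw, p_hand, tolerance = 1e-12)
  expect_equal(res$p, p_hand, tolerance = 1e-12)  # single w: no correction
  # Bonferroni over a grid
  res2 <- centralEnrichment(target, negative, w_grid = c(50, 100))
  expect_equal(res2$p, min(1, res2$p_raw * 2), tolerance = 1e-12)
  # no target hits -> p = 1
  none <- mk_hits(numeric(0), 4)
  expect_equal(centralEnrichment(none, negative, w_grid = 50)$p, 1)
})

test_that("binomial tail matches exhaustive enumeration for tiny targets", {
  # enumerate all outcomes of Binomial(n, pi) directly
  for (n in c(3, 7, 12)) {
    offs <- seq(-40, 40, length.out = n)
    target <- data.frame(gene_id = paste0("t", 1:n), offset = offs,
                         strand = "+", score = 1)
    attr(target, "n_genes") <- n
    negative <- data.frame(gene_id = paste0("n", 1:10),
                           offset = seq(-450, 450, length.out = 10),
                           strand = "+", score = 1)
    attr(negative, "n_genes") <- 10
    res <- centralEnrichment(target, negative, w_grid = 100)
    k <- res$k_target
    pi0 <- res$pi_null
    p_enum <- sum(vapply(k:n, function(j)
      choose(n, j) * pi0^j * (1 - pi0)^(n - j), numeric(1)))
    expect_equal(res$p_raw, p_enum, tolerance = 1e-12)
  }
})

test_that("planted central signal is detected with high significance", {
  gm <- makeGenome(1200, 1, 3e6, seed = 40)
  ids <- geneIds(gm)
  pwm <- rfxLikePwm()
  target <- makePromoters(gm, pwm, genes = ids[1:200], offset_sd = 50,
                          seed = 41)
  negative <- makePromoters(gm, pwm, genes = ids[201:1200],
                            plant_fraction = 0, seed = 42)
  th <- scanPwm(target$sequences, pwm)
  nh <- scanPwm(negative$sequences, pwm)
  res <- centralEnrichment(th, nh)
  expect_lte(res$p, 0.01)
  expect_gt(res$fold_concentration, 5)
})

test_that("motif probability curve behaves at its extremes", {
  h <- data.frame(gene_id = paste0("g", 1:7), offset = rep(0L, 7),
                  strand = "+", score = 5)
  attr(h, "n_genes") <- 10
  cv <- motifProbabilityCurve(h, bin_width = 50, half_width = 500)
  expect_equal(sum(cv$probability), 0.7)
  expect_equal(cv$n_hits[cv$bin_start == 0], 7)
  expect_equal(sum(cv$n_hits > 0), 1)
  # no hits -> all-zero curve
  h0 <- h[0, ]; attr(h0, "n_genes") <- 10
  cv0 <- motifProbabilityCurve(h0, bin_width = 50, half_width = 500)
  expect_equal(cv0$probability, rep(0, 20))
  expect_error(motifProbabilityCurve(h, bin_width = 33), "divide")
  # near-uniform synthetic best hits -> no bin dominates
  set.seed(43)
  hu <- data.frame(gene_id = paste0("g", 1:2000),
                   offset = sample(-500:499, 2000, TRUE),
                   strand = "+", score = 1)
  attr(hu, "n_genes") <- 2000
  cvu <- motifProbabilityCurve(hu, bin_width = 100, half_width = 500)
  expect_lt(max(abs(cvu$probability - 0.1)), 4 * sqrt(0.1 * 0.9 / 2000))
})

test_that("motif files round-trip through JASPAR and MEME formats", {
  pwm <- rfxLikePwm()
  f <- tempfile(fileext = ".meme")
  writeMemeMotif(pwm, f)
  back <- readMemeMotifs(f, pseudocount = 0)
  expect_named(back, "RFX_like_synthetic")
  expect_equal(back[[1]]@probs, pwm@probs, tolerance = 1e-4)
  jf <- tempfile(fileext = ".pfm")
  writeLines(c(">MA0001.1 TOYRFX",
               "A  [ 10  0  2 ]",
               "C  [  0 10  2 ]",
               "G  [  0  0  4 ]",
               "T  [  0  0  2 ]"), jf)
  ps <- readJasparPfm(jf)
  expect_named(ps, "TOYRFX")
  expect_equal(motifWidth(ps[[1]]), 3)
  expect_equal(consensusSeq(ps[[1]]), "ACG")
  # column sums are exactly 1 after pseudocount normalization
  expect_equal(colSums(ps[[1]]@probs), rep(1, 3), tolerance = 1e-12)
})

test_that("promoter windows are extracted per the TSS-centered contract", {
  chr <- paste(rep("ACGT", 5000), collapse = "")
  genome_seq <- Biostrings::DNAStringSet(c(chr1 = chr))
  tss <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(10001, 10001, 201), width = 1),
    strand = c("+", "-", "+"),
    gene_id = c("plus", "minus", "edge"))
  win <- extractPromoterWindows(tss, genome_seq, half_width = 500)
  # plus strand: 0-based [9500, 10500) == 1-based [9501, 10500]
  expect_equal(GenomicRanges::start(win$windows)[1], 9501)
  expect_equal(GenomicRanges::end(win$windows)[1], 10500)
  # minus strand: same genomic interval, sequence reverse-complemented
  expect_equal(GenomicRanges::start(win$windows)[2], 9501)
  expect_equal(as.character(win$sequences[["minus"]]),
               revcomp_chr(as.character(win$sequences[["plus"]])))
  # edge window clipped and flagged
  expect_true(win$windows$clipped[3])
  expect_equal(GenomicRanges::start(win$windows)[3], 1)
  expect_equal(Biostrings::width(win$sequences)[3], 700)
  expect_false(any(win$windows$clipped[1:2]))
  expect_error(extractPromoterWindows(
    GenomicRanges::GRanges("chrX", IRanges::IRanges(5, 5), strand = "+",
                           gene_id = "gx"), genome_seq), "missing")
})
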