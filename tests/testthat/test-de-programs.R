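test_that("differential-table validation rejects malformed input", {
  rec <- toy_de_records()
  expect_s4_class(DifferentialTable(rec), "DifferentialTable")
  bad_q <- rec; bad_q$qvalue[1] <- 1.2
  expect_error(DifferentialTable(bad_q), "qvalue")
  dup <- rbind(rec, rec[1, ])
  expect_error(DifferentialTable(dup), "duplicate")
  f <- tempfile(fileext = ".tsv")
  write.table(rec[, -2], f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readDifferentialTable(f), "log2fc")
  write.table(transform(rec, log2fc = "oops"), f, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(readDifferentialTable(f), "non-numeric")
  write.table(rec, f, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- readDifferentialTable(f)
  expect_equal(nrow(deRecords(tab)), 8)
  expect_equal(deRecords(tab)$log2fc, rec$log2fc)
})

test_that("gene lists match the brute-force filter on the toy table", {
  tab <- DifferentialTable(toy_de_records())
  lists <- buildGeneLists(tab, thresholdPolicy())
  oracle <- oracle_gene_lists(toy_de_records(), 0.3, 0.1)
  expect_identical(lists, oracle)
  # strict inequalities: g3 (log2fc == 0.3) and g5 (log2fc == -0.31, ok)
  expect_false("g3" %in% lists$up)
  expect_true("g5" %in% lists$down)
  # empty table -> two empty lists
  e <- buildGeneLists(DifferentialTable(toy_de_records()[0, ]))
  expect_identical(lengths(e), c(up = 0L, down = 0L))
})

test_that("gene lists equal brute-force filtering on random tables", {
  for (r in 1:60) {
    tab <- random_de_table(n = 40, seed = r)
    pol <- thresholdPolicy(lfc_min = 0.3, q_max = 0.5,
                           top_n = if (r %% 2) 5 else NULL)
    got <- buildGeneLists(tab, pol)
    want <- oracle_gene_lists(deRecords(tab), 0.3, 0.5, pol$top_n)
    expect_identical(got, want)
  }
})

test_that("threshold policy enforces its contract", {
  expect_error(thresholdPolicy(lfc_min = -1), ">= 0")
  expect_error(thresholdPolicy(q_max = NULL, p_adj_max = NULL), "one of")
  expect_error(thresholdPolicy(q_max = 0.1, p_adj_max = 0.05),
               "exactly one")
  pol <- thresholdPolicy(q_max = NULL, p_adj_max = 0.05)
  tab <- DifferentialTable(toy_de_records())
  lists <- buildGeneLists(tab, pol)
  expect_identical(lists, oracle_gene_lists(toy_de_records(), 0.3, 0.05))
})

test_that("catalog scoring reproduces exhaustive hypergeometric tails", {
  # 10-gene universe, 4-gene catalog, 3 up of which 2 in catalog
  ids <- sprintf("u%02d", 1:10)
  rec <- data.frame(feature_id = ids,
                    log2fc = c(2, 1.5, 1, rep(0, 7)),
                    pvalue = c(rep(1e-5, 3), rep(0.9, 7)),
                    qvalue = c(rep(1e-4, 3), rep(0.95, 7)),
                    mean_expression = 1)
  tab <- DifferentialTable(rec)
  catalog <- GeneCatalog(c("u01", "u02", "u05", "u06"), "motile-specific")
  lists <- buildGeneLists(tab)
  expect_identical(lists$up, c("u01", "u02", "u03"))
  sc <- scoreCatalog(lists, tab, catalog)
  ov <- sc[sc$category == "overall", ]
  expect_equal(ov$n_total, 4)
  expect_equal(ov$n_up, 2)
  p_enum <- oracle_hyper_enum(ids, c("u01", "u02", "u05", "u06"),
                              lists$up)
  expect_equal(ov$p_hyper, p_enum, tolerance = 1e-12)
})

test_that("catalog scores are invariant to row and catalog order", {
  tab <- random_de_table(60, seed = 5)
  rec <- deRecords(tab)
  catalog <- GeneCatalog(rec$feature_id[c(3, 10, 22, 40, 55)],
                         c("motile-specific", "motile-specific",
                           "pan-ciliary", "pan-ciliary", "pan-ciliary"))
  pol <- thresholdPolicy(q_max = 0.8)
  lists <- buildGeneLists(tab, pol)
  s1 <- scoreCatalog(lists, tab, catalog, pol)
  tab2 <- DifferentialTable(rec[rev(seq_len(nrow(rec))), ])
  ent <- catalogEntries(catalog)[c(4, 2, 5, 1, 3), ]
  catalog2 <- GeneCatalog(ent$gene_id, ent$category)
  s2 <- scoreCatalog(buildGeneLists(tab2, pol), tab2, catalog2, pol)
  key <- order(s1$category)
  expect_equal(s1[key, c("n_total", "n_up", "n_down", "p_hyper")],
               s2[order(s2$category),
                  c("n_total", "n_up", "n_down", "p_hyper")],
               ignore_attr = TRUE)
  # disjoint catalog: zero counts, p = 1, warning
  stranger <- GeneCatalog(c("nope1", "nope2"), "other")
  expect_warning(s3 <- scoreCatalog(lists, tab, stranger, pol),
                 "do not overlap")
  expect_equal(s3$n_up, rep(0L, nrow(s3)), ignore_attr = TRUE)
  expect_equal(s3$p_hyper, rep(1, nrow(s3)))
})

test_that("gene-id matching is case-insensitive", {
  tab <- DifferentialTable(toy_de_records())
  catalog <- GeneCatalog(c("G1", "G7"), "motile-specific")
  sc <- scoreCatalog(buildGeneLists(tab), tab, catalog)
  ov <- sc[sc$category == "overall", ]
  expect_equal(ov$n_detected, 2)
  expect_equal(ov$n_up, 1)    # g1 up
  expect_equal(ov$n_down, 1)  # g7 down
})

test_that("changed-feature counts equal a brute-force filter", {
  rec <- toy_de_records()[1:6, ]
  tab <- DifferentialTable(rec)
  grouping <- c(g1 = "ceramide", g2 = "ceramide", g3 = "sterol",
                g4 = "sterol", g5 = "sterol", g6 = "glycerolipid")
  out <- countChangedFeatures(tab, grouping)
  want_changed <- sum(rec$qvalue < 0.1 & abs(rec$log2fc) > 0.3)
  expect_equal(out$n_changed[out$class == "overall"], want_changed)
  for (cl in unique(grouping)) {
    i <- rec$feature_id %in% names(grouping)[grouping == cl]
    expect_equal(out$n_changed[out$class == cl],
                 sum(rec$qvalue[i] < 0.1 & abs(rec$log2fc[i]) > 0.3))
  }
  # all p = 1 -> zero changed
  null_rec <- transform(rec, pvalue = 1, qvalue = 1)
  out0 <- countChangedFeatures(DifferentialTable(null_rec), grouping)
  expect_equal(out0$n_changed, rep(0L, nrow(out0)), ignore_attr = TRUE)
  # ungrouped features are tallied with a warning
  expect_warning(out2 <- countChangedFeatures(tab, grouping[1:3]),
                 "ungrouped")
  expect_true("ungrouped" %in% out2$class)
})

test_that("cross-dataset matrix separates planted activation from null", {
  gm <- makeGenome(600, 1, 2e6, seed = 20)
  catalog <- GeneCatalog(geneIds(gm)[1:50], "motile-specific")
  de_on <- makeDifferentialTable(gm, catalog, planted_fraction = 0.6,
                                 seed = 21)
  de_off <- makeDifferentialTable(gm, catalog, planted_fraction = 0,
                                  seed = 22)
  m <- crossDatasetMatrix(list(on = de_on, off = de_off), catalog)
  on_row <- m[m$dataset == "on" & m$category == "overall", ]
  off_row <- m[m$dataset == "off" & m$category == "overall", ]
  se <- sqrt(0.6 * 0.4 / 50)
  expect_gte(on_row$frac_changed - off_row$frac_changed, 0.6 - 2 * se)
  # fractions sum to 1
  expect_equal(on_row$frac_up + on_row$frac_down + on_row$frac_unchanged +
                 on_row$frac_not_detected, 1)
  # dataset with no catalog genes detected
  rec <- deRecords(de_on)
  rec$feature_id <- paste0("other_", rec$feature_id)
  m2 <- crossDatasetMatrix(list(x = DifferentialTable(rec)), catalog)
  expect_equal(m2$frac_changed, rep(0, nrow(m2)))
  expect_equal(m2$frac_not_detected, rep(1, nrow(m2)))
})

test_that("row Z-scoring has exact moments and declared edge policy", {
  expect_equal(as.numeric(zscoreRows(matrix(1:3, 1))), c(-1, 0, 1))
  set.seed(30)
  m <- matrix(rnorm(20), 5, 4)
  z <- zscoreRows(m)
  expect_equal(rowMeans(z), rep(0, 5), tolerance = 1e-12)
  expect_equal(apply(z, 1, sd), rep(1, 5), tolerance = 1e-12)
  expect_warning(zc <- zscoreRows(rbind(c(1, 1, 1), c(1, 2, 3))),
                 "zero-variance")
  expect_equal(zc[1, ], c(0, 0, 0), ignore_attr = TRUE)
  expect_error(zscoreRows(matrix(1:3, 3, 1)), "2 columns")
})
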