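test_that("a straight segment yields arc = chord = proxy and tortuosity 1", {
  m <- measureCilium(rbind(c(1, 2, 3), c(4, 6, 3)))
  expect_equal(m$arc_length, 5)
  expect_equal(m$end_to_end, 5)
  expect_equal(m$length_proxy, 5, tolerance = 1e-9)
  expect_equal(m$tortuosity, 1)
  # subdivided straight line behaves identically
  t_ <- seq(0, 1, length.out = 11)
  line <- cbind(5 * t_, 0 * t_, 0 * t_)
  m2 <- measureCilium(line)
  expect_equal(m2$length_proxy, 5, tolerance = 1e-9)
  expect_equal(m2$tortuosity, 1, tolerance = 1e-12)
  # degenerate input errors
  expect_error(measureCilium(rbind(c(1, 1, 1), c(1, 1, 1))),
               "degenerate")
  expect_error(measureCilium(rbind(c(1, 1, 1))), "2 points")
  expect_error(measureCilium(rbind(c(0, 0, 0), c(NA, 1, 1))),
               "non-finite")
})

test_that("measures are invariant to rigid motion and point reversal", {
  set.seed(90)
  tr <- makeCilia(6, list(g = list(length_mean = 5, length_sd = 1,
                                   curvature = 0.5)), seed = 91)
  for (cid in unique(tr$cilium_id)) {
    pts <- as.matrix(tr[tr$cilium_id == cid, c("x", "y", "z")])
    m0 <- measureCilium(pts)
    m1 <- measureCilium(rigid_motion(pts, seed = 92))
    for (col in c("arc_length", "end_to_end", "length_proxy",
                  "tortuosity"))
      expect_equal(m1[[col]], m0[[col]], tolerance = 1e-6)
    m2 <- measureCilium(pts[rev(seq_len(nrow(pts))), ])
    expect_equal(m2$length_proxy, m0$length_proxy, tolerance = 1e-9)
    expect_equal(m2$arc_length, m0$arc_length, tolerance = 1e-12)
  }
})

test_that("measure ordering invariants hold", {
  tr <- makeCilia(25, list(g = list(length_mean = 4, length_sd = 1,
                                    curvature = 1)), seed = 93)
  m <- measureCilia(tr)
  # the longest box edge never exceeds the arc length, and the chord is
  # bounded by the box diagonal (sqrt(3) x longest edge); the chord can
  # legitimately exceed the longest edge for strongly bent shapes
  expect_true(all(m$length_proxy <= m$arc_length + 1e-9))
  expect_true(all(m$end_to_end <= sqrt(3) * m$length_proxy + 1e-9))
  expect_true(all(m$tortuosity >= 1 - 1e-12))
})

test_that("OBB length proxy matches the rotation-grid brute force on planar shapes", {
  shapes <- list(
    # L-shape: two 3-um legs at a right angle
    rbind(c(0, 0), c(1.5, 0), c(3, 0), c(3, 1.5), c(3, 3)),
    # shallow arc
    cbind(seq(0, 4, length.out = 12),
          0.4 * sin(seq(0, pi, length.out = 12))),
    # zig-zag
    rbind(c(0, 0), c(1, 0.8), c(2, 0), c(3, 0.8), c(4, 0)),
    # hairpin
    rbind(c(0, 0), c(2.5, 0), c(2.5, 0.5), c(0.2, 0.5)))
  for (s in shapes) {
    want <- oracle_planar_obb_edge(s)
    got <- obbLongestEdge(cbind(s, 0))
    expect_equal(got, want, tolerance = 1e-3)
  }
})

test_that("morphology rules apply half-open thresholds and loop detection", {
  base <- data.frame(arc_length = 5, end_to_end = 5, length_proxy = 5,
                     min_self_distance = Inf)
  m <- rbind(transform(base, tortuosity = 1.0),
             transform(base, tortuosity = 1.05),
             transform(base, tortuosity = 1.3),
             transform(base, tortuosity = 1.5),
             transform(base, tortuosity = 3))
  cls <- classifyMorphology(m)$morphology
  expect_equal(as.character(cls),
               c("straight", "bent", "bent", "contorted", "contorted"))
  # a loop triggers contorted even at low tortuosity... but not a
  # gentle open curve
  loop <- transform(base, tortuosity = 1.02, min_self_distance = 0.05)
  expect_equal(as.character(classifyMorphology(loop)$morphology),
               "contorted")
})

test_that("high-curvature populations are classified contorted at defaults", {
  tr <- makeCilia(100, list(g = list(length_mean = 5, length_sd = 1,
                                     curvature = 3)), seed = 94)
  m <- classifyMorphology(measureCilia(tr))
  expect_gte(mean(m$morphology == "contorted"), 0.9)
  # and near-straight populations are not
  tr0 <- makeCilia(100, list(g = list(length_mean = 3.5, length_sd = 0.5,
                                      curvature = 0.02)), seed = 95)
  m0 <- classifyMorphology(measureCilia(tr0))
  expect_gte(mean(m0$morphology == "straight"), 0.9)
})

test_that("KS statistic equals exhaustive ECDF-gap maximization", {
  # identical samples -> D = 0, p = 1
  m_same <- data.frame(cilium_id = sprintf("c%d", 1:20),
                       mouse_id = rep(c("a1", "b1"), each = 10),
                       genotype = rep(c("a", "b"), each = 10),
                       length_proxy = rep(seq(2, 4.25, 0.25), 2))
  cmp0 <- compareCiliaGroups(m_same)
  expect_equal(cmp0$ks$D, 0)
  expect_equal(cmp0$ks$p, 1)
  # fully separated supports -> D = 1
  m_sep <- transform(m_same,
                     length_proxy = c(seq(1, 2, length.out = 10),
                                      seq(5, 7, length.out = 10)))
  expect_equal(compareCiliaGroups(m_sep)$ks$D, 1)
  # two 7-point toy samples vs hand enumeration
  x <- c(2.1, 2.5, 2.8, 3.0, 3.3, 3.9, 4.2)
  y <- c(2.9, 3.4, 3.8, 4.1, 4.6, 5.0, 5.5)
  m_toy <- data.frame(cilium_id = sprintf("c%d", 1:14),
                      mouse_id = rep(c("a1", "b1"), each = 7),
                      genotype = rep(c("a", "b"), each = 7),
                      length_proxy = c(x, y))
  expect_equal(compareCiliaGroups(m_toy)$ks$D, oracle_ks_D(x, y),
               tolerance = 1e-12)
  # random instances up to 50 points per group
  set.seed(96)
  for (r in 1:20) {
    nx <- sample(5:50, 1); ny <- sample(5:50, 1)
    x <- rnorm(nx, 3, 1); y <- rnorm(ny, 3.5, 1.2)
    mm <- data.frame(cilium_id = sprintf("c%d", seq_len(nx + ny)),
                     mouse_id = rep(c("a1", "b1"), c(nx, ny)),
                     genotype = rep(c("a", "b"), c(nx, ny)),
                     length_proxy = c(x, y))
    expect_equal(compareCiliaGroups(mm)$ks$D, oracle_ks_D(x, y),
                 tolerance = 1e-12)
  }
})

test_that("group comparison emits ANOVA at both units and class proportions", {
  tr <- makeCilia(60, list(ctrl = list(length_mean = 3.2, length_sd = 0.8,
                                       curvature = 0.05),
                           mut = list(length_mean = 4.8, length_sd = 1.2,
                                      curvature = 0.6)), seed = 97)
  m <- classifyMorphology(measureCilia(tr))
  cmp <- compareCiliaGroups(m)
  expect_lt(cmp$anova_cilium$p, 0.001)
  expect_true(is.finite(cmp$anova_mouse$F))
  expect_equal(rowSums(cmp$class_proportions),
               c(ctrl = 1, mut = 1), tolerance = 1e-12)
  expect_equal(nrow(cmp$mouse_means), 10)  # 5 mice per genotype
  # single group errors
  one <- m[m$genotype == "ctrl", ]
  expect_error(compareCiliaGroups(one), "2 genotype")
})

test_that("length-shifted populations are detected by KS in most seeds", {
  hits <- vapply(1:20, function(r) {
    tr <- makeCilia(150, list(a = list(length_mean = 3.2, length_sd = 1,
                                       curvature = 0.05),
                              b = list(length_mean = 4.2, length_sd = 1,
                                       curvature = 0.05)), seed = 200 + r)
    compareCiliaGroups(measureCilia(tr))$ks$p < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("trace tables round-trip and enforce unit declarations", {
  tr <- makeCilia(4, list(g = list(length_mean = 3, length_sd = 0.2,
                                   curvature = 0.3)), seed = 98)
  f <- tempfile(fileext = ".csv")
  writeCiliaTraces(tr, f)
  expect_identical(readLines(f, 1), "# seed: 98")
  back <- readCiliaTraces(f)
  expect_equal(back$x, tr$x, tolerance = 1e-12)
  expect_equal(back$cilium_id, tr$cilium_id)
  mixed <- tr; mixed$unit[1] <- "nm"
  f2 <- tempfile(fileext = ".csv")
  write.csv(mixed, f2, row.names = FALSE)
  expect_error(readCiliaTraces(f2), "mixed units")
  noun <- tr; noun$unit <- NULL
  write.csv(noun, f2, row.names = FALSE)
  expect_error(readCiliaTraces(f2), "unit")
})
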