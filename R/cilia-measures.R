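#' Longest edge of an (approximately) minimal oriented bounding box
#'
#' The length proxy used for cilia: the longest principal axis of the
#' minimal rectangular box fully enclosing the 3D point set. The box is
#' found by aligning to the principal axes of the points and then
#' searching the rotation group (10-degree Euler-angle grid over the
#' box-symmetry fundamental domain, refined by a pattern search to below
#' 1e-6 rad) to minimize the regularized box volume `prod(extent + eps)`;
#' the `eps` term makes the objective meaningful for planar and collinear
#' sets (where the true minimal volume is 0), where it reduces to
#' minimal-area / minimal-length boxes. Exact volume ties are broken
#' toward the smaller longest edge.
#'
#' All computation happens in the principal-axis frame, so the result is
#' invariant to rigid motions of the input (up to principal-axis
#' degeneracy).
#'
#' @param pts Numeric n x 3 matrix of coordinates (um).
#' @return Length of the longest box edge (um).
#' @export
obbLongestEdge <- function(pts) {
  pts <- as.matrix(pts)
  stopifnot(ncol(pts) == 3, nrow(pts) >= 2)
  ctr <- colMeans(pts)
  x <- sweep(pts, 2, ctr)
  # deterministic principal frame: singular vectors ordered by singular
  # value, sign fixed so the largest-magnitude loading is positive
  sv <- svd(x, nu = 0, nv = 3)
  v <- sv$v
  y <- x %*% v
  # intrinsic sign convention: flip each principal axis so the point with
  # the largest-magnitude projection projects positively -- this depends
  # only on the shape, not on its pose, so the search below sees an
  # identical landscape for any rigid motion of the input
  for (j in 1:3) {
    k <- which.max(abs(y[, j]))
    if (y[k, j] < 0) y[, j] <- -y[, j]
  }
  scale <- max(apply(y, 2, function(cc) diff(range(cc))), 1e-12)
  eps <- 1e-6 * scale
  obb_longest_edge_core(y, eps)
}

#' Measure one cilium trace
#'
#' @param pts Numeric n x 3 matrix (um), ordered along the cilium.
#' @param loop_arc_sep Minimum arc-length separation (um) between segment
#'   pairs eligible for the self-proximity measure (default 1); without
#'   it, neighbouring segments of any contiguous curve would count as
#'   self-proximal.
#' @return A one-row `data.frame`: `arc_length`, `end_to_end`,
#'   `length_proxy` (OBB longest edge), `tortuosity` (arc/chord, >= 1 up
#'   to numerical tolerance; `Inf` for closed shapes), and
#'   `min_self_distance` (minimum distance between segment pairs at least
#'   `loop_arc_sep` apart along the curve; `Inf` when no eligible pair).
#' @export
measureCilium <- function(pts, loop_arc_sep = 1) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 2) stop("a trace needs at least 2 points")
  if (!all(is.finite(pts))) stop("non-finite coordinates in trace")
  seg <- diff(pts)
  seg_len <- sqrt(rowSums(seg^2))
  if (all(seg_len == 0)) stop("degenerate trace: all points coincide")
  if (any(seg_len == 0)) {
    # drop repeated consecutive points rather than fail on digitization
    keep <- c(TRUE, seg_len > 0)
    pts <- pts[keep, , drop = FALSE]
    seg <- diff(pts)
    seg_len <- sqrt(rowSums(seg^2))
  }
  arc <- sum(seg_len)
  chord <- sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2))
  data.frame(arc_length = arc, end_to_end = chord,
             length_proxy = obbLongestEdge(pts),
             tortuosity = if (chord > 0) arc / chord else Inf,
             min_self_distance = polyline_self_distance(pts, loop_arc_sep))
}

#' Measure every cilium in a trace table
#'
#' @param traces Long-format trace `data.frame` as produced by
#'   [makeCilia()] / [readCiliaTraces()] (columns `cilium_id`, `mouse_id`,
#'   `genotype`, `point_index`, `x`, `y`, `z`, `unit`).
#' @return Per-cilium `data.frame`: ids and labels plus the
#'   [measureCilium()] columns.
#' @export
measureCilia <- function(traces) {
  req <- c("cilium_id", "mouse_id", "genotype", "point_index",
           "x", "y", "z")
  miss <- setdiff(req, names(traces))
  if (length(miss))
    stop("trace table missing columns: ", paste(miss, collapse = ", "))
  if (!"unit" %in% names(traces))
    stop("trace table must declare a 'unit' column (um)")
  if (!all(traces$unit %in% c("um", "µm")))
    stop("unsupported or mixed units in trace table; expected 'um'")
  sp <- split(traces, traces$cilium_id)
  rows <- lapply(sp, function(tr) {
    tr <- tr[order(tr$point_index), ]
    m <- measureCilium(as.matrix(tr[, c("x", "y", "z")]))
    cbind(data.frame(cilium_id = tr$cilium_id[1],
                     mouse_id = tr$mouse_id[1],
                     genotype = tr$genotype[1],
                     stringsAsFactors = FALSE), m)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify cilium morphology from tortuosity and self-proximity
#'
#' Operationalizes the straight / bent / contorted classes with explicit
#' rules: straight when `tortuosity < t1`; contorted when
#' `tortuosity >= t2` *or* two non-adjacent segments approach within
#' `loop_radius` um (loops and corkscrews); bent otherwise. Intervals are
#' half-open, so a cilium at exactly `t1` is bent.
#'
#' @param measures [measureCilia()] output.
#' @param t1 Straight/bent tortuosity boundary (default 1.05).
#' @param t2 Bent/contorted tortuosity boundary (default 1.5).
#' @param loop_radius Self-proximity radius in um (default 0.2).
#' @return `measures` with a `morphology` factor column
#'   (straight/bent/contorted); thresholds recorded as attributes.
#' @export
classifyMorphology <- function(measures, t1 = 1.05, t2 = 1.5,
                               loop_radius = 0.2) {
  tort <- measures$tortuosity
  loopy <- measures$min_self_distance < loop_radius
  cls <- ifelse(tort >= t2 | loopy, "contorted",
                ifelse(tort < t1, "straight", "bent"))
  measures$morphology <- factor(cls,
                                levels = c("straight", "bent", "contorted"))
  attr(measures, "thresholds") <- c(t1 = t1, t2 = t2,
                                    loop_radius = loop_radius)
  measures
}

#' Compare cilium length distributions between genotype groups
#'
#' Two-sample Kolmogorov-Smirnov test on per-cilium lengths (first two
#' genotype levels), one-way ANOVA of length by genotype at the cilium
#' level and at the mouse level (per-mouse means as the unit of analysis),
#' per-mouse mean lengths, and per-genotype morphology-class proportions
#' when a `morphology` column is present.
#'
#' @param measures [measureCilia()] output (optionally after
#'   [classifyMorphology()]).
#' @param value Column to compare (default `"length_proxy"`).
#' @return A list of class `"CiliaGroupComparison"`: `ks` (D, p and the
#'   two group labels), `anova_cilium` (F, p), `anova_mouse` (F, p),
#'   `mouse_means` data.frame, `class_proportions` (matrix or NULL),
#'   `n_per_group`.
#' @export
compareCiliaGroups <- function(measures, value = "length_proxy") {
  g <- factor(measures$genotype)
  if (nlevels(g) < 2) stop("need at least 2 genotype groups")
  if (any(table(g) < 2)) stop("every group needs at least 2 cilia")
  v <- measures[[value]]
  l1 <- levels(g)[1]; l2 <- levels(g)[2]
  ks <- suppressWarnings(stats::ks.test(v[g == l1], v[g == l2]))
  fit <- stats::aov(v ~ g)
  an <- summary(fit)[[1]]
  mouse_means <- stats::aggregate(
    list(mean_length = v),
    by = list(genotype = measures$genotype, mouse_id = measures$mouse_id),
    FUN = mean)
  an_m <- if (nrow(mouse_means) > nlevels(g) &&
              all(table(mouse_means$genotype) >= 2)) {
    summary(stats::aov(mean_length ~ factor(genotype),
                       data = mouse_means))[[1]]
  } else NULL
  props <- NULL
  if ("morphology" %in% names(measures)) {
    tab <- table(measures$genotype, measures$morphology)
    props <- prop.table(tab, margin = 1)
  }
  structure(list(
    ks = list(groups = c(l1, l2), D = unname(ks$statistic),
              p = ks$p.value),
    anova_cilium = list(F = an$`F value`[1], p = an$`Pr(>F)`[1]),
    anova_mouse = if (!is.null(an_m))
      list(F = an_m$`F value`[1], p = an_m$`Pr(>F)`[1]) else NULL,
    mouse_means = mouse_means,
    class_proportions = props,
    n_per_group = table(g),
    value = value), class = "CiliaGroupComparison")
}

#' @export
print.CiliaGroupComparison <- function(x, ...) {
  cat("Cilia group comparison on", x$value, "\n")
  cat(sprintf("  KS (%s vs %s): D = %.4f, p = %.3g\n", x$ks$groups[1],
              x$ks$groups[2], x$ks$D, x$ks$p))
  cat(sprintf("  one-way ANOVA (cilium level): F = %.3f, p = %.3g\n",
              x$anova_cilium$F, x$anova_cilium$p))
  if (!is.null(x$anova_mouse))
    cat(sprintf("  one-way ANOVA (mouse level) : F = %.3f, p = %.3g\n",
                x$anova_mouse$F, x$anova_mouse$p))
  if (!is.null(x$class_proportions)) {
    cat("  morphology proportions:\n")
    print(round(x$class_proportions, 3))
  }
  invisible(x)
}
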