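#' Generate synthetic 3D cilium traces for two (or more) genotype groups
#'
#' Each cilium is an ordered 3D polyline of `n_points` points with a total
#' arc length drawn Normal(length_mean, length_sd) per group (truncated at
#' `min_length`) and a tangent direction that performs an angular random
#' walk whose step size is set by the group's `curvature` level: curvature 0
#' gives perfectly straight traces (tortuosity exactly 1), large curvature
#' gives contorted, loop-prone traces. Cilia are assigned round-robin to
#' `n_mice` mice per genotype, mimicking the per-mouse structure of imaging
#' datasets.
#'
#' @param n_per_group Integer: cilia per group (>= 1), recycled across
#'   groups.
#' @param group_params Named list, one element per genotype label, each a
#'   list with `length_mean` (um), `length_sd` (um), `curvature`
#'   (dimensionless >= 0, radians of direction change per step at level 1).
#' @param seed Integer seed.
#' @param n_points Points per trace (default 21).
#' @param n_mice Mice per genotype (default 5).
#' @param min_length Truncation floor for drawn lengths in um
#'   (default 0.2).
#' @return A long-format `data.frame` with columns `cilium_id`, `mouse_id`,
#'   `genotype`, `point_index`, `x`, `y`, `z`, `unit` (always `"um"`), and
#'   the seed in `attr(, "seed")`.
#' @examples
#' tr <- makeCilia(5, list(ctrl = list(length_mean = 3, length_sd = 0.5,
#'                                     curvature = 0)), seed = 1)
#' @export
makeCilia <- function(n_per_group, group_params, seed = 1L, n_points = 21L,
                      n_mice = 5L, min_length = 0.2) {
  stopifnot(is.list(group_params), length(group_params) >= 1,
            !is.null(names(group_params)))
  n_per_group <- rep_len(as.integer(n_per_group), length(group_params))
  if (any(n_per_group < 1L)) stop("need at least one cilium per group")
  for (gp in group_params) {
    if (gp$length_mean <= 0 || gp$length_sd < 0)
      stop("group length parameters must be positive")
    if (gp$curvature < 0) stop("curvature must be >= 0")
  }
  set.seed(as.integer(seed))
  out <- vector("list", sum(n_per_group))
  idx <- 0L
  for (g in seq_along(group_params)) {
    gname <- names(group_params)[g]
    gp <- group_params[[g]]
    for (i in seq_len(n_per_group[g])) {
      idx <- idx + 1L
      L <- max(min_length, stats::rnorm(1, gp$length_mean, gp$length_sd))
      seg <- L / (n_points - 1L)
      # tangent random walk on the unit sphere
      d <- stats::rnorm(3); d <- d / sqrt(sum(d^2))
      dirs <- matrix(0, n_points - 1L, 3L)
      dirs[1L, ] <- d
      if (n_points > 2L) for (k in 2L:(n_points - 1L)) {
        if (gp$curvature > 0) {
          d <- d + gp$curvature * stats::rnorm(3)
          d <- d / sqrt(sum(d^2))
        }
        dirs[k, ] <- d
      }
      origin <- stats::runif(3, 0, 50)
      cum <- matrix(apply(dirs * seg, 2, cumsum), ncol = 3L)
      pts <- rbind(origin, sweep(cum, 2, origin, "+"))
      out[[idx]] <- data.frame(
        cilium_id = sprintf("%s_c%04d", gname, i),
        mouse_id = sprintf("%s_m%d", gname, ((i - 1L) %% n_mice) + 1L),
        genotype = gname,
        point_index = seq_len(n_points),
        x = pts[, 1], y = pts[, 2], z = pts[, 3],
        unit = "um",
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "seed") <- as.integer(seed)
  res
}
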