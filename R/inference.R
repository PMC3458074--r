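stack_maps <- function(maps) {
  vals <- lapply(maps, map_values)
  d <- dim(vals[[1]])
  for (v in vals) if (!identical(dim(v), d)) {
    stop("maps are not on a common grid", call. = FALSE)
  }
  list(x = do.call(rbind, lapply(vals, as.vector)), dims = d)
}

tmap_from_matrix <- function(x, dims, df) {
  n <- nrow(x)
  m <- colMeans(x)
  v <- colSums(x^2) - n * m^2
  v <- pmax(v, 0) / (n - 1)
  m2 <- colMeans(x^2)
  zero_var <- v <= 1e-14 * pmax(m2, 1e-300)
  tval <- numeric(length(m))
  ok <- !zero_var
  tval[ok] <- m[ok] / sqrt(v[ok] / n)
  out <- stat_map(array(tval, dims), kind = "t", df = df)
  attr(out, "n_zero_variance") <- sum(zero_var & m != 0)
  out
}

#' Voxelwise one-sample t map
#'
#' At each voxel computes `t = mean / (sd / sqrt(n))` across subjects,
#' with `df = n - 1` recorded on the map. Voxels with zero across-subject
#' variance get `t = 0`; those whose mean is nonzero (where the t would be
#' infinite) are counted in the `n_zero_variance` attribute.
#'
#' @param maps list of per-subject [stat_map]s (or 3D arrays) on a common
#'   grid; at least 3.
#' @return A [stat_map] of kind `"t"`.
#' @export
one_sample_tmap <- function(maps) {
  if (length(maps) < 3L) stop("need at least 3 subjects", call. = FALSE)
  s <- stack_maps(maps)
  tmap_from_matrix(s$x, s$dims, df = length(maps) - 1L)
}

#' Voxelwise paired-samples t map
#'
#' Computes a one-sample t map on the per-subject differences `a - b`;
#' the two lists must be subject-aligned.
#'
#' @param a_maps,b_maps equal-length, subject-aligned lists of maps.
#' @return A [stat_map] of kind `"t"` with `df = n - 1`.
#' @export
paired_tmap <- function(a_maps, b_maps) {
  if (length(a_maps) != length(b_maps)) {
    stop("paired lists differ in length (", length(a_maps), " vs ",
         length(b_maps), ")", call. = FALSE)
  }
  diffs <- Map(function(a, b) {
    check_same_grid(a, b)
    map_values(a) - map_values(b)
  }, a_maps, b_maps)
  one_sample_tmap(diffs)
}

#' Voxelwise independent-samples t map
#'
#' Pooled-variance two-sample t by default (`df = n1 + n2 - 2`), with
#' Welch's unequal-variance statistic available. The sign convention is
#' group 1 minus group 2. Voxels where both groups have zero variance get
#' `t = 0`.
#'
#' @param group1_maps,group2_maps lists of per-subject maps, at least 2
#'   subjects each.
#' @param var_equal logical; `TRUE` (default) for the pooled statistic,
#'   `FALSE` for Welch. With Welch the map's `df` slot holds the rounded
#'   median Satterthwaite df across voxels (voxelwise df are not stored).
#' @return A [stat_map] of kind `"t"`.
#' @export
two_sample_tmap <- function(group1_maps, group2_maps, var_equal = TRUE) {
  if (length(group1_maps) < 2L || length(group2_maps) < 2L) {
    stop("need at least 2 subjects per group", call. = FALSE)
  }
  s1 <- stack_maps(group1_maps)
  s2 <- stack_maps(group2_maps)
  if (!identical(s1$dims, s2$dims)) stop("group grids differ", call. = FALSE)
  n1 <- nrow(s1$x); n2 <- nrow(s2$x)
  m1 <- colMeans(s1$x); m2 <- colMeans(s2$x)
  v1 <- pmax(colSums(s1$x^2) - n1 * m1^2, 0) / (n1 - 1)
  v2 <- pmax(colSums(s2$x^2) - n2 * m2^2, 0) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2L
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df_vox <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    df <- as.integer(round(stats::median(df_vox, na.rm = TRUE)))
  }
  tval <- numeric(length(m1))
  ok <- se > 0
  tval[ok] <- (m1[ok] - m2[ok]) / se[ok]
  out <- stat_map(array(tval, s1$dims), kind = "t", df = df)
  attr(out, "n_zero_variance") <- sum(!ok & m1 != m2)
  out
}

#' Two-sample pooled t test from summary statistics
#'
#' Computes the independent-samples t test (pooled variance by default,
#' Welch optionally) from printed group means, SDs and sizes -- the scalar
#' analogue of [two_sample_tmap()], useful for checking reported group
#' comparisons from their summary statistics alone.
#'
#' @param mean1,sd1,n1 first group's mean, SD, size.
#' @param mean2,sd2,n2 second group's mean, SD, size.
#' @param var_equal pooled (`TRUE`, default) or Welch.
#' @return List with `statistic`, `df`, `p.value` (two-tailed).
#' @export
two_sample_t_from_stats <- function(mean1, sd1, n1, mean2, sd2, n2,
                                    var_equal = TRUE) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (var_equal) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(sd1^2 / n1 + sd2^2 / n2)
    df <- se^4 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  }
  tval <- (mean1 - mean2) / se
  list(statistic = tval, df = df, p.value = 2 * stats::pt(-abs(tval), df))
}

#' One-sample t test from summary statistics
#'
#' @param mean,sd,n sample mean, SD and size.
#' @param mu null value (default 0).
#' @return List with `statistic`, `df`, `p.value` (two-tailed).
#' @export
one_sample_t_from_stats <- function(mean, sd, n, mu = 0) {
  stopifnot(n >= 2, sd > 0)
  tval <- (mean - mu) / (sd / sqrt(n))
  list(statistic = tval, df = n - 1,
       p.value = 2 * stats::pt(-abs(tval), n - 1))
}
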