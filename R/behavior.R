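#' Stroop interference effect
#'
#' The executive-control cost: incongruent-condition completion time minus
#' color-naming completion time, in seconds.
#'
#' @param color_naming_time,incongruent_time completion times (s), > 0.
#' @return `incongruent_time - color_naming_time` (vectorized).
#' @export
stroop_interference <- function(color_naming_time, incongruent_time) {
  if (any(color_naming_time <= 0, na.rm = TRUE) ||
      any(incongruent_time <= 0, na.rm = TRUE)) {
    stop("completion times must be positive", call. = FALSE)
  }
  incongruent_time - color_naming_time
}

#' Pearson chi-square test for a 2x2 table
#'
#' The uncorrected (no continuity correction) Pearson chi-square with one
#' degree of freedom, via the closed form
#' `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`.
#'
#' @param tab 2x2 matrix of counts.
#' @return List with `statistic`, `df` (= 1), `p.value`.
#' @export
chi_square_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0))
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (any(rs == 0) || any(cs == 0)) {
    stop("zero marginal: every row and column needs a positive total",
         call. = FALSE)
  }
  expected <- outer(rs, cs) / n
  if (any(expected <= 0)) stop("expected counts must be positive", call. = FALSE)
  stat <- n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
    (rs[1] * rs[2] * cs[1] * cs[2])
  stat <- unname(stat)
  list(statistic = stat, df = 1L,
       p.value = stats::pchisq(stat, 1L, lower.tail = FALSE))
}

#' Mean map value inside a sphere around a peak voxel
#'
#' Extracts, for every subject, the mean of the map over all voxels whose
#' centers lie within `radius_mm` (Euclidean distance, inclusive) of the
#' center voxel's center. On a 3 mm grid a 3 mm radius therefore picks the
#' center voxel and its six face neighbors (a 7-voxel cross), because the
#' neighbors sit at exactly the radius.
#'
#' @param maps list of per-subject [stat_map]s or 3D arrays.
#' @param center integer length-3 voxel index (1-based) of the sphere
#'   center; must lie inside the grid.
#' @param radius_mm sphere radius in mm, `>= 0`.
#' @param voxel_size_mm voxel edge length in mm.
#' @return Numeric vector, one mean per subject.
#' @export
sphere_roi_values <- function(maps, center, radius_mm = 3, voxel_size_mm = 3) {
  stopifnot(length(center) == 3L, radius_mm >= 0)
  dims <- dim(map_values(maps[[1]]))
  if (any(center < 1) || any(center > dims)) {
    stop("sphere center lies outside the grid", call. = FALSE)
  }
  rad_vox <- floor(radius_mm / voxel_size_mm)
  offs <- as.matrix(expand.grid(i = -rad_vox:rad_vox, j = -rad_vox:rad_vox,
                                k = -rad_vox:rad_vox))
  dist <- sqrt(rowSums(offs^2)) * voxel_size_mm
  offs <- offs[dist <= radius_mm + 1e-9, , drop = FALSE]
  pts <- sweep(offs, 2L, as.integer(center), `+`)
  inside <- pts[, 1] >= 1 & pts[, 1] <= dims[1] &
            pts[, 2] >= 1 & pts[, 2] <= dims[2] &
            pts[, 3] >= 1 & pts[, 3] <= dims[3]
  pts <- pts[inside, , drop = FALSE]
  vapply(maps, function(m) mean(map_values(m)[pts]), 0)
}

#' Direction of a group effect within a region
#'
#' For a region showing a between-group difference, determines the sign of
#' the underlying connectivity in each group: per subject the mean map
#' value over the region is extracted, then a one-sample t test against
#' zero is run per group. The sign of the group mean gives the direction
#' (e.g. whether a reduced connection was positive or negative to begin
#' with); when the test is not significant the direction is flagged
#' unreliable.
#'
#' @param maps list of per-subject maps.
#' @param region_mask logical 3D array, non-empty.
#' @param groups character vector of group labels, one per subject.
#' @param alpha significance level for the reliability flag.
#' @return Data frame: `group`, `n`, `mean`, `t`, `df`, `p`, `sign`,
#'   `reliable`.
#' @export
posthoc_region_direction <- function(maps, region_mask, groups, alpha = 0.05) {
  region_mask <- array(as.logical(region_mask), dim(region_mask))
  if (!any(region_mask)) stop("region mask is empty", call. = FALSE)
  stopifnot(length(groups) == length(maps))
  vals <- vapply(maps, function(m) mean(map_values(m)[region_mask]), 0)
  rows <- lapply(unique(groups), function(g) {
    x <- vals[groups == g]
    if (length(x) < 2L) {
      stop("group '", g, "' has fewer than 2 subjects", call. = FALSE)
    }
    tt <- one_sample_t_from_stats(mean(x), stats::sd(x), length(x))
    data.frame(group = g, n = length(x), mean = mean(x), t = tt$statistic,
               df = tt$df, p = tt$p.value, sign = sign(mean(x)),
               reliable = tt$p.value < alpha)
  })
  do.call(rbind, rows)
}

#' Pearson correlation between an imaging and a clinical measure
#'
#' Pairwise-complete Pearson correlation with the two-tailed p value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom, and
#' a Bonferroni-adjusted p (`min(1, m_tests * p)`) for use when the pair
#' is one of a family of tested pairs.
#'
#' @param imaging,clinical per-subject numeric vectors of equal length;
#'   incomplete pairs are dropped (count reported).
#' @param m_tests number of tests in the family (default 1).
#' @return One-row data frame: `r`, `n`, `n_dropped`, `t`, `p`,
#'   `p_bonferroni`.
#' @export
correlate <- function(imaging, clinical, m_tests = 1L) {
  if (length(imaging) != length(clinical)) {
    stop("imaging and clinical vectors differ in length (", length(imaging),
         " vs ", length(clinical), ")", call. = FALSE)
  }
  ok <- stats::complete.cases(imaging, clinical)
  x <- imaging[ok]; y <- clinical[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs (got ", n, ")", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in one of the measures", call. = FALSE)
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    tval <- Inf * sign(r)
    p <- 0
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tval), n - 2)
  }
  data.frame(r = r, n = n, n_dropped = sum(!ok), t = tval,
             p = p, p_bonferroni = min(1, m_tests * p))
}

#' Imaging-behavior correlation report
#'
#' Runs [correlate()] for every combination of the supplied imaging
#' measures and clinical measures, Bonferroni-adjusting over the full
#' family of tested pairs.
#'
#' @param imaging named list of per-subject imaging vectors.
#' @param clinical named list (or data frame) of per-subject clinical
#'   vectors.
#' @return Data frame, one row per (imaging, clinical) pair.
#' @export
correlation_report <- function(imaging, clinical) {
  clinical <- as.list(clinical)
  m <- length(imaging) * length(clinical)
  rows <- list()
  for (im in names(imaging)) {
    for (cl in names(clinical)) {
      row <- correlate(imaging[[im]], clinical[[cl]], m_tests = m)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(imaging = im, clinical = cl), row)
    }
  }
  do.call(rbind, rows)
}

#' Group comparison table for behavioral variables
#'
#' The demographics/behavior table of a two-group study: a pooled
#' two-sample t test (two-tailed) per continuous variable and an
#' uncorrected chi-square for the sex split. Variables missing from the
#' table are skipped and reported in the `skipped` attribute; missing
#' values are dropped per variable.
#'
#' @param behavior data frame with a `group` column, optionally `sex`
#'   (female coded `"F"`), and numeric variables.
#' @param variables continuous variables to compare; defaults to all
#'   numeric columns present in both groups.
#' @return Data frame: `variable`, `mean_1`, `sd_1`, `mean_2`, `sd_2`,
#'   `statistic`, `df`, `p` (group order = order of first appearance).
#' @export
group_compare_table <- function(behavior, variables = NULL) {
  gs <- unique(behavior$group)
  if (length(gs) != 2L) stop("exactly two groups required", call. = FALSE)
  if (any(table(behavior$group) < 2L)) {
    stop("need at least 2 subjects per group", call. = FALSE)
  }
  if (is.null(variables)) {
    variables <- setdiff(names(behavior)[vapply(behavior, is.numeric, TRUE)],
                         c("subject"))
  }
  skipped <- character(0)
  rows <- list()
  if ("sex" %in% names(behavior)) {
    tab <- rbind(
      c(sum(behavior$sex[behavior$group == gs[1]] == "F"),
        sum(behavior$sex[behavior$group == gs[1]] != "F")),
      c(sum(behavior$sex[behavior$group == gs[2]] == "F"),
        sum(behavior$sex[behavior$group == gs[2]] != "F")))
    cs <- tryCatch(chi_square_2x2(tab), error = function(e) NULL)
    if (is.null(cs)) {
      skipped <- c(skipped, "sex_female")
    } else {
      rows[[1L]] <- data.frame(variable = "sex_female", mean_1 = tab[1, 1],
                               sd_1 = NA, mean_2 = tab[2, 1], sd_2 = NA,
                               statistic = cs$statistic, df = 1, p = cs$p.value)
    }
  }
  for (v in variables) {
    if (!v %in% names(behavior)) { skipped <- c(skipped, v); next }
    x1 <- behavior[[v]][behavior$group == gs[1]]
    x2 <- behavior[[v]][behavior$group == gs[2]]
    x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
    if (length(x1) < 2L || length(x2) < 2L ||
        (stats::sd(x1) == 0 && stats::sd(x2) == 0)) {
      skipped <- c(skipped, v); next
    }
    tt <- two_sample_t_from_stats(mean(x1), stats::sd(x1), length(x1),
                                  mean(x2), stats::sd(x2), length(x2))
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, mean_1 = mean(x1), sd_1 = stats::sd(x1),
      mean_2 = mean(x2), sd_2 = stats::sd(x2),
      statistic = tt$statistic, df = tt$df, p = tt$p.value)
  }
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- skipped
  out
}
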