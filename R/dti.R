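#' Fractional anisotropy from diffusion-tensor eigenvalues
#'
#' Computes the standard FA index per voxel:
#' `FA = sqrt(3/2) * sqrt(sum((lambda_i - mean(lambda))^2)) / sqrt(sum(lambda_i^2))`,
#' which is 0 for an isotropic tensor and 1 for a fully anisotropic one,
#' and is invariant under rescaling of the eigenvalues. Voxels whose
#' eigenvalues are all zero get FA = 0.
#'
#' @param eigen_img 4D numeric array with the three eigenvalues in the
#'   last dimension (`lambda1 >= lambda2 >= lambda3 >= 0` inside the
#'   mask), units mm^2/s.
#' @param mask optional logical 3D array; FA is computed inside the mask
#'   (0 outside). Default: everywhere.
#' @return 3D numeric array of FA values in `[0, 1]`.
#' @export
fa_from_eigenvalues <- function(eigen_img, mask = NULL) {
  d <- dim(eigen_img)
  stopifnot(length(d) == 4L, d[4] == 3L)
  nv <- prod(d[1:3])
  lam <- matrix(eigen_img, nv, 3L)
  vox <- if (is.null(mask)) seq_len(nv) else which(array(as.logical(mask), d[1:3]))
  lam <- lam[vox, , drop = FALSE]
  n_neg <- sum(rowSums(lam < 0) > 0)
  if (n_neg > 0L) {
    stop("negative eigenvalues at ", n_neg, " voxels", call. = FALSE)
  }
  if (any(lam[, 1] < lam[, 2] | lam[, 2] < lam[, 3])) {
    stop("eigenvalues must be ordered lambda1 >= lambda2 >= lambda3",
         call. = FALSE)
  }
  lbar <- rowMeans(lam)
  num <- rowSums((lam - lbar)^2)
  den <- rowSums(lam^2)
  fa <- numeric(nrow(lam))
  ok <- den > 0
  fa[ok] <- sqrt(3 / 2) * sqrt(num[ok]) / sqrt(den[ok])
  out <- array(0, d[1:3])
  out[vox] <- fa
  out
}

#' Threshold a mean FA map into a skeleton-style mask
#'
#' Retains voxels whose mean FA exceeds the threshold, the rule used to
#' exclude gray-matter/CSF or high-variability voxels from a white-matter
#' skeleton (conventional threshold 0.2).
#'
#' @param mean_fa 3D numeric array, the across-subject mean FA map.
#' @param threshold FA threshold in (0, 1).
#' @return Logical 3D array: `mean_fa > threshold`.
#' @export
fa_skeleton_mask <- function(mean_fa, threshold = 0.2) {
  stopifnot(threshold > 0, threshold < 1)
  mean_fa > threshold
}

#' Mean FA over an ROI
#'
#' @param fa_map 3D numeric FA array.
#' @param roi_mask logical 3D array, non-empty.
#' @return Scalar mean FA over the ROI voxels.
#' @export
roi_mean_fa <- function(fa_map, roi_mask) {
  roi_mask <- array(as.logical(roi_mask), dim(roi_mask))
  check_same_grid(fa_map, roi_mask)
  if (!any(roi_mask)) stop("ROI mask is empty", call. = FALSE)
  mean(fa_map[roi_mask])
}

#' Hemispheric asymmetry index
#'
#' `AI = (right - left) / (0.5 * (right + left))`: negative values
#' indicate leftward (left greater than right) asymmetry, positive values
#' rightward. For positive inputs the index is bounded in (-2, 2).
#'
#' @param right,left scalar (or vector) measurements, e.g. ROI mean FA;
#'   `right + left` must be positive.
#' @return The asymmetry index (vectorized).
#' @export
asymmetry_index <- function(right, left) {
  if (any(right + left <= 0)) {
    stop("`right + left` must be positive", call. = FALSE)
  }
  (right - left) / (0.5 * (right + left))
}

#' Per-subject FA summary with asymmetry index
#'
#' Builds the per-subject table of left-ROI mean FA, right-ROI mean FA and
#' their asymmetry index, either from a `fa_dataset` table or from
#' per-subject FA maps plus ROI masks.
#'
#' @param fa either a `fa_dataset` (from [generate_fa()]), a data frame
#'   with columns `subject`, `group`, `left_fa`, `right_fa`, or a list of
#'   per-subject 3D FA arrays.
#' @param rois list with `left` and `right` masks (required when `fa` is a
#'   list of maps).
#' @param groups group labels (required when `fa` is a list of maps).
#' @return Data frame: `subject`, `group`, `left_fa`, `right_fa`, `ai`.
#' @export
fa_summary <- function(fa, rois = NULL, groups = NULL) {
  if (inherits(fa, "fa_dataset")) {
    tab <- fa$table
  } else if (is.data.frame(fa)) {
    tab <- fa
  } else {
    stopifnot(!is.null(rois), !is.null(groups), length(groups) == length(fa))
    tab <- data.frame(subject = sprintf("dti-%03d", seq_along(fa)),
                      group = groups,
                      left_fa = vapply(fa, roi_mean_fa, 0, roi_mask = rois$left),
                      right_fa = vapply(fa, roi_mean_fa, 0, roi_mask = rois$right))
  }
  stopifnot(all(c("subject", "group", "left_fa", "right_fa") %in% names(tab)))
  tab$ai <- asymmetry_index(tab$right_fa, tab$left_fa)
  tab
}

#' Group tests on FA summaries
#'
#' Runs the standard battery on a per-subject FA summary: independent-
#' samples pooled-variance t tests between the two groups on left-ROI FA,
#' right-ROI FA and the asymmetry index, plus a one-sample t test of the
#' asymmetry index against zero within each group (the laterality test).
#' All p values are two-tailed.
#'
#' @param summaries data frame from [fa_summary()] (columns `group`,
#'   `left_fa`, `right_fa`, `ai`).
#' @param var_equal pooled (`TRUE`, default) or Welch between-group tests.
#' @return Data frame with columns `test`, `measure`, `group`, `estimate`,
#'   `t`, `df`, `p`.
#' @export
group_fa_tests <- function(summaries, var_equal = TRUE) {
  gs <- unique(summaries$group)
  if (length(gs) != 2L) stop("exactly two groups required", call. = FALSE)
  if (any(table(summaries$group) < 2L)) {
    stop("need at least 2 subjects per group", call. = FALSE)
  }
  rows <- list()
  for (measure in c("left_fa", "right_fa", "ai")) {
    x1 <- summaries[[measure]][summaries$group == gs[1]]
    x2 <- summaries[[measure]][summaries$group == gs[2]]
    tt <- two_sample_t_from_stats(mean(x1), stats::sd(x1), length(x1),
                                  mean(x2), stats::sd(x2), length(x2),
                                  var_equal = var_equal)
    rows[[length(rows) + 1L]] <- data.frame(
      test = "between-group", measure = measure, group = paste(gs, collapse = " vs "),
      estimate = mean(x1) - mean(x2), t = tt$statistic, df = tt$df, p = tt$p.value)
  }
  for (g in gs) {
    x <- summaries$ai[summaries$group == g]
    tt <- one_sample_t_from_stats(mean(x), stats::sd(x), length(x))
    rows[[length(rows) + 1L]] <- data.frame(
      test = "one-sample-ai", measure = "ai", group = g,
      estimate = mean(x), t = tt$statistic, df = tt$df, p = tt$p.value)
  }
  do.call(rbind, rows)
}
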