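#' Mean timeseries over a seed ROI
#'
#' The seed signal is the unweighted arithmetic mean, at each timepoint,
#' of the series of every voxel inside the mask.
#'
#' @param bold 4D numeric array, time last.
#' @param mask logical 3D array, non-empty, same grid as `bold`.
#' @return Numeric vector of length `dim(bold)[4]`.
#' @export
seed_timeseries <- function(bold, mask) {
  stopifnot(length(dim(bold)) == 4L)
  mask <- array(as.logical(mask), dim(mask))
  if (!identical(dim(mask), dim(bold)[1:3])) {
    stop("mask grid does not match the BOLD grid", call. = FALSE)
  }
  vox <- which(mask)
  if (length(vox) == 0L) stop("seed mask is empty", call. = FALSE)
  d <- dim(bold)
  colMeans(matrix(bold, prod(d[1:3]), d[4])[vox, , drop = FALSE])
}

#' Voxelwise Pearson correlation with a seed series
#'
#' Correlates every voxel's timeseries with the seed series. Voxels with
#' constant series get `r = 0`; their count is attached as the
#' `n_constant` attribute of the returned map.
#'
#' @param bold 4D numeric array, time last.
#' @param seed_series numeric vector, one value per timepoint; must not be
#'   constant.
#' @param side optional seed-side tag for the result.
#' @return A [stat_map] of kind `"r"`.
#' @export
correlation_map <- function(bold, seed_series, side = NULL) {
  d <- dim(bold)
  stopifnot(length(d) == 4L)
  n_t <- d[4]
  if (n_t < 3L) stop("need at least 3 timepoints", call. = FALSE)
  if (length(seed_series) != n_t) {
    stop("seed series length ", length(seed_series), " != ", n_t,
         " timepoints", call. = FALSE)
  }
  s <- seed_series - mean(seed_series)
  ss <- sqrt(sum(s^2))
  if (ss == 0) stop("seed series is constant", call. = FALSE)
  x <- matrix(bold, prod(d[1:3]), n_t)
  x <- x - rowMeans(x)
  denom <- sqrt(rowSums(x^2)) * ss
  r <- as.numeric(x %*% s)
  const <- denom == 0
  r[!const] <- r[!const] / denom[!const]
  r[const] <- 0
  r <- pmin(1, pmax(-1, r))  # guard rounding at |r| = 1
  out <- stat_map(array(r, d[1:3]), kind = "r", side = side)
  attr(out, "n_constant") <- sum(const)
  out
}

#' Fisher r-to-Z transformation
#'
#' Applies `z = atanh(r)` elementwise. Correlations at exactly +/-1 are
#' clipped to +/-(1 - 1e-7) before the transform so the map stays finite;
#' the number of clipped voxels is attached as the `n_clipped` attribute.
#'
#' @param map a [stat_map] of kind `"r"`.
#' @return A [stat_map] of kind `"z"` with the same side tag.
#' @export
fisher_z <- function(map) {
  if (!inherits(map, "stat_map") || map$kind != "r") {
    stop("`map` must be a stat_map of kind 'r'", call. = FALSE)
  }
  r <- map$values
  clip <- 1 - 1e-7
  n_clipped <- sum(abs(r) > clip)
  r <- pmin(pmax(r, -clip), clip)  # argument order keeps the dim attribute
  out <- stat_map(atanh(r), kind = "z", side = map$side)
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Per-subject hemispheric asymmetry contrast
#'
#' Subtracts the left-right-flipped right-seed Z-map from the left-seed
#' Z-map, voxel by voxel, producing the per-subject contrast whose
#' right-hemisphere half compares each seed with its ipsilateral
#' hemisphere and whose left half compares each seed with its
#' contralateral hemisphere.
#'
#' @param z_left left-seed [stat_map] (kind `"z"`, side `"left-seed"`).
#' @param z_right right-seed [stat_map] (kind `"z"`, side `"right-seed"`);
#'   flipped internally.
#' @return A [stat_map] of kind `"diff"`, side `"contrast"`.
#' @export
asymmetry_contrast <- function(z_left, z_right) {
  stopifnot(inherits(z_left, "stat_map"), inherits(z_right, "stat_map"))
  check_same_grid(z_left, z_right)
  if (!is.null(z_left$side) && z_left$side != "left-seed") {
    stop("`z_left` must carry side 'left-seed'", call. = FALSE)
  }
  if (!is.null(z_right$side) && z_right$side != "right-seed") {
    stop("`z_right` must carry side 'right-seed' (it is flipped internally)",
         call. = FALSE)
  }
  stat_map(z_left$values - lr_flip(z_right$values), kind = "diff",
           side = "contrast")
}

#' Seed-based Z-maps for every subject of a dataset
#'
#' Convenience wrapper running the standard per-subject chain: clean the
#' BOLD volume, extract the left- and right-seed mean series, correlate,
#' and Fisher-transform. Returns, per subject, the left-seed Z-map, the
#' right-seed Z-map, and their asymmetry contrast.
#'
#' @param dataset a `bold_dataset` from [generate_bold()] (or any list with
#'   `subjects` and a `seed` [roi_pair]).
#' @param spec a [cleaning_spec()]; `NULL` to skip cleaning.
#' @return List with per-subject lists `z_left`, `z_right`, `contrast`,
#'   plus `group` (character vector of group labels).
#' @export
subject_zmaps <- function(dataset, spec = cleaning_spec()) {
  seed <- dataset$seed
  maps <- lapply(dataset$subjects, function(sub) {
    bold <- if (is.null(spec)) sub$bold else clean_bold(sub$bold, spec)
    zl <- fisher_z(correlation_map(bold, seed_timeseries(bold, seed$left),
                                   side = "left-seed"))
    zr <- fisher_z(correlation_map(bold, seed_timeseries(bold, seed$right),
                                   side = "right-seed"))
    list(z_left = zl, z_right = zr, contrast = asymmetry_contrast(zl, zr))
  })
  list(z_left = lapply(maps, `[[`, "z_left"),
       z_right = lapply(maps, `[[`, "z_right"),
       contrast = lapply(maps, `[[`, "contrast"),
       group = vapply(dataset$subjects, `[[`, "", "group"))
}
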