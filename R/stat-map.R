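#' Statistical map on a 3D voxel grid
#'
#' A `stat_map` wraps a 3D array of voxel values together with a `kind` tag
#' saying what the values are (Pearson `"r"`, Fisher `"z"`, Student `"t"`, a
#' `"diff"`erence of z values, or a `"binary"` mask), the degrees of freedom
#' where the kind calls for them, and a `side` tag recording which seed the
#' map belongs to (`"left-seed"`, `"right-seed"`, `"flipped-right-seed"`,
#' `"contrast"`).
#'
#' @param values 3D numeric array of voxel values.
#' @param kind one of `"r"`, `"z"`, `"t"`, `"diff"`, `"binary"`.
#' @param df degrees of freedom (required downstream for `kind = "t"`).
#' @param side optional seed-side tag.
#'
#' @return An object of class `stat_map`.
#' @export
stat_map <- function(values, kind = c("r", "z", "t", "diff", "binary"),
                     df = NULL, side = NULL) {
  kind <- match.arg(kind)
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3D array", call. = FALSE)
  }
  storage.mode(values) <- "double"
  if (kind == "r" && any(abs(values) > 1 + 1e-12, na.rm = TRUE)) {
    stop("r-kind values must lie in [-1, 1]", call. = FALSE)
  }
  if (kind == "binary" && !all(values %in% c(0, 1))) {
    stop("binary-kind values must be 0 or 1", call. = FALSE)
  }
  if (!is.null(side)) {
    side <- match.arg(side,
                      c("left-seed", "right-seed", "flipped-right-seed", "contrast"))
  }
  structure(list(values = values, kind = kind,
                 df = if (!is.null(df)) as.integer(df) else NULL,
                 side = side),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<stat_map> kind=%s grid=%dx%dx%d%s%s\n", x$kind, d[1], d[2], d[3],
              if (!is.null(x$df)) sprintf(" df=%d", x$df) else "",
              if (!is.null(x$side)) sprintf(" side=%s", x$side) else ""))
  cat(sprintf("  range [%.4g, %.4g], %d nonzero voxels\n",
              min(x$values), max(x$values), sum(x$values != 0)))
  invisible(x)
}

#' @export
as.array.stat_map <- function(x, ...) x$values

map_values <- function(x) {
  if (inherits(x, "stat_map")) x$values else x
}

check_same_grid <- function(a, b) {
  if (!identical(dim(map_values(a)), dim(map_values(b)))) {
    stop("grids do not match: ", paste(dim(map_values(a)), collapse = "x"),
         " vs ", paste(dim(map_values(b)), collapse = "x"), call. = FALSE)
  }
  invisible(TRUE)
}

#' Mirror a volume or statistical map across the left-right midline
#'
#' Flips the first array axis, which the package convention takes to be the
#' left-right axis of a symmetric grid. The flip is a pure index
#' permutation: the value at index `i` moves to `N - 1 - i` (0-based), so it
#' is its own inverse and introduces no interpolation. The grid extent along
#' the flip axis must be even so that every voxel has a mirror partner and
#' no voxel straddles the midline.
#'
#' For a `stat_map` the `side` tag is updated: a right-seed map becomes a
#' flipped-right-seed map and vice versa.
#'
#' @param x a 3D array, 4D array (flip applied per volume), or `stat_map`.
#' @return Object of the same type, mirrored.
#' @export
lr_flip <- function(x) UseMethod("lr_flip")

#' @export
lr_flip.array <- function(x) {
  d <- dim(x)
  if (d[1] %% 2L != 0L) {
    stop("flip-axis extent must be even (got ", d[1], ")", call. = FALSE)
  }
  if (length(d) == 3L) {
    x[d[1]:1, , , drop = FALSE]
  } else if (length(d) == 4L) {
    x[d[1]:1, , , , drop = FALSE]
  } else {
    stop("lr_flip expects a 3D or 4D array", call. = FALSE)
  }
}

#' @export
lr_flip.stat_map <- function(x) {
  side <- x$side
  flipped_side <- switch(
    side %||% "none",
    "right-seed" = "flipped-right-seed",
    "flipped-right-seed" = "right-seed",
    side
  )
  stat_map(lr_flip(x$values), kind = x$kind, df = x$df, side = flipped_side)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Left/right pair of mirror-image ROI masks
#'
#' Bundles a left-hemisphere binary mask with its right-hemisphere
#' counterpart and enforces the package's symmetric-grid contract: the right
#' mask must equal the left mask mirrored across the midline exactly, both
#' masks must be non-empty, and they must not overlap.
#'
#' @param left logical/0-1 3D array, the left-hemisphere mask.
#' @param right optional right-hemisphere mask; defaults to `lr_flip(left)`.
#' @return An object of class `roi_pair` with elements `left` and `right`.
#' @export
roi_pair <- function(left, right = NULL) {
  left <- array(as.logical(left), dim(left))
  if (is.null(right)) right <- lr_flip(left)
  right <- array(as.logical(right), dim(right))
  check_same_grid(left, right)
  if (!any(left)) stop("left mask is empty", call. = FALSE)
  if (!identical(right, lr_flip(left))) {
    stop("right mask is not the exact mirror image of the left mask",
         call. = FALSE)
  }
  if (any(left & right)) stop("left and right masks overlap", call. = FALSE)
  structure(list(left = left, right = right), class = "roi_pair")
}

#' @export
print.roi_pair <- function(x, ...) {
  cat(sprintf("<roi_pair> %d voxels per side on %s grid\n", sum(x$left),
              paste(dim(x$left), collapse = "x")))
  invisible(x)
}

#' Build a rectangular box mask
#'
#' Convenience constructor for synthetic ROI masks: a box of voxels given by
#' inclusive index ranges along each axis.
#'
#' @param dims grid dimensions (length 3).
#' @param i,j,k inclusive index ranges (vectors of indices) along each axis.
#' @return Logical 3D array.
#' @export
box_mask <- function(dims, i, j, k) {
  if (any(i < 1 | i > dims[1]) || any(j < 1 | j > dims[2]) ||
      any(k < 1 | k > dims[3])) {
    stop("box indices fall outside the grid", call. = FALSE)
  }
  m <- array(FALSE, dims)
  m[i, j, k] <- TRUE
  m
}

#' Convert a cluster extent in voxels to a volume in mm^3
#'
#' @param n_voxels integer vector of cluster extents.
#' @param voxel_size_mm isotropic voxel edge length in mm (default 3, giving
#'   27 mm^3 per voxel).
#' @return Numeric vector of volumes in mm^3.
#' @export
#' @examples
#' voxels_to_mm3(c(14, 13, 10))  # 378 351 270
voxels_to_mm3 <- function(n_voxels, voxel_size_mm = 3) {
  n_voxels * voxel_size_mm^3
}
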