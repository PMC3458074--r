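#' Read a NIfTI volume
#'
#' Reads a NIfTI-1 file and returns the image as an array with its affine
#' available via `RNifti::xform()`. Volumes containing non-finite values
#' are rejected.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return An `RNifti` `niftiImage` (a numeric array subclass).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  if (any(!is.finite(img))) {
    stop("volume contains non-finite values: ", path, call. = FALSE)
  }
  img
}

#' Write a NIfTI volume
#'
#' Writes a 3D or 4D array as NIfTI-1 with an RAS diagonal affine at the
#' given isotropic voxel size, stored as float64 so that a write-read
#' round trip is bit-exact.
#'
#' @param x numeric array (3D or 4D), [stat_map], or logical mask (written
#'   as uint8).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm isotropic voxel edge length in mm.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, voxel_size_mm = 3) {
  if (inherits(x, "stat_map")) x <- x$values
  d <- dim(x)
  dt <- if (is.logical(x)) {
    x <- array(as.integer(x), d)
    "uint8"
  } else "double"
  # full 8-element header pixdim: qfac, then spatial (and time) steps
  pix8 <- c(1, rep(voxel_size_mm, 3L), rep(1, 4L))
  img <- RNifti::asNifti(x, reference = list(pixdim = pix8), datatype = dt)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Check that a set of NIfTI files share one affine
#'
#' @param paths character vector of NIfTI paths.
#' @param tol absolute tolerance on affine entries.
#' @return `TRUE` invisibly; errors naming the first offending file.
#' @export
assert_consistent_affines <- function(paths, tol = 1e-5) {
  stopifnot(length(paths) >= 1L)
  ref <- RNifti::xform(RNifti::niftiHeader(paths[1]))
  for (p in paths[-1]) {
    a <- RNifti::xform(RNifti::niftiHeader(p))
    if (max(abs(a - ref)) > tol) {
      stop("affine of '", p, "' does not match '", paths[1], "'",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Read a tab-separated table with required columns
#'
#' @param path path to a TSV file with a header row.
#' @param required character vector of column names that must be present.
#' @return Data frame.
#' @export
read_table_tsv <- function(path, required = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop("table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab
}

#' Write a data frame as tab-separated UTF-8 with a header row
#'
#' @param tab data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a cluster table as TSV with 0-based voxel indices
#'
#' The on-disk convention uses 0-based `peak_i/j/k` indices (the in-memory
#' tables are 1-based, following R).
#'
#' @param clusters cluster data frame from [correct_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(clusters, path) {
  out <- clusters
  for (cc in c("peak_i", "peak_j", "peak_k")) out[[cc]] <- out[[cc]] - 1L
  write_table_tsv(out, path)
}

#' Write a dataset manifest
#'
#' Records, in YAML, the subjects, group labels, file paths and generator
#' seed of a written dataset.
#'
#' @param manifest named list (subjects, groups, paths, seed, ...).
#' @param path output path (e.g. `manifest.yaml`).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' @param path path to a YAML file of pipeline parameters (see
#'   [run_pipeline()] for recognized fields).
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

#' Write a generated BOLD dataset to disk
#'
#' Writes each subject's 4D BOLD as NIfTI, the seed and target masks as
#' uint8 NIfTI, and a YAML manifest listing subjects, groups, paths and
#' the generator seed.
#'
#' @param dataset a `bold_dataset` from [generate_bold()].
#' @param dir output directory (created if needed).
#' @return The manifest list, invisibly.
#' @export
write_bold_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vs <- dataset$config$voxel_size_mm
  paths <- vapply(dataset$subjects, function(sub) {
    p <- file.path(dir, paste0(sub$id, "_bold.nii.gz"))
    write_volume(sub$bold, p, vs)
    p
  }, "")
  write_volume(dataset$seed$left, file.path(dir, "seed_left.nii.gz"), vs)
  write_volume(dataset$seed$right, file.path(dir, "seed_right.nii.gz"), vs)
  for (nm in names(dataset$rois)) {
    write_volume(dataset$rois[[nm]], file.path(dir, paste0("roi_", nm, ".nii.gz")), vs)
  }
  manifest <- list(
    subjects = vapply(dataset$subjects, `[[`, "", "id"),
    groups = vapply(dataset$subjects, `[[`, "", "group"),
    bold_paths = unname(paths),
    seed = dataset$config$rng_seed,
    grid_dims = dataset$config$grid_dims,
    voxel_size_mm = vs)
  write_manifest(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}
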