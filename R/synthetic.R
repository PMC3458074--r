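#' Simulation configuration for two-group synthetic datasets
#'
#' Bundles every knob of the synthetic-data generator: the symmetric voxel
#' grid, the BOLD acquisition (number of timepoints, repetition time),
#' group sizes, the planted seed-target couplings, the temporal noise
#' model, the per-ROI fractional-anisotropy distributions, and the planted
#' imaging-behavior correlations. The defaults emulate a two-group
#' case-control resting-state + DTI study: ~30 subjects per group for the
#' connectivity arm, 29/24 for the DTI arm, bilateral seed ROIs coupled
#' positively and negatively to target regions with a right-greater-than-
#' left strength asymmetry, a group-dependent positive-coupling reduction,
#' per-subject FA with leftward (left > right) asymmetry plus a planted
#' right-hemisphere group reduction, and a planted negative correlation
#' between the FA asymmetry index and negative-symptom severity.
#'
#' The grid default is 24 x 28 x 24 voxels at 3 mm isotropic (27 mm^3 per
#' voxel); the first axis is the left-right flip axis and must have even
#' extent so that the mirror operation is an exact index permutation with
#' no midline voxel. Low first-axis indices are the left hemisphere.
#'
#' @param grid_dims voxel counts per axis; `grid_dims[1]` must be even.
#' @param voxel_size_mm isotropic voxel edge length in mm.
#' @param n_timepoints number of BOLD volumes per subject.
#' @param tr_s repetition time in seconds.
#' @param n_per_group named integer vector of subject counts for the
#'   functional arm (names are the group labels).
#' @param n_dti named integer vector of subject counts for the DTI arm.
#' @param rois named list of ROI masks: a `seed` element (a [roi_pair]) plus
#'   named binary target masks. Defaults to [default_rois()].
#' @param coupling_spec list of couplings, each
#'   `list(target = <roi name>, seed = "left"|"right", weights = <named
#'   numeric, one weight in [-1, 1] per group>)`.
#' @param noise_sd standard deviation of the voxelwise noise process.
#' @param ar1_rho lag-1 autocorrelation of latent and noise series, in
#'   `[0, 1)`. The AR(1) processes are scaled to unit marginal variance.
#' @param fa_spec data frame with columns `roi` (`"left"`/`"right"`),
#'   `group`, `mean`, `sd` giving the per-ROI FA distribution per group;
#'   means must lie in (0, 1).
#' @param behavior_spec list with element `correlations`: a list of planted
#'   imaging-behavior links `list(variable=, imaging=, rho=, group=)`.
#' @param mirror logical; if `TRUE` the generator produces exactly
#'   mirror-symmetric BOLD data (shared bilateral latent series, mirrored
#'   noise field) for testing the asymmetry pipeline's null behavior.
#'   Requires left/right couplings to be symmetric.
#' @param rng_seed integer seed; identical seeds give bit-identical output.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(grid_dims = c(24L, 28L, 24L),
                       voxel_size_mm = 3,
                       n_timepoints = 120L,
                       tr_s = 2,
                       n_per_group = c(control = 30L, patient = 30L),
                       n_dti = c(control = 29L, patient = 24L),
                       rois = default_rois(grid_dims),
                       coupling_spec = default_couplings(),
                       noise_sd = 1,
                       ar1_rho = 0.3,
                       fa_spec = default_fa_spec(),
                       behavior_spec = default_behavior_spec(),
                       mirror = FALSE,
                       rng_seed = 1L) {
  grid_dims <- as.integer(grid_dims)
  stopifnot(length(grid_dims) == 3L, all(grid_dims >= 2L))
  if (grid_dims[1] %% 2L != 0L) {
    stop("flip-axis extent must be even so every voxel has a mirror partner",
         call. = FALSE)
  }
  if (is.null(names(n_per_group)) || length(n_per_group) != 2L) {
    stop("`n_per_group` must be a named vector of two group sizes", call. = FALSE)
  }
  if (noise_sd <= 0) stop("`noise_sd` must be positive", call. = FALSE)
  if (ar1_rho < 0 || ar1_rho >= 1) {
    stop("`ar1_rho` must lie in [0, 1)", call. = FALSE)
  }
  for (cp in coupling_spec) {
    if (any(abs(cp$weights) > 1)) {
      stop("coupling weights must lie in [-1, 1]", call. = FALSE)
    }
    if (!cp$seed %in% c("left", "right")) {
      stop("coupling seed side must be 'left' or 'right'", call. = FALSE)
    }
    if (!all(names(n_per_group) %in% names(cp$weights))) {
      stop("coupling weights must name every group", call. = FALSE)
    }
  }
  if (any(fa_spec$mean <= 0 | fa_spec$mean >= 1)) {
    stop("FA means must lie in (0, 1)", call. = FALSE)
  }
  if (any(fa_spec$sd < 0)) stop("FA SDs must be non-negative", call. = FALSE)
  for (pl in behavior_spec$correlations) {
    if (abs(pl$rho) > 1) stop("planted rho must lie in [-1, 1]", call. = FALSE)
  }
  structure(list(grid_dims = grid_dims, voxel_size_mm = voxel_size_mm,
                 n_timepoints = as.integer(n_timepoints), tr_s = tr_s,
                 n_per_group = n_per_group, n_dti = n_dti, rois = rois,
                 coupling_spec = coupling_spec, noise_sd = noise_sd,
                 ar1_rho = ar1_rho, fa_spec = fa_spec,
                 behavior_spec = behavior_spec, mirror = mirror,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> grid %s @ %g mm, T=%d, TR=%g s, groups %s\n",
              paste(x$grid_dims, collapse = "x"), x$voxel_size_mm,
              x$n_timepoints, x$tr_s,
              paste(sprintf("%s=%d", names(x$n_per_group), x$n_per_group),
                    collapse = ", ")))
  cat(sprintf("  %d couplings, noise sd %g, AR(1) rho %g, seed %d%s\n",
              length(x$coupling_spec), x$noise_sd, x$ar1_rho, x$rng_seed,
              if (x$mirror) ", mirror-symmetric" else ""))
  invisible(x)
}

frac_range <- function(n, lo, hi) {
  a <- max(1L, round(lo * n))
  b <- min(n, max(a, round(hi * n)))
  a:b
}

#' Default ROI layout for the synthetic grid
#'
#' Places a bilateral seed pair near the anterior midline plus mirror-image
#' target boxes standing in for the regions a cingulate seed couples to:
#' a bilateral striatum-like pair (planted positive coupling), a bilateral
#' inferior-frontal-like pair (planted right-greater-than-left coupling
#' asymmetry), and a posterior midline-adjacent region (planted negative
#' coupling). Positions scale with the grid so reduced grids used in tests
#' keep the same layout.
#'
#' @param dims grid dimensions (first-axis extent even).
#' @return Named list: `seed` (a [roi_pair]) and logical target masks.
#' @export
default_rois <- function(dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  mirror_i <- function(i) sort(nx + 1L - i)
  seed_i <- frac_range(nx, 0.355, 0.42)
  seed_j <- frac_range(ny, 0.68, 0.75)
  seed_k <- frac_range(nz, 0.50, 0.58)
  put_i <- frac_range(nx, 0.17, 0.25)
  put_j <- frac_range(ny, 0.54, 0.61)
  put_k <- frac_range(nz, 0.46, 0.54)
  ifg_i <- frac_range(nx, 0.08, 0.17)
  ifg_j <- frac_range(ny, 0.79, 0.86)
  ifg_k <- frac_range(nz, 0.33, 0.42)
  pcc_i <- frac_range(nx, 0.42, 0.50)
  pcc_j <- frac_range(ny, 0.18, 0.25)
  pcc_k <- frac_range(nz, 0.54, 0.63)
  list(
    seed = roi_pair(box_mask(dims, seed_i, seed_j, seed_k)),
    putamen_left  = box_mask(dims, put_i, put_j, put_k),
    putamen_right = box_mask(dims, mirror_i(put_i), put_j, put_k),
    ifg_left  = box_mask(dims, ifg_i, ifg_j, ifg_k),
    ifg_right = box_mask(dims, mirror_i(ifg_i), ifg_j, ifg_k),
    pcc_left  = box_mask(dims, pcc_i, pcc_j, pcc_k)
  )
}

#' Default planted couplings
#'
#' Control-group couplings with a right-greater-than-left asymmetry in the
#' frontal pair, and patient-group alterations: a positive-coupling
#' reduction in the striatum-like pair (delta w = 0.3), an increased
#' negative coupling in the posterior region, and a further increased
#' right-sided frontal coupling (increased asymmetry).
#'
#' @return List of coupling entries for [sim_config()].
#' @export
default_couplings <- function() {
  list(
    list(target = "putamen_left",  seed = "left",
         weights = c(control = 0.6, patient = 0.3)),
    list(target = "putamen_right", seed = "right",
         weights = c(control = 0.6, patient = 0.3)),
    list(target = "ifg_left",  seed = "left",
         weights = c(control = 0.40, patient = 0.40)),
    list(target = "ifg_right", seed = "right",
         weights = c(control = 0.55, patient = 0.70)),
    list(target = "pcc_left", seed = "left",
         weights = c(control = -0.30, patient = -0.50))
  )
}

#' Default FA distributions per ROI and group
#'
#' Leftward (left > right) FA asymmetry in both groups and a planted
#' right-hemisphere FA reduction in the patient group.
#'
#' @return Data frame with columns `roi`, `group`, `mean`, `sd`.
#' @export
default_fa_spec <- function() {
  data.frame(
    roi   = c("left", "left", "right", "right"),
    group = c("control", "patient", "control", "patient"),
    mean  = c(0.525, 0.505, 0.471, 0.433),
    sd    = c(0.060, 0.047, 0.064, 0.038)
  )
}

#' Default behavioral generation spec
#'
#' One planted imaging-behavior link: the FA asymmetry index against the
#' negative-symptom subscale in the patient group, rho = -0.532.
#'
#' @return List with a `correlations` element.
#' @export
default_behavior_spec <- function() {
  list(correlations = list(
    list(variable = "panss_n", imaging = "ai", rho = -0.532, group = "patient")
  ))
}

#' Stationary AR(1) series with unit marginal variance
#'
#' Recursion vectorized across series (columns); the first row is drawn at
#' the stationary scale so the marginal variance is exactly 1 at every t.
#' @noRd
ar1_series <- function(n_t, rho, n = 1L) {
  e <- matrix(stats::rnorm(n_t * n), n_t, n)
  if (rho != 0) {
    scale <- sqrt(1 - rho^2)
    for (t in 2:n_t) e[t, ] <- rho * e[t - 1L, ] + scale * e[t, ]
  }
  e
}

#' Generate synthetic two-group 4D BOLD data with planted couplings
#'
#' For every subject a latent unit-variance AR(1) series is drawn per seed
#' side; each seed-ROI voxel carries the latent series plus noise, each
#' target voxel carries `w * latent + sqrt(1 - w^2) * noise` where `w` is
#' the group's coupling weight, and every other voxel is pure AR(1) noise.
#' With `noise_sd = 1` the population correlation between a target voxel
#' and the latent series is exactly `w`. With `config$mirror = TRUE` the
#' two seed latents are shared and the noise field is mirrored across the
#' midline so the data are exactly left-right symmetric.
#'
#' @param config a [sim_config()].
#' @return An object of class `bold_dataset`: a list with `subjects` (each
#'   `list(id, group, bold, latent)` where `bold` is a 4D array, time last,
#'   and `latent` holds the two seed latent series for calibration checks),
#'   `seed` (the seed [roi_pair]), `rois` (target masks), and `config`.
#' @export
generate_bold <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  dims <- config$grid_dims
  n_t <- config$n_timepoints
  rois <- config$rois
  seed <- rois$seed
  if (!inherits(seed, "roi_pair")) stop("`rois$seed` must be a roi_pair", call. = FALSE)
  check_same_grid(seed$left, array(0, dims))

  # reject overlapping masks: seeds and all coupled targets must be disjoint
  used <- seed$left | seed$right
  for (cp in config$coupling_spec) {
    m <- rois[[cp$target]]
    if (is.null(m)) stop("unknown coupling target '", cp$target, "'", call. = FALSE)
    check_same_grid(m, seed$left)
    if (any(m & used)) {
      stop("mask '", cp$target, "' overlaps the seed ROIs or another coupled mask",
           call. = FALSE)
    }
    used <- used | m
  }

  set.seed(config$rng_seed)
  n_vox <- prod(dims)
  groups <- rep(names(config$n_per_group), config$n_per_group)
  flip_src <- as.vector(lr_flip(array(seq_len(n_vox), dims)))
  xi <- slice.index(array(0, dims), 1L)
  right_cols <- which(as.vector(xi) > dims[1] / 2)
  seed_cols <- list(left = which(seed$left), right = which(seed$right))

  subjects <- vector("list", length(groups))
  for (s in seq_along(groups)) {
    grp <- groups[s]
    latent <- ar1_series(n_t, config$ar1_rho, 2L)
    if (config$mirror) latent[, 2L] <- latent[, 1L]
    lat <- list(left = latent[, 1L], right = latent[, 2L])
    eps <- ar1_series(n_t, config$ar1_rho, n_vox)
    if (config$mirror) eps[, right_cols] <- eps[, flip_src[right_cols]]
    y <- config$noise_sd * eps
    for (side in c("left", "right")) {
      cols <- seed_cols[[side]]
      y[, cols] <- lat[[side]] + y[, cols]
    }
    for (cp in config$coupling_spec) {
      w <- cp$weights[[grp]]
      cols <- which(rois[[cp$target]])
      y[, cols] <- w * lat[[cp$seed]] + sqrt(1 - w^2) * y[, cols]
    }
    subjects[[s]] <- list(id = sprintf("sub-%03d", s), group = grp,
                          bold = array(t(y), c(dims, n_t)),
                          latent = lat)
  }
  structure(list(subjects = subjects, seed = seed,
                 rois = rois[setdiff(names(rois), "seed")], config = config),
            class = "bold_dataset")
}

#' @export
print.bold_dataset <- function(x, ...) {
  cat(sprintf("<bold_dataset> %d subjects (%s), grid %s, T=%d\n",
              length(x$subjects),
              paste(sprintf("%s=%d", names(x$config$n_per_group),
                            x$config$n_per_group), collapse = ", "),
              paste(x$config$grid_dims, collapse = "x"),
              x$config$n_timepoints))
  invisible(x)
}

rtnorm01 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= 0 | out >= 1)
  while (length(bad) > 0L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= 0 | out[bad] >= 1]
  }
  out
}

#' Cingulum-bundle style ROI masks for the DTI arm
#'
#' A left/right pair of white-matter ROIs deliberately *not* mirror images:
#' on the default grid the left ROI covers 99 voxels and the right 135,
#' matching the convention that anatomically defined tract ROIs differ in
#' size across hemispheres. On smaller grids the spans shrink to fit.
#'
#' @param dims grid dimensions.
#' @return List with logical masks `left` and `right`.
#' @export
cingulum_rois <- function(dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  mid <- nx %/% 2L
  kc <- max(2L, round(0.5 * nz))
  k_rng <- max(1L, kc - 1L):min(nz, kc + 1L)
  jc <- max(2L, round(0.5 * ny))
  span_l <- min(5L, jc - 1L, ny - jc)
  span_r <- min(7L, jc - 1L, ny - jc)
  i_l <- max(1L, mid - 4L):(mid - 2L)
  i_r <- (nx + 1L) - rev(i_l)
  list(left  = box_mask(dims, i_l, (jc - span_l):(jc + span_l), k_rng),
       right = box_mask(dims, i_r, (jc - span_r):(jc + span_r), k_rng))
}

#' Generate per-subject ROI fractional anisotropy (and optional eigenvalue maps)
#'
#' Draws each subject's mean FA per ROI from the configured per-group
#' normal distribution truncated to (0, 1). With `eigenvalue_maps = TRUE`
#' the function additionally constructs per-subject diffusion-tensor
#' eigenvalue images in which every ROI voxel carries an axially symmetric
#' tensor whose FA equals the drawn ROI value exactly, so the downstream
#' eigenvalue-to-FA computation recovers the table to machine precision.
#'
#' @param config a [sim_config()]; group sizes come from `config$n_dti`.
#' @param eigenvalue_maps logical; also build eigenvalue images.
#' @return An object of class `fa_dataset`: list with `table` (data frame
#'   `subject`, `group`, `left_fa`, `right_fa`), `rois` (cingulum masks),
#'   and, if requested, `eigen_maps` (per subject a 4D array, last dim the
#'   three eigenvalues, units mm^2/s).
#' @export
generate_fa <- function(config, eigenvalue_maps = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  spec <- config$fa_spec
  set.seed(config$rng_seed + 1L)
  groups <- rep(names(config$n_dti), config$n_dti)
  n <- length(groups)
  tab <- data.frame(subject = sprintf("dti-%03d", seq_len(n)), group = groups,
                    left_fa = NA_real_, right_fa = NA_real_)
  for (g in unique(groups)) {
    idx <- which(groups == g)
    for (roi in c("left", "right")) {
      row <- spec[spec$roi == roi & spec$group == g, ]
      if (nrow(row) != 1L) stop("fa_spec lacks a row for ", roi, "/", g, call. = FALSE)
      tab[[paste0(roi, "_fa")]][idx] <- rtnorm01(length(idx), row$mean, row$sd)
    }
  }
  rois <- cingulum_rois(config$grid_dims)
  out <- list(table = tab, rois = rois, config = config)
  if (eigenvalue_maps) {
    # axially symmetric tensor (l1, l, l) with mean diffusivity 0.7e-3 mm^2/s;
    # delta solves the FA formula exactly: delta = f * sqrt(3 / (9 - 6 f^2))
    md <- 0.7e-3
    out$eigen_maps <- lapply(seq_len(n), function(s) {
      ev <- array(md, c(config$grid_dims, 3L))
      for (roi in c("left", "right")) {
        f <- tab[[paste0(roi, "_fa")]][s]
        delta <- f * sqrt(3 / (9 - 6 * f^2))
        idx <- which(rois[[roi]])
        nvx <- prod(config$grid_dims)
        ev[idx] <- md * (1 + 2 * delta)
        ev[idx + nvx] <- md * (1 - delta)
        ev[idx + 2L * nvx] <- md * (1 - delta)
      }
      ev
    })
  }
  structure(out, class = "fa_dataset")
}

table1_behavior_defaults <- function() {
  list(
    n_female = c(control = 12L, patient = 13L),
    continuous = data.frame(
      variable = c("age", "education",
                   "stroop_word_time", "stroop_color_time", "stroop_incong_time",
                   "stroop_word_acc", "stroop_color_acc", "stroop_incong_acc"),
      control_mean = c(23.0, 14.3, 11.4, 15.2, 31.4, 1.000, 0.997, 0.922),
      control_sd   = c(3.2, 2.0, 2.6, 3.3, 7.6, 0.000, 0.014, 0.085),
      patient_mean = c(23.1, 13.7, 12.5, 18.3, 37.7, 0.999, 1.000, 0.879),
      patient_sd   = c(3.6, 2.0, 2.4, 4.4, 9.4, 0.006, 0.000, 0.096)
    ),
    patient_only = data.frame(
      variable = c("panss_p", "panss_n", "panss_g",
                   "onset_age", "illness_duration", "medication_dose"),
      mean = c(19.4, 16.1, 31.8, 19.4, 39.0, 407.7),
      sd   = c(4.6, 4.7, 5.4, 3.2, 33.3, 240.6),
      min  = c(7, 7, 16, 5, 0.5, 0),
      integer = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
    )
  )
}

rtnorm_min <- function(n, mean, sd, min) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < min)
  while (length(bad) > 0L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < min]
  }
  out
}

#' Generate a synthetic behavioral and clinical table
#'
#' Produces one row per subject across both groups: sex (fixed female
#' counts per group), age, education, Stroop completion times and
#' accuracies for the word-reading, color-naming and incongruent
#' conditions (incongruent slower than color naming in expectation),
#' and, for the patient group, symptom subscale scores (total = sum of
#' subscales), onset age, illness duration and medication dose.
#'
#' Planted imaging-behavior correlations listed in
#' `config$behavior_spec$correlations` are imposed by constructing the
#' behavioral variable as `rho * z(x) + sqrt(1 - rho^2) * noise` on the
#' standardized imaging measure `x`, then rescaling to the configured
#' mean/SD (so the population correlation is `rho`).
#'
#' One subject per group has missing Stroop data (did not finish the
#' task), exercising pairwise deletion downstream.
#'
#' @param config a [sim_config()].
#' @param imaging optional named list of per-subject imaging measures
#'   (e.g. `list(ai = <numeric>)`); each vector must either cover all
#'   subjects or be named by subject id of the group it applies to.
#'   Lengths must match the subjects they are planted into.
#' @param n_per_group group sizes for the table; defaults to
#'   `config$n_dti` because the planted link defaults to a DTI measure.
#' @return Data frame (class `behavior_table`), one row per subject.
#' @export
generate_behavior <- function(config, imaging = NULL,
                              n_per_group = config$n_dti) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed + 2L)
  defs <- table1_behavior_defaults()
  groups <- rep(names(n_per_group), n_per_group)
  n <- length(groups)
  tab <- data.frame(subject = sprintf("dti-%03d", seq_len(n)), group = groups)
  tab$sex <- "M"
  for (g in names(n_per_group)) {
    idx <- which(groups == g)
    nf <- min(defs$n_female[[g]] %||% 0L, length(idx))
    tab$sex[idx[seq_len(nf)]] <- "F"
  }
  for (r in seq_len(nrow(defs$continuous))) {
    v <- defs$continuous[r, ]
    x <- numeric(n)
    for (g in names(n_per_group)) {
      idx <- which(groups == g)
      m <- v[[paste0(g, "_mean")]] %||% v$control_mean
      s <- v[[paste0(g, "_sd")]] %||% v$control_sd
      x[idx] <- if (grepl("_acc$", v$variable)) rtnorm01(length(idx), m, s)
                else rtnorm_min(length(idx), m, s, 0.1)
    }
    tab[[v$variable]] <- x
  }
  pat <- which(groups == "patient")
  for (r in seq_len(nrow(defs$patient_only))) {
    v <- defs$patient_only[r, ]
    x <- rep(NA_real_, n)
    if (length(pat) > 0L) {
      draw <- rtnorm_min(length(pat), v$mean, v$sd, v$min)
      x[pat] <- if (v$integer) round(draw) else draw
    }
    tab[[v$variable]] <- x
  }

  # plant imaging-behavior correlations
  for (pl in config$behavior_spec$correlations) {
    if (is.null(imaging) || is.null(imaging[[pl$imaging]])) next
    idx <- if (is.null(pl$group)) seq_len(n) else which(groups == pl$group)
    x <- imaging[[pl$imaging]]
    if (length(x) == n) x <- x[idx]
    if (length(x) != length(idx)) {
      stop("imaging measure '", pl$imaging, "' has length ", length(x),
           " but ", length(idx), " subjects need it", call. = FALSE)
    }
    if (!pl$variable %in% names(tab)) {
      stop("unknown behavioral variable '", pl$variable, "'", call. = FALSE)
    }
    old <- tab[[pl$variable]][idx]
    zx <- as.numeric(scale(x))
    y0 <- pl$rho * zx + sqrt(1 - pl$rho^2) * stats::rnorm(length(idx))
    y <- mean(old) + stats::sd(old) * as.numeric(scale(y0))
    isint <- pl$variable %in% defs$patient_only$variable &&
      defs$patient_only$integer[defs$patient_only$variable == pl$variable]
    tab[[pl$variable]][idx] <- if (isint) round(y) else y
  }
  if (all(c("panss_p", "panss_n", "panss_g") %in% names(tab))) {
    tab$panss_t <- tab$panss_p + tab$panss_n + tab$panss_g
  }
  # one subject per group did not finish the Stroop task
  stroop_cols <- grep("^stroop_", names(tab), value = TRUE)
  for (g in names(n_per_group)) {
    idx <- which(groups == g)
    if (length(idx) > 0L) tab[idx[1L], stroop_cols] <- NA_real_
  }
  class(tab) <- c("behavior_table", "data.frame")
  tab
}
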