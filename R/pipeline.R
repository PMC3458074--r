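#' Run the full synthetic-data analysis pipeline
#'
#' Chains every stage of the seed-connectivity laterality analysis on a
#' synthetic two-group dataset: simulate BOLD, clean it, build per-subject
#' left-seed / right-seed Z-maps and asymmetry contrasts, run the
#' within-group one-sample t maps and the paired-t asymmetry maps with the
#' two-criterion correction, run the between-group two-sample t maps
#' corrected inside the union of the two within-group significant maps,
#' run the between-group asymmetry comparison inside the explicit mask
#' built from the two corrected within-group asymmetry maps, compute the
#' FA group and laterality tests, and correlate imaging measures with the
#' behavioral table. Returns a report bundle with every intermediate
#' statistic plus a provenance record (parameters, seed, config hash,
#' package version).
#'
#' Correction regimes (each two-tailed, extents strict `>`): within-group
#' connectivity `voxel_p = 0.001`, extent > 14; within-group asymmetry
#' `voxel_p = 0.001`, extent > 10; between-group connectivity
#' `voxel_p = 0.001`, extent > 10; between-group asymmetry
#' `voxel_p = 0.01`, extent > 13. Any `min_extent` given as `NULL` is
#' derived from a Monte-Carlo cluster null at the configured smoothness
#' instead.
#'
#' @param config a [sim_config()] describing the synthetic study.
#' @param cleaning a [cleaning_spec()] (or `NULL` to skip cleaning).
#' @param voxel_p named numeric: per-voxel thresholds for regimes
#'   `within`, `within_asym`, `between`, `between_asym`.
#' @param min_extent named list/numeric of cluster-extent cutoffs (strict
#'   `>`) for the same regimes; entries set to `NA` are derived from
#'   [simulate_cluster_null()] with `fwhm_mm` and `n_iter_null`.
#' @param connectivity cluster neighborhood.
#' @param fwhm_mm assumed smoothness for derived extent thresholds.
#' @param n_iter_null Monte-Carlo iterations for derived thresholds.
#' @param sphere_radius_mm radius for peak-sphere imaging measures.
#' @param out_dir optional directory; when given, cluster tables, the FA
#'   summary, the correlation report and the provenance log are written
#'   there as TSV/YAML.
#' @return A list of class `fcasym_report`; see Details.
#' @export
run_pipeline <- function(config = sim_config(),
                         cleaning = cleaning_spec(tr_s = config$tr_s),
                         voxel_p = c(within = 0.001, within_asym = 0.001,
                                     between = 0.001, between_asym = 0.01),
                         min_extent = c(within = 14, within_asym = 10,
                                        between = 10, between_asym = 13),
                         connectivity = "faces",
                         fwhm_mm = 6,
                         n_iter_null = 1000,
                         sphere_radius_mm = 3,
                         out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  groups <- names(config$n_per_group)
  vs <- config$voxel_size_mm

  regime_extent <- function(regime) {
    k <- min_extent[[regime]]
    if (!is.null(k) && !is.na(k)) return(k)
    null <- simulate_cluster_null(array(TRUE, config$grid_dims),
                                  fwhm_mm = fwhm_mm,
                                  voxel_p = voxel_p[[regime]],
                                  connectivity = connectivity,
                                  n_iter = n_iter_null, voxel_size_mm = vs,
                                  seed = config$rng_seed + 7L)
    extent_threshold(null, 0.05) - 1  # correct_map keeps extents > min_extent
  }

  # --- simulate and map ----------------------------------------------------
  dataset <- generate_bold(config)
  zm <- subject_zmaps(dataset, cleaning)
  by_group <- lapply(groups, function(g) which(zm$group == g))
  names(by_group) <- groups

  # --- within-group connectivity and asymmetry -----------------------------
  within <- list()
  for (g in groups) {
    idx <- by_group[[g]]
    zl <- zm$z_left[idx]
    zr_flip <- lapply(zm$z_right[idx], lr_flip)
    t_l <- one_sample_tmap(zl)
    t_rf <- one_sample_tmap(zr_flip)
    c_l <- correct_map(t_l, voxel_p[["within"]], regime_extent("within"),
                       connectivity = connectivity, voxel_size_mm = vs)
    c_rf <- correct_map(t_rf, voxel_p[["within"]], regime_extent("within"),
                        connectivity = connectivity, voxel_size_mm = vs)
    t_pair <- paired_tmap(zl, zr_flip)
    c_pair <- correct_map(t_pair, voxel_p[["within_asym"]],
                          regime_extent("within_asym"),
                          connectivity = connectivity, voxel_size_mm = vs)
    asym_mask <- asymmetry_within_group_mask(c_l$map, c_rf$map, c_pair$map)
    within[[g]] <- list(t_left = t_l, t_right_flipped = t_rf,
                        corrected_left = c_l, corrected_right_flipped = c_rf,
                        t_paired = t_pair, corrected_paired = c_pair,
                        asymmetry_mask = asym_mask)
  }

  # --- between-group connectivity (combined within-group mask) -------------
  between <- list()
  for (side in c("z_left", "z_right")) {
    cw <- lapply(groups, function(g) {
      wi <- within[[g]]
      cm <- if (side == "z_left") wi$corrected_left else wi$corrected_right_flipped
      vals <- cm$map$values
      if (side == "z_right") vals <- lr_flip(vals)  # back to native orientation
      vals != 0
    })
    union_mask <- Reduce(`|`, cw)
    t_bg <- two_sample_tmap(zm[[side]][by_group[[groups[1]]]],
                            zm[[side]][by_group[[groups[2]]]])
    between[[side]] <- correct_map(t_bg, voxel_p[["between"]],
                                   regime_extent("between"),
                                   analysis_mask = union_mask,
                                   connectivity = connectivity,
                                   voxel_size_mm = vs)
  }

  # --- between-group asymmetry (explicit mask from within-group maps) ------
  asym_union <- Reduce(`|`, lapply(groups, function(g) {
    within[[g]]$asymmetry_mask$values != 0
  }))
  t_asym_bg <- two_sample_tmap(zm$contrast[by_group[[groups[1]]]],
                               zm$contrast[by_group[[groups[2]]]])
  between_asym <- correct_map(t_asym_bg, voxel_p[["between_asym"]],
                              regime_extent("between_asym"),
                              analysis_mask = asym_union,
                              connectivity = connectivity, voxel_size_mm = vs)

  # --- post-hoc direction of between-group regions -------------------------
  posthoc <- list()
  for (side in c("z_left", "z_right")) {
    cl <- between[[side]]$clusters
    if (nrow(cl) > 0L) {
      region <- between[[side]]$map$values != 0
      posthoc[[side]] <- posthoc_region_direction(zm[[side]], region, zm$group)
    }
  }

  # --- DTI arm -------------------------------------------------------------
  fa_data <- generate_fa(config)
  fa_tab <- fa_summary(fa_data)
  fa_tests <- group_fa_tests(fa_tab)

  # --- behavior and correlations -------------------------------------------
  behavior <- generate_behavior(config, imaging = list(ai = fa_tab$ai))
  behavior_tests <- group_compare_table(
    behavior, variables = c("age", "education", "stroop_word_time",
                            "stroop_color_time", "stroop_incong_time"))
  pat <- behavior$group == "patient"
  interference <- stroop_interference(behavior$stroop_color_time[pat],
                                      behavior$stroop_incong_time[pat])
  imaging_measures <- list(ai = fa_tab$ai[fa_tab$group == "patient"])
  for (side in c("z_left", "z_right")) {
    cl <- between[[side]]$clusters
    if (nrow(cl) > 0L) {
      peak <- unlist(cl[1, c("peak_i", "peak_j", "peak_k")])
      nm <- paste0(sub("z_", "", side), "_seed_peak_sphere")
      idx_pat <- by_group[["patient"]]
      imaging_measures[[nm]] <-
        sphere_roi_values(zm[[side]][idx_pat], peak, sphere_radius_mm, vs)
    }
  }
  clinical <- lapply(
    behavior[pat, c("panss_p", "panss_n", "panss_g", "onset_age",
                    "illness_duration", "medication_dose")],
    as.numeric)
  clinical$stroop_interference <- interference
  # imaging measures are per patient; sphere measures came from the
  # functional arm, whose patient count may differ from the DTI arm --
  # correlate() requires aligned lengths, so keep only aligned pairs
  n_pat_dti <- sum(fa_tab$group == "patient")
  n_pat_beh <- sum(pat)
  correlations <- NULL
  if (n_pat_dti == n_pat_beh) {
    usable <- imaging_measures[vapply(imaging_measures, length, 0L) == n_pat_beh]
    if (length(usable) > 0L) {
      correlations <- correlation_report(usable, clinical)
    }
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("fcasym")),
    r_version = as.character(getRversion()),
    rng_seed = config$rng_seed,
    grid_dims = config$grid_dims,
    voxel_size_mm = vs,
    n_timepoints = config$n_timepoints,
    n_per_group = as.list(config$n_per_group),
    band_hz = if (!is.null(cleaning)) cleaning$band_hz,
    global_signal = if (!is.null(cleaning)) cleaning$global_signal,
    detrend_order = if (!is.null(cleaning)) cleaning$detrend_order,
    voxel_p = as.list(voxel_p),
    min_extent = as.list(min_extent),
    extent_rule = "strict: clusters must exceed min_extent voxels",
    connectivity = connectivity,
    fwhm_mm = fwhm_mm,
    config_hash = hash_object(config))

  report <- structure(
    list(within = within, between = between, between_asym = between_asym,
         posthoc = posthoc, fa_summary = fa_tab, fa_tests = fa_tests,
         behavior = behavior, behavior_tests = behavior_tests,
         correlations = correlations, zmaps = zm, provenance = provenance),
    class = "fcasym_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (g in groups) {
      write_cluster_table(within[[g]]$corrected_left$clusters,
                          file.path(out_dir, paste0("within_", g, "_left.tsv")))
      write_cluster_table(within[[g]]$corrected_paired$clusters,
                          file.path(out_dir, paste0("asym_", g, "_paired.tsv")))
    }
    write_cluster_table(between$z_left$clusters,
                        file.path(out_dir, "between_left.tsv"))
    write_cluster_table(between$z_right$clusters,
                        file.path(out_dir, "between_right.tsv"))
    write_cluster_table(between_asym$clusters,
                        file.path(out_dir, "between_asym.tsv"))
    write_table_tsv(fa_tab, file.path(out_dir, "fa_summary.tsv"))
    write_table_tsv(fa_tests, file.path(out_dir, "fa_tests.tsv"))
    write_table_tsv(behavior, file.path(out_dir, "behavior.tsv"))
    if (!is.null(correlations)) {
      write_table_tsv(correlations, file.path(out_dir, "correlations.tsv"))
    }
    write_manifest(provenance, file.path(out_dir, "provenance.yaml"))
  }
  report
}

#' @export
print.fcasym_report <- function(x, ...) {
  cat("<fcasym_report>\n")
  for (g in names(x$within)) {
    cat(sprintf("  within-group %s: %d connectivity clusters, %d asymmetry clusters\n",
                g, nrow(x$within[[g]]$corrected_left$clusters),
                nrow(x$within[[g]]$corrected_paired$clusters)))
  }
  cat(sprintf("  between-group: %d left-seed, %d right-seed, %d asymmetry clusters\n",
              nrow(x$between$z_left$clusters), nrow(x$between$z_right$clusters),
              nrow(x$between_asym$clusters)))
  cat(sprintf("  FA tests: right-ROI between-group p = %.4g\n",
              x$fa_tests$p[x$fa_tests$measure == "right_fa" &
                           x$fa_tests$test == "between-group"]))
  invisible(x)
}

#' Stable hash of an R object
#'
#' MD5 of the version-2 serialization, for provenance records.
#' @param x any serializable object.
#' @return Character MD5 string.
#' @export
hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
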