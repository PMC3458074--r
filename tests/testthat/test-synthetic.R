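test_that("generator is deterministic under a fixed seed", {
  cfg <- tiny_config(n_timepoints = 30L,
                     n_per_group = c(control = 2L, patient = 2L))
  a <- generate_bold(cfg)
  b <- generate_bold(cfg)
  expect_identical(a$subjects[[1]]$bold, b$subjects[[1]]$bold)
  expect_identical(a$subjects[[4]]$bold, b$subjects[[4]]$bold)
  fa1 <- generate_fa(cfg)
  fa2 <- generate_fa(cfg)
  expect_identical(fa1$table, fa2$table)
  be1 <- generate_behavior(cfg)
  be2 <- generate_behavior(cfg)
  expect_identical(be1, be2)
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(grid_dims = c(13, 14, 12)), "even")
  expect_error(tiny_config(ar1_rho = 1), "ar1_rho")
  expect_error(tiny_config(noise_sd = 0), "noise_sd")
  expect_error(tiny_config(coupling_spec = list(
    list(target = "putamen_left", seed = "left",
         weights = c(control = 1.2, patient = 0)))), "\\[-1, 1\\]")
  bad_fa <- default_fa_spec()
  bad_fa$mean[1] <- 1.2
  expect_error(tiny_config(fa_spec = bad_fa), "\\(0, 1\\)")
})

test_that("overlapping seed and target masks are rejected", {
  rois <- default_rois(tiny_grid)
  rois$bad <- rois$seed$left  # exactly the seed ROI
  cfg <- tiny_config(rois = rois, coupling_spec = list(
    list(target = "bad", seed = "left", weights = c(control = .5, patient = .5))))
  expect_error(generate_bold(cfg), "overlaps")
})

test_that("zero coupling gives near-zero seed-target correlation", {
  cfg <- tiny_config(coupling_spec = list(
    list(target = "putamen_left", seed = "left",
         weights = c(control = 0, patient = 0))),
    n_timepoints = 200L, n_per_group = c(control = 1L, patient = 1L))
  ds <- generate_bold(cfg)
  sub <- ds$subjects[[1]]
  tgt <- seed_timeseries(sub$bold, ds$rois$putamen_left)
  r <- cor(sub$latent$left, tgt)
  expect_lt(abs(r), 3 / sqrt(200))
})

test_that("unit coupling reproduces the latent series exactly", {
  cfg <- tiny_config(coupling_spec = list(
    list(target = "putamen_left", seed = "left",
         weights = c(control = 1, patient = 1))),
    n_timepoints = 40L, n_per_group = c(control = 1L, patient = 1L))
  ds <- generate_bold(cfg)
  sub <- ds$subjects[[1]]
  vox <- which(ds$rois$putamen_left)[1]
  d <- dim(sub$bold)
  series <- matrix(sub$bold, prod(d[1:3]), d[4])[vox, ]
  expect_equal(cor(series, sub$latent$left), 1)
  expect_equal(series, sub$latent$left)
})

test_that("coupling weight is the population correlation with the latent", {
  # w = 0.6, unit-variance latent and noise, T = 200: sample correlations
  # concentrate around 0.6 (the closed-form population value)
  rs <- vapply(1:100, function(s) {
    cfg <- tiny_config(coupling_spec = list(
      list(target = "putamen_left", seed = "left",
           weights = c(control = 0.6, patient = 0.6))),
      n_timepoints = 200L, n_per_group = c(control = 1L, patient = 1L),
      rng_seed = 1000L + s)
    ds <- generate_bold(cfg)
    sub <- ds$subjects[[1]]
    vox <- which(ds$rois$putamen_left)[1]
    d <- dim(sub$bold)
    cor(matrix(sub$bold, prod(d[1:3]), d[4])[vox, ], sub$latent$left)
  }, 0)
  expect_gte(mean(abs(rs - 0.6) <= 0.15), 0.95)
  expect_lt(abs(mean(rs) - 0.6), 0.05)
})

test_that("empirical seed-target correlation converges with series length", {
  err <- vapply(c(100L, 400L), function(T) {
    rs <- vapply(1:40, function(s) {
      cfg <- tiny_config(coupling_spec = list(
        list(target = "putamen_left", seed = "left",
             weights = c(control = 0.5, patient = 0.5))),
        n_timepoints = T, n_per_group = c(control = 1L, patient = 1L),
        rng_seed = 2000L + s)
      ds <- generate_bold(cfg)
      sub <- ds$subjects[[1]]
      vox <- which(ds$rois$putamen_left)[1]
      d <- dim(sub$bold)
      cor(matrix(sub$bold, prod(d[1:3]), d[4])[vox, ], sub$latent$left)
    }, 0)
    sqrt(mean((rs - 0.5)^2))
  }, 0)
  expect_lt(err[2], err[1])  # RMS error shrinks as T grows
  expect_lt(err[2], 0.06)
})

test_that("FA generator honors means, truncation and the AI sign", {
  spec0 <- default_fa_spec()
  spec0$sd[] <- 0
  cfg <- tiny_config(fa_spec = spec0)
  fa <- generate_fa(cfg)
  ctrl <- fa$table[fa$table$group == "control", ]
  expect_true(all(ctrl$left_fa == 0.525))
  expect_true(all(ctrl$right_fa == 0.471))
  # leftward asymmetry: control group means force a negative AI
  expect_lt(mean(asymmetry_index(ctrl$right_fa, ctrl$left_fa)), 0)
  fa2 <- generate_fa(tiny_config())
  expect_true(all(fa2$table$left_fa > 0 & fa2$table$left_fa < 1))
  expect_true(all(fa2$table$right_fa > 0 & fa2$table$right_fa < 1))
})

test_that("eigenvalue maps reproduce the drawn FA exactly", {
  cfg <- tiny_config(n_dti = c(control = 2L, patient = 2L))
  fa <- generate_fa(cfg, eigenvalue_maps = TRUE)
  for (s in seq_along(fa$eigen_maps)) {
    fmap <- fa_from_eigenvalues(fa$eigen_maps[[s]])
    expect_equal(roi_mean_fa(fmap, fa$rois$left), fa$table$left_fa[s],
                 tolerance = 1e-10)
    expect_equal(roi_mean_fa(fmap, fa$rois$right), fa$table$right_fa[s],
                 tolerance = 1e-10)
  }
})

test_that("behavioral generator plants correlations at the requested strength", {
  # rho = 0: no association beyond sampling noise
  cfg0 <- tiny_config(behavior_spec = list(correlations = list(
    list(variable = "onset_age", imaging = "x", rho = 0, group = "patient"))),
    n_dti = c(control = 4L, patient = 24L))
  x <- rnorm(24)
  beh <- generate_behavior(cfg0, imaging = list(x = x))
  r0 <- cor(x, beh$onset_age[beh$group == "patient"])
  expect_lt(abs(r0), 2 / sqrt(24) + 0.15)

  # rho = 1 with a continuous variable: exact linear agreement
  cfg1 <- tiny_config(behavior_spec = list(correlations = list(
    list(variable = "onset_age", imaging = "x", rho = 1, group = "patient"))),
    n_dti = c(control = 4L, patient = 24L))
  beh1 <- generate_behavior(cfg1, imaging = list(x = x))
  expect_equal(cor(x, beh1$onset_age[beh1$group == "patient"]), 1)

  # rho = -0.5, n = 24: recovered r lands in [-0.8, -0.1] almost always
  hits <- vapply(1:200, function(s) {
    cfg <- tiny_config(behavior_spec = list(correlations = list(
      list(variable = "onset_age", imaging = "x", rho = -0.5,
           group = "patient"))),
      n_dti = c(control = 4L, patient = 24L), rng_seed = 3000L + s)
    set.seed(s)
    xs <- rnorm(24)
    b <- generate_behavior(cfg, imaging = list(x = xs))
    r <- cor(xs, b$onset_age[b$group == "patient"])
    r >= -0.8 && r <= -0.1
  }, NA)
  expect_gte(mean(hits), 0.95)
})

test_that("behavior table has the expected structure", {
  beh <- generate_behavior(tiny_config(n_dti = c(control = 10L, patient = 10L)))
  expect_s3_class(beh, "data.frame")
  expect_true(all(c("group", "sex", "stroop_color_time", "panss_t") %in% names(beh)))
  pat <- beh$group == "patient"
  # total symptom score dominates every subscale
  expect_true(all(beh$panss_t[pat] >= beh$panss_p[pat]))
  expect_true(all(beh$panss_t[pat] >= beh$panss_n[pat]))
  expect_true(all(beh$panss_t[pat] >= beh$panss_g[pat]))
  # controls carry no symptom scores
  expect_true(all(is.na(beh$panss_t[!pat])))
  # incongruent slower than color naming in expectation
  expect_gt(mean(beh$stroop_incong_time, na.rm = TRUE),
            mean(beh$stroop_color_time, na.rm = TRUE))
  # one subject per group did not finish the Stroop task
  expect_equal(sum(is.na(beh$stroop_color_time)), 2L)
  # accuracies are proportions
  acc <- unlist(beh[, grep("_acc$", names(beh))])
  expect_true(all(is.na(acc) | (acc >= 0 & acc <= 1)))
  # imaging measure of the wrong length is rejected
  expect_error(
    generate_behavior(tiny_config(), imaging = list(ai = rnorm(3))),
    "length")
})

test_that("mirrored construction yields no asymmetry downstream", {
  runs <- vapply(1:10, function(s) {
    cfg <- tiny_config(coupling_spec = symmetric_couplings(),
                       mirror = TRUE, n_timepoints = 40L,
                       n_per_group = c(control = 4L, patient = 4L),
                       rng_seed = 4000L + s)
    zm <- subject_zmaps(generate_bold(cfg), spec = NULL)
    max(vapply(zm$contrast, function(m) max(abs(m$values)), 0))
  }, 0)
  expect_true(all(runs == 0))
})
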