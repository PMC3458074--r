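test_that("one-sample t map matches hand computation and handles degeneracy", {
  d <- c(3, 3, 2)
  maps <- lapply(c(1, 2, 3), function(v) array(v, d))
  tm <- one_sample_tmap(maps)
  expect_identical(tm$df, 2L)
  expect_equal(tm$values[1], 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(tm$values[1], 3.4641, tolerance = 1e-4)
  # identical nonzero constant maps: zero-variance rule, t = 0, counted
  same <- lapply(1:4, function(i) array(2, d))
  tm0 <- one_sample_tmap(same)
  expect_true(all(tm0$values == 0))
  expect_equal(attr(tm0, "n_zero_variance"), prod(d))
  # sign flip negates the map
  maps_r <- random_zmaps(5, d)
  expect_equal(one_sample_tmap(lapply(maps_r, function(m) -m))$values,
               -one_sample_tmap(maps_r)$values, tolerance = 1e-12)
  expect_error(one_sample_tmap(maps_r[1:2]), "at least 3")
})

test_that("paired t equals one-sample t on differences, bit for bit", {
  a <- random_zmaps(6, c(4, 4, 3), seed = 11)
  b <- random_zmaps(6, c(4, 4, 3), seed = 12)
  tp <- paired_tmap(a, b)
  t1 <- one_sample_tmap(Map(`-`, a, b))
  expect_identical(tp$values, t1$values)
  expect_identical(tp$df, 5L)
  # a = b: all-zero map via the zero-variance rule
  expect_true(all(paired_tmap(a, a)$values == 0))
  # constant nonzero differences engage the zero-variance rule
  shifted <- lapply(a, function(m) m + 1)
  tc <- paired_tmap(shifted, a)
  expect_true(all(tc$values == 0))
  expect_gt(attr(tc, "n_zero_variance"), 0)
  expect_error(paired_tmap(a, b[1:3]), "length")
})

test_that("two-sample t map matches the pooled formula oracle", {
  g1 <- random_zmaps(7, c(4, 3, 3), seed = 13)
  g2 <- random_zmaps(5, c(4, 3, 3), seed = 14)
  tm <- two_sample_tmap(g1, g2)
  expect_identical(tm$df, 10L)
  expect_equal(tm$values, oracle_two_sample_t(g1, g2), tolerance = 1e-10)
  # swapping the groups negates the map
  expect_equal(two_sample_tmap(g2, g1)$values, -tm$values, tolerance = 1e-12)
  expect_error(two_sample_tmap(g1[1], g2), "at least 2")
  # Welch option agrees voxelwise with t.test
  tw <- two_sample_tmap(g1, g2, var_equal = FALSE)
  for (v in sample(prod(dim(tw$values)), 8)) {
    x <- vapply(g1, function(a) a[v], 0)
    y <- vapply(g2, function(a) a[v], 0)
    expect_equal(tw$values[v], unname(t.test(x, y)$statistic),
                 tolerance = 1e-10)
  }
})

test_that("summary-statistic t tests agree with t.test on raw data", {
  set.seed(15)
  x <- rnorm(20, 1, 2); y <- rnorm(25, 0, 2)
  ours <- two_sample_t_from_stats(mean(x), sd(x), 20, mean(y), sd(y), 25)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
  ow <- two_sample_t_from_stats(mean(x), sd(x), 20, mean(y), sd(y), 25,
                                var_equal = FALSE)
  rw <- t.test(x, y)
  expect_equal(ow$statistic, unname(rw$statistic), tolerance = 1e-10)
  expect_equal(ow$df, unname(rw$parameter), tolerance = 1e-8)
  o1 <- one_sample_t_from_stats(mean(x), sd(x), 20)
  r1 <- t.test(x)
  expect_equal(o1$statistic, unname(r1$statistic), tolerance = 1e-10)
  expect_equal(o1$p.value, r1$p.value, tolerance = 1e-10)
})

test_that("cluster labeling honors the neighborhood definition", {
  d <- c(3, 3, 3)
  # two voxels sharing a face
  m <- array(FALSE, d); m[1, 1, 1] <- m[2, 1, 1] <- TRUE
  cl <- label_clusters(m, "faces")
  expect_equal(cl$sizes, 2L)
  # two voxels sharing only an edge: separate under faces, joined under edges
  m2 <- array(FALSE, d); m2[1, 1, 1] <- m2[2, 2, 1] <- TRUE
  expect_equal(sort(label_clusters(m2, "faces")$sizes), c(1L, 1L))
  expect_equal(label_clusters(m2, "edges")$sizes, 2L)
  # corner-only contact needs the full 26-neighborhood
  m3 <- array(FALSE, d); m3[1, 1, 1] <- m3[2, 2, 2] <- TRUE
  expect_equal(sort(label_clusters(m3, "edges")$sizes), c(1L, 1L))
  expect_equal(label_clusters(m3, "corners")$sizes, 2L)
  # a full mask is one cluster of its own size
  full <- array(TRUE, d)
  expect_equal(label_clusters(full, "faces")$sizes, 27L)
  # empty map: empty table
  expect_equal(label_clusters(array(FALSE, d))$sizes, integer(0))
  # enumeration oracle on a random 3x3x3 pattern: component count by
  # exhaustive pairwise flood fill
  set.seed(16)
  m4 <- array(runif(27) < 0.4, d)
  cl4 <- label_clusters(m4, "faces")
  idx <- which(m4); coords <- arrayInd(idx, d)
  parent <- seq_along(idx)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (a in seq_along(idx)) for (b in seq_along(idx)) {
    if (sum(abs(coords[a, ] - coords[b, ])) == 1) {
      parent[find(a)] <- find(b)
    }
  }
  n_comp <- length(unique(vapply(seq_along(idx), find, 0L)))
  expect_equal(length(cl4$sizes), n_comp)
})

test_that("unit-variance smoothing keeps white noise standardized", {
  set.seed(17)
  v <- array(rnorm(20^3), c(20, 20, 20))
  s <- gaussian_smooth(v, fwhm_mm = 6, voxel_size_mm = 3, var_norm = TRUE)
  expect_lt(abs(sd(s) - 1), 0.1)
  expect_lt(abs(mean(s)), 0.05)
  # smoothing induces positive neighbor correlation
  expect_gt(cor(as.vector(s[-20, , ]), as.vector(s[-1, , ])), 0.3)
  expect_identical(gaussian_smooth(v, 0), v)
  # a 4D stack smooths each volume independently
  stack <- array(rnorm(10 * 10 * 10 * 3), c(10, 10, 10, 3))
  sm4 <- gaussian_smooth(stack, 6, 3, var_norm = TRUE)
  for (i in 1:3) {
    expect_equal(sm4[, , , i],
                 gaussian_smooth(stack[, , , i], 6, 3, var_norm = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("cluster null reproduces the independent-voxel closed form at fwhm 0", {
  mask <- array(FALSE, c(10, 10, 1)); mask[1:50] <- TRUE
  null <- simulate_cluster_null(mask, fwhm_mm = 0, voxel_p = 0.001,
                                n_iter = 2000, seed = 18)
  # exact binomial oracle: P(any suprathreshold voxel) = 1 - 0.999^50
  p_any <- 1 - 0.999^50
  expect_lt(abs(mean(null$max_extents >= 1) - p_any),
            3 * sqrt(p_any * (1 - p_any) / 2000))
  expect_lte(extent_threshold(null, 0.05), 2L)
  expect_equal(extent_threshold(null, 1), 1L)
})

test_that("voxel_p = 1 floods the mask and yields the no-threshold sentinel", {
  mask <- array(TRUE, c(4, 4, 3))
  null <- simulate_cluster_null(mask, fwhm_mm = 0, voxel_p = 1,
                                n_iter = 200, seed = 19)
  expect_true(all(null$max_extents == 48L))
  expect_warning(k <- extent_threshold(null, 0.05), "no finite")
  expect_identical(k, Inf)
})

test_that("extent thresholds are monotone in voxel p", {
  mask <- array(TRUE, c(12, 12, 12))
  n1 <- simulate_cluster_null(mask, fwhm_mm = 6, voxel_p = 0.01,
                              n_iter = 300, seed = 20)
  n2 <- simulate_cluster_null(mask, fwhm_mm = 6, voxel_p = 0.001,
                              n_iter = 300, seed = 20)
  expect_gte(extent_threshold(n1, 0.05), extent_threshold(n2, 0.05))
})

test_that("correct_map applies the strict extent rule on planted blobs", {
  d <- c(10, 10, 10)
  tv <- array(0, d)
  blob <- box_mask(d, 2:6, 2:5, 2:2)  # 5 x 4 x 1 = 20 voxels
  tv[blob] <- 8
  tm <- stat_map(tv, "t", df = 20L)
  res <- correct_map(tm, voxel_p = 0.001, min_extent = 14)
  expect_equal(nrow(res$clusters), 1L)
  expect_equal(res$clusters$extent_voxels, 20L)
  expect_equal(res$clusters$extent_mm3, 540)
  expect_equal(res$clusters$sign, "positive")
  expect_identical(res$map$values != 0, blob)
  # strict inequality: a 20-voxel blob dies at min_extent = 20
  res20 <- correct_map(tm, voxel_p = 0.001, min_extent = 20)
  expect_equal(nrow(res20$clusters), 0L)
  expect_true(all(res20$map$values == 0))
  # all-zero map: empty table
  res0 <- correct_map(stat_map(array(0, d), "t", df = 20L), 0.001, 14)
  expect_equal(nrow(res0$clusters), 0L)
  # positive and negative clusters labeled separately
  tv2 <- tv; tv2[box_mask(d, 7:9, 7:9, 5:8)] <- -9
  both <- correct_map(stat_map(tv2, "t", df = 20L), 0.001, 10)
  expect_setequal(both$clusters$sign, c("positive", "negative"))
  # analysis mask restricts the search
  masked <- correct_map(tm, 0.001, 14, analysis_mask = !blob)
  expect_equal(nrow(masked$clusters), 0L)
  expect_error(correct_map(stat_map(tv, "t"), 0.001, 14), "degrees of freedom")
})

test_that("two-criterion asymmetry mask intersects paired and union maps", {
  d <- c(8, 8, 4)
  zero <- stat_map(array(0, d), "t", df = 5L)
  paired <- array(0, d); paired[box_mask(d, 2:5, 2:5, 2:3)] <- 4
  paired <- stat_map(paired, "t", df = 5L)
  lacc <- array(0, d); lacc[box_mask(d, 2:3, 2:5, 2:3)] <- 6
  lacc <- stat_map(lacc, "t", df = 5L)
  # empty union: nothing survives no matter the paired map
  m0 <- asymmetry_within_group_mask(zero, zero, paired)
  expect_true(all(m0$values == 0))
  # paired cluster fully inside the union survives intact
  big <- stat_map(array(1, d), "t", df = 5L)
  m1 <- asymmetry_within_group_mask(big, zero, paired)
  expect_equal(sum(m1$values), sum(paired$values != 0))
  # straddling cluster: only the overlapping voxels survive
  m2 <- asymmetry_within_group_mask(lacc, zero, paired)
  expect_equal(which(m2$values != 0),
               which(paired$values != 0 & lacc$values != 0))
  expect_equal(sum(m2$values), 2 * 4 * 2)
})

test_that("voxel extents convert to mm^3 at 27 mm^3 per voxel", {
  expect_equal(voxels_to_mm3(c(14, 13, 10)), c(378, 351, 270))
  expect_equal(voxels_to_mm3(1, voxel_size_mm = 2), 8)
})
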