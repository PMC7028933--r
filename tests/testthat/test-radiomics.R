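# Radiomic extraction: roster contract, first-order statistics, shape and
# curvature closed forms, texture conventions, delta features and
# normalization.

test_that("the roster defines exactly 423 uniquely named features in blocks", {
  roster <- feature_roster()
  expect_equal(nrow(roster), 423)
  expect_equal(as.integer(table(roster$category)[c("first_order", "shape",
                                                   "texture", "curvature")]),
               c(146L, 33L, 200L, 44L))
  expect_false(anyDuplicated(roster$name) > 0)
})

test_that("extract_features matches the roster order and is deterministic", {
  lv <- sphere_volume(1, 0.2, seed = 3)
  f1 <- extract_features(lv)
  expect_equal(ncol(f1), 423)
  expect_equal(names(f1), feature_roster()$name)
  expect_true(all(is.finite(unlist(f1))))
  expect_true("shape.volume_to_surface_ratio" %in% names(f1))
  f2 <- extract_features(lv)
  expect_identical(unlist(f1), unlist(f2))
})

test_that("features are invariant to translation and background padding", {
  set.seed(11)
  n <- 24
  mask <- sphere_mask(0.9, 0.2, margin = 2)
  img <- array(rnorm(length(mask)), dim(mask))
  f1 <- extract_features(labeled_volume(img, mask, rep(0.2, 3)))
  # embed the same lesion elsewhere in a larger grid
  big_m <- array(FALSE, dim(mask) + c(8, 6, 10))
  big_i <- array(0, dim(big_m))
  idx <- which(mask, arr.ind = TRUE)
  sh <- c(5, 2, 7)
  big_m[sweep(idx, 2, sh, `+`)] <- TRUE
  big_i[sweep(idx, 2, sh, `+`)] <- img[idx]
  f2 <- extract_features(labeled_volume(big_i, big_m, rep(0.2, 3)))
  expect_equal(unlist(f1), unlist(f2), tolerance = 1e-12)
})

test_that("first-order statistics match direct computation", {
  # constant field
  mask <- array(TRUE, c(3, 3, 3))
  lv <- labeled_volume(array(7, c(3, 3, 3)), mask, c(1, 1, 1))
  f <- extract_first_order(lv)
  expect_equal(f$fo.mean, 7)
  expect_equal(f$fo.variance, 0)
  expect_equal(f$fo.hist32_entropy, 0)
  expect_equal(f$fo.min, 7)
  expect_equal(f$fo.max, 7)
  expect_equal(f$fo.median, 7)
  # intensities 1..100 with the linear-interpolation percentile convention
  m2 <- array(TRUE, c(10, 10, 1))
  lv2 <- labeled_volume(array(1:100, c(10, 10, 1)), m2, c(1, 1, 1))
  f2 <- extract_first_order(lv2)
  expect_equal(f2$fo.mean, 50.5)
  expect_equal(f2$fo.p010.0, 10.9)
  expect_equal(f2$fo.p050.0, 50.5)
  expect_equal(ncol(f2), 146)
  # single voxel: dispersion defined as zero
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  f3 <- extract_first_order(labeled_volume(array(5, c(3, 3, 3)), one, c(1, 1, 1)))
  expect_equal(f3$fo.sd, 0)
  expect_true(all(is.finite(unlist(f3))))
})

test_that("shape features reproduce sphere and cube closed forms", {
  r <- 6; sp <- 0.5
  lv <- sphere_volume(r, sp, seed = 5)
  f <- extract_shape(lv)
  expect_equal(ncol(f), 33)
  expect_equal(f$shape.volume_to_surface_ratio, r / 3, tolerance = 0.05)
  expect_equal(f$shape.sphericity, 1, tolerance = 0.05)
  expect_equal(f$shape.max_3d_diameter, 2 * r, tolerance = 0.08)
  expect_equal(f$shape.elongation, 1, tolerance = 0.05)
  # 10 mm cube at 1 mm voxels: exact voxel volume, near-exact surface
  box <- array(FALSE, c(14, 14, 14)); box[3:12, 3:12, 3:12] <- TRUE
  lvb <- labeled_volume(array(rnorm(14^3), c(14, 14, 14)), box, c(1, 1, 1))
  fb <- extract_shape(lvb)
  expect_equal(fb$shape.volume_voxel, 1000)
  expect_equal(voxel_face_area(box, c(1, 1, 1)), 600) # face-counting oracle
  expect_equal(fb$shape.surface_area, 600, tolerance = 0.10)
  expect_equal(fb$shape.bbox_volume, 1000)
})

test_that("curvature features approach sphere closed forms and Gauss-Bonnet", {
  r <- 6; sp <- 0.5
  lv <- sphere_volume(r, sp, seed = 6)
  mesh <- mask_mesh(lv$mask, lv$spacing)
  curv <- mesh_curvature(mesh)
  va <- attr(curv, "vertex_area")
  expect_equal(mean(curv$mean), 1 / r, tolerance = 0.10)
  expect_equal(mean(curv$gaussian), 1 / r^2, tolerance = 0.15)
  # integrated Gaussian curvature vs the exact angle-defect total (4 pi)
  expect_equal(attr(curv, "total_gaussian"), 4 * pi, tolerance = 1e-9)
  expect_equal(sum(curv$gaussian * va), 4 * pi, tolerance = 0.10)
  f <- extract_curvature(lv, mesh)
  expect_equal(ncol(f), 44)
  expect_equal(f$curv.mean_mean, 1 / r, tolerance = 0.10)
  expect_equal(f$curv.gaussian_mean, 1 / r^2, tolerance = 0.15)
  expect_true(all(curv$k1 >= curv$k2))
})

test_that("texture statistics match the R reference implementation", {
  lv <- sphere_volume(0.8, 0.2, seed = 9)
  f <- extract_texture(lv)
  expect_equal(ncol(f), 200)
  expect_true(all(is.finite(unlist(f))))
  # dual-route check: C++ fused counts+stats vs the R-side reference on the
  # same discretized array
  lab <- icbmri:::discretize_mask(list(intensities = lv$intensities,
                                       mask = lv$mask), 8)
  offs <- icbmri:::tex_offsets(1L)
  cpp <- icbmri:::.glcm_stats_cpp(as.integer(lab), dim(lab), 8L, offs)
  counts <- icbmri:::.glcm_counts_cpp(as.integer(lab), dim(lab), 8L, offs)
  for (o in seq_len(nrow(offs))) {
    M <- counts[[o]]
    if (sum(M) == 0) M[1, 1] <- 1 else M <- M / sum(M)
    ref <- icbmri:::glcm_stat_vector(M, icbmri:::glcm_stats_d1)
    expect_equal(unname(cpp[, o]), unname(ref), tolerance = 1e-10,
                 info = paste("offset", o))
  }
  rl_cpp <- icbmri:::.glrlm_stats_cpp(as.integer(lab), dim(lab), 8L, offs,
                                      max(dim(lab)))
  rl_counts <- icbmri:::.glrlm_counts_cpp(as.integer(lab), dim(lab), 8L, offs,
                                          max(dim(lab)))
  for (o in seq_len(nrow(offs))) {
    ref <- icbmri:::glrlm_stat_vector(rl_counts[[o]])
    expect_equal(unname(rl_cpp[, o]), unname(ref), tolerance = 1e-10)
  }
})

test_that("degenerate and hand-enumerated texture cases take their closed forms", {
  # constant intensity: contrast 0, homogeneity 1 at every bin count
  mask <- sphere_mask(0.6, 0.2, margin = 2)
  lv <- labeled_volume(array(3, dim(mask)), mask, rep(0.2, 3))
  f <- extract_texture(lv)
  for (b in c(8, 16, 32, 64)) {
    expect_equal(f[[sprintf("tex.glcm_d1_b%d_contrast", b)]], 0)
    expect_equal(f[[sprintf("tex.glcm_d1_b%d_id", b)]], 1)
    expect_equal(f[[sprintf("tex.glcm_d1_b%d_correlation", b)]], 1)
  }
  # a single alternating row: only the row-aligned offset has pairs, with
  # all pairs in the extreme bins; the other 12 offsets are degenerate
  m <- array(FALSE, c(8, 3, 3)); m[1:8, 2, 2] <- TRUE
  img <- array(0, c(8, 3, 3)); img[1:8, 2, 2] <- rep(c(1, 2), 4)
  ft <- extract_texture(labeled_volume(img, m, c(1, 1, 1)))
  for (b in c(8, 16, 32, 64)) {
    expect_equal(ft[[sprintf("tex.glcm_d1_b%d_contrast", b)]], (b - 1)^2 / 13,
                 tolerance = 1e-10)
    expect_equal(ft[[sprintf("tex.glcm_d1_b%d_max_probability", b)]],
                 (0.5 + 12) / 13, tolerance = 1e-10)
  }
})

test_that("delta features are absolute, symmetric and roster-checked", {
  f1 <- tibble::tibble(a = 5, b = 2)
  f2 <- tibble::tibble(a = 3, b = 9)
  d <- delta_features(f1, f2)
  expect_equal(unlist(d), c(delta_a = 2, delta_b = 7))
  expect_equal(unlist(delta_features(f2, f1)), unlist(d))
  expect_true(all(unlist(delta_features(f1, f1)) == 0))
  expect_error(delta_features(f1, tibble::tibble(a = 1, c = 2)), "roster")
})

test_that("z-score normalization is exact, reusable and invertible", {
  tbl <- tibble::tibble(id = c("a", "b", "c"), x = c(1, 2, 3),
                        y = c(4, 4, 4), z = c(10, 0, 5))
  norm <- zscore_normalize(tbl)
  expect_equal(norm$x, c(-1, 0, 1))
  expect_equal(norm$y, c(0, 0, 0)) # constant column, flagged
  st <- attr(norm, "norm_state")
  expect_true(st$constant[st$column == "y"])
  expect_equal(mean(norm$z), 0, tolerance = 1e-10)
  expect_equal(sd(norm$z), 1, tolerance = 1e-10)
  # round trip and held-out application
  back <- denormalize(norm)
  expect_equal(back$z, tbl$z, tolerance = 1e-10)
  held <- apply_normalization(tibble::tibble(id = "d", x = 2, y = 9, z = 0), st)
  expect_equal(held$x, 0)
  expect_equal(held$y, 0)
  expect_error(zscore_normalize(tbl[1, ]), "2 rows")
})
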