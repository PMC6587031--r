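test_that("compiled co-occurrence counts match a brute-force oracle", {
  set.seed(4)
  disc <- array(sample(0:4, 6^3, replace = TRUE), c(6, 6, 6))
  cpp <- matrix(rowSums(mrtraj:::cpp_glcm(as.integer(disc), dim(disc), 4L)),
                4, 4)
  expect_equal(cpp, oracle_glcm_counts(disc, 4L), tolerance = 1e-12)
})

test_that("degenerate and hand-computable ROIs give the expected textures", {
  m <- tumor_mask(array(TRUE, c(4, 4, 4)))
  f <- compute_texture_features(image_volume(array(7, c(4, 4, 4))), m, 32)
  expect_equal(f[["firstorder_variance"]], 0)
  expect_equal(f[["firstorder_entropy"]], 0)
  expect_equal(f[["glcm_contrast"]], 0)
  expect_true(all(is.finite(f)))
  expect_length(f, 92)

  # 4x4x1 checkerboard at 2 gray levels: off-diagonal mass only on the
  # axial directions, same-level pairs on the two in-plane diagonals;
  # contrast from the oracle count matrix = 24/42
  cb <- array((row(matrix(0, 4, 4)) + col(matrix(0, 4, 4))) %% 2, c(4, 4, 1))
  f2 <- compute_texture_features(image_volume(cb),
                                 tumor_mask(array(TRUE, c(4, 4, 1))), 2)
  oc <- oracle_glcm_counts(array(as.integer(cb) + 1L, dim(cb)), 2L)
  expect_equal(f2[["glcm_contrast"]],
               sum(abs(row(oc) - col(oc))^2 * oc) / sum(oc))  # = 24/42
  expect_equal(f2[["glcm_contrast"]], 24 / 42, tolerance = 1e-12)
  expect_equal(f2[["glcm_maximum_probability"]],
               max(oc) / sum(oc), tolerance = 1e-12)

  # 8 uniform values at 8 bins: 3-bit first-order entropy
  f3 <- compute_texture_features(image_volume(array(1:8, c(8, 1, 1))),
                                 tumor_mask(array(TRUE, c(8, 1, 1))), 8)
  expect_equal(f3[["firstorder_entropy"]], 3, tolerance = 1e-12)
  expect_equal(f3[["firstorder_uniformity"]], 1 / 8, tolerance = 1e-12)
})

test_that("texture is invariant to outside-mask voxels and to affine rescaling", {
  set.seed(8)
  vox <- array(rnorm(8^3, 100, 15), c(8, 8, 8))
  mask <- array(FALSE, c(8, 8, 8)); mask[3:6, 2:7, 3:7] <- TRUE
  m <- tumor_mask(mask)
  f1 <- compute_texture_features(image_volume(vox), m, 16)
  vox2 <- vox; vox2[!mask] <- -999
  expect_identical(f1, compute_texture_features(image_volume(vox2), m, 16))
  # fixed bin count: affine intensity rescaling leaves the matrix families
  # untouched (first-order location/scale features of course move)
  f3 <- compute_texture_features(image_volume(3.7 * vox + 250), m, 16)
  matrix_feats <- grep("^(glcm|glrlm|glszm|gldm|ngtdm)_", names(f1), value = TRUE)
  expect_equal(f1[matrix_feats], f3[matrix_feats], tolerance = 1e-9)
  expect_equal(f1[["firstorder_entropy"]], f3[["firstorder_entropy"]],
               tolerance = 1e-9)
})

test_that("shape features match closed-form oracles", {
  # digital ball, radius 10 voxels at 1 mm spacing
  n <- 25L; ctr <- 12
  g <- expand.grid(x = 0:(n - 1), y = 0:(n - 1), z = 0:(n - 1))
  ball <- array((g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2 <= 100,
                c(n, n, n))
  sf <- compute_shape_features(tumor_mask(ball))
  expect_gt(sf[["sphericity"]], 0.95)
  expect_lte(sf[["sphericity"]], 1.0)
  expect_equal(sf[["mesh_volume"]], 4 / 3 * pi * 1000, tolerance = 0.05)
  expect_equal(sf[["surface_area"]], 4 * pi * 100, tolerance = 0.05)
  expect_equal(sf[["maximum_3d_diameter"]], 20, tolerance = 0.05)
  expect_equal(sf[["elongation"]], 1, tolerance = 1e-6)

  # two disjoint voxels 10 mm apart: diameter via brute-force distance
  two <- array(FALSE, c(15, 5, 5)); two[3, 3, 3] <- TRUE; two[13, 3, 3] <- TRUE
  sf2 <- compute_shape_features(tumor_mask(two))
  expect_equal(sf2[["maximum_3d_diameter"]], 10, tolerance = 1e-12)

  # single voxel: mesh volume near the voxel volume, diameter within the
  # voxel diagonal
  one <- array(FALSE, c(5, 5, 5)); one[3, 3, 3] <- TRUE
  sf1 <- compute_shape_features(tumor_mask(one))
  expect_gt(sf1[["mesh_volume"]], 0.2)
  expect_lt(sf1[["mesh_volume"]], 1.2)
  expect_lte(sf1[["maximum_3d_diameter"]], sqrt(3))
  expect_error(compute_shape_features(
    tumor_mask(array(c(TRUE, FALSE), c(2, 1, 1)))[c("voxels", "spacing",
                                                    "origin")]),
    class = "error")
})

test_that("anisotropic spacing enters volumes and diameters in mm", {
  cube <- array(TRUE, c(4, 4, 4))
  sf <- compute_shape_features(tumor_mask(cube, spacing = c(1, 2, 3)))
  expect_equal(sf[["voxel_volume"]], 64 * 6)
  expect_equal(sf[["maximum_3d_diameter"]],
               sqrt(3^2 + 6^2 + 9^2), tolerance = 1e-12)
})
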