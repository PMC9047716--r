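digital_ball <- function(r) {
  d <- 2 * r + 3
  g <- as.matrix(expand.grid(i = 0:(d - 1), j = 0:(d - 1), k = 0:(d - 1)))
  c0 <- (d - 1) / 2
  g[rowSums(sweep(g, 2, c0)^2) <= r^2, , drop = FALSE]
}

test_that("a digital ball approaches sphericity 1 as resolution grows", {
  s6 <- shape_features(digital_ball(6))
  s12 <- shape_features(digital_ball(12))
  expect_gt(s6[["shape_Sphericity"]], 0.9)
  expect_lte(s6[["shape_Sphericity"]], 1)
  expect_gt(s12[["shape_Sphericity"]], 0.97)
  expect_lte(s12[["shape_Sphericity"]], 1)
  expect_equal(s12[["shape_Elongation"]], 1, tolerance = 0.02)
  expect_equal(s12[["shape_Flatness"]], 1, tolerance = 0.02)
  # mesh volume converges on the true ball volume
  expect_equal(s12[["shape_MeshVolume"]], 4 / 3 * pi * 12^3,
    tolerance = 0.02
  )
})

test_that("a 1x1x10 rod reproduces the within-voxel PCA convention", {
  rod <- cbind(0L, 0L, 0:9)
  s <- shape_features(rod, c(1, 1, 1))
  # population variance of 0..9 is 8.25; cross-axes carry 1/12 each:
  # elongation = sqrt((1/12) / (8.25 + 1/12)) = 0.1 exactly
  expect_equal(s[["shape_Elongation"]], 0.1, tolerance = 1e-12)
  expect_equal(s[["shape_VoxelVolume"]], 10)
  expect_equal(s[["shape_MajorAxisLength"]], 4 * sqrt(8.25 + 1 / 12))
  expect_equal(s[["shape_Maximum3DDiameter"]], sqrt(1 + 1 + 100))
  expect_equal(s[["shape_Maximum2DDiameterSlice"]], sqrt(2))
  expect_equal(s[["shape_Maximum2DDiameterRow"]], sqrt(1 + 100))
  expect_equal(s[["shape_Maximum2DDiameterColumn"]], sqrt(1 + 100))
})

test_that("an exact cube mesh gives the closed-form cube sphericity", {
  # hand-built unit cube: 12 outward-oriented triangles
  v <- matrix(c(
    0, 0, 0, 1, 0, 0, 1, 1, 0, 0, 0, 0, 1, 1, 0, 0, 1, 0,
    0, 0, 1, 1, 1, 1, 1, 0, 1, 0, 0, 1, 0, 1, 1, 1, 1, 1,
    0, 0, 0, 0, 1, 0, 0, 1, 1, 0, 0, 0, 0, 1, 1, 0, 0, 1,
    1, 0, 0, 1, 1, 1, 1, 1, 0, 1, 0, 0, 1, 0, 1, 1, 1, 1,
    0, 0, 0, 0, 0, 1, 1, 0, 1, 0, 0, 0, 1, 0, 1, 1, 0, 0,
    0, 1, 0, 1, 1, 1, 0, 1, 1, 0, 1, 0, 1, 1, 0, 1, 1, 1
  ), ncol = 3, byrow = TRUE)
  mp <- mesh_properties(v)
  expect_equal(mp$area, 6)
  expect_equal(mp$volume, 1)
  expect_equal(mp$sphericity, (pi / 6)^(1 / 3), tolerance = 1e-12)
})

test_that("single-voxel ROIs stay finite with isotropic conventions", {
  s <- shape_features(cbind(2L, 3L, 4L), c(1, 1, 1))
  expect_true(all(is.finite(s)))
  expect_equal(s[["shape_Elongation"]], 1)
  expect_equal(s[["shape_Flatness"]], 1)
  expect_equal(s[["shape_VoxelVolume"]], 1)
  expect_equal(s[["shape_Maximum3DDiameter"]], sqrt(3))
})

test_that("voxel volume respects anisotropic spacing", {
  pts <- cbind(0:4, 0L, 0L)
  s <- shape_features(pts, c(1, 2, 0.5))
  expect_equal(s[["shape_VoxelVolume"]], 5 * 1 * 2 * 0.5)
  expect_equal(s[["shape_Maximum3DDiameter"]], sqrt(25 + 4 + 0.25))
})
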