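strip_roi <- function(levels) {
  list(
    coords = cbind(seq_along(levels) - 1L, 0L, 0L),
    disc = structure(
      list(
        bins = as.integer(levels), n_levels = max(levels),
        bin_width = 25
      ),
      class = "discretized_roi"
    )
  )
}

test_that("GLCM of a constant ROI is the degenerate single-cell matrix", {
  coords <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  storage.mode(coords) <- "integer"
  disc <- discretize_roi(rep(5, 8))
  f <- glcm_features(coords, disc)
  expect_equal(f[["glcm_JointEnergy"]], 1)
  expect_equal(f[["glcm_JointEntropy"]], 0)
  expect_equal(f[["glcm_Contrast"]], 0)
  expect_equal(f[["glcm_MaximumProbability"]], 1)
  expect_equal(f[["glcm_Correlation"]], 1)
})

test_that("GLCM of the alternating strip matches the hand enumeration", {
  s <- strip_roi(c(1, 2, 1, 2))
  # only the in-strip direction has pairs: P(1,2) = P(2,1) = 0.5
  f <- glcm_features(s$coords, s$disc)
  expect_equal(f[["glcm_Contrast"]], 1)
  expect_equal(f[["glcm_MaximumProbability"]], 0.5)
  expect_equal(f[["glcm_JointEntropy"]], 1)
  expect_equal(f[["glcm_JointEnergy"]], 0.5)
})

test_that("directional co-occurrence matrices are symmetric and normalized", {
  for (seed in c(3, 14)) {
    roi <- random_roi(seed)
    disc <- discretize_roi(roi$x)
    counts <- radiomath:::cpp_glcm_counts(
      radiomath:::.roi_bins_array(roi$coords, disc$bins), disc$n_levels
    )
    for (d in 1:13) {
      cm <- matrix(counts[, , d], disc$n_levels, disc$n_levels)
      cm <- cm + t(cm)
      if (sum(cm) == 0) next
      p <- cm / sum(cm)
      expect_equal(sum(p), 1, tolerance = 1e-9)
      expect_equal(p, t(p), tolerance = 1e-12)
    }
  }
})

test_that("run-length features match hand enumeration on 1D strips", {
  # constant strip, in-strip direction: one run of length 4
  s <- strip_roi(c(1, 1, 1, 1))
  arr <- radiomath:::.roi_bins_array(s$coords, s$disc$bins)
  counts <- radiomath:::cpp_glrlm_counts(arr, 1L)
  in_strip <- counts
  in_strip[, , 2:13] <- 0L # isolate direction (1,0,0)
  f <- radiomath:::cpp_glrlm_feats(in_strip, 1L, 4L)
  names(f) <- radiomath:::.glrlm_names
  expect_equal(f[["LongRunEmphasis"]], 16)
  expect_equal(f[["ShortRunEmphasis"]], 1 / 16)
  expect_equal(f[["RunPercentage"]], 0.25)

  # alternating strip: four runs of length 1 in every direction
  s2 <- strip_roi(c(1, 2, 1, 2))
  f2 <- glrlm_features(s2$coords, s2$disc)
  expect_equal(f2[["glrlm_ShortRunEmphasis"]], 1)
  expect_equal(f2[["glrlm_LongRunEmphasis"]], 1)
  expect_equal(f2[["glrlm_RunPercentage"]], 1)
})

test_that("GLSZM zones are 26-connected equal-level components", {
  coords <- as.matrix(expand.grid(0:1, 0:1, 0L))
  storage.mode(coords) <- "integer"
  disc <- discretize_roi(rep(10, 4))
  f <- glszm_features(coords, disc)
  expect_equal(f[["glszm_ZonePercentage"]], 0.25) # one zone of size 4
  expect_equal(f[["glszm_SmallAreaEmphasis"]], 1 / 16)
  expect_equal(f[["glszm_LargeAreaEmphasis"]], 16)

  # all-distinct levels: every zone has size 1
  disc2 <- structure(
    list(bins = 1:4, n_levels = 4L, bin_width = 25),
    class = "discretized_roi"
  )
  f2 <- glszm_features(coords, disc2)
  expect_equal(f2[["glszm_SmallAreaEmphasis"]], 1)
  expect_equal(f2[["glszm_ZonePercentage"]], 1)
})

test_that("GLDM dependence counts match the hand count on a 3x3 plane", {
  coords <- as.matrix(expand.grid(0:2, 0:2, 0L))
  storage.mode(coords) <- "integer"
  disc <- discretize_roi(rep(1, 9))
  arr <- radiomath:::.roi_bins_array(coords, disc$bins)
  cm <- radiomath:::cpp_gldm_counts(arr, 1L)
  expect_equal(cm[1, 9], 1) # centre voxel: 8 equal neighbours
  expect_equal(cm[1, 4], 4) # corners: 3 neighbours
  expect_equal(cm[1, 6], 4) # edges: 5 neighbours
  f <- gldm_features(coords, disc)
  # hand arithmetic on p = {4, 4, 1} / 9 at j = {4, 6, 9}
  expect_equal(
    f[["gldm_SmallDependenceEmphasis"]],
    (4 / 16 + 4 / 36 + 1 / 81) / 9
  )
  expect_equal(
    f[["gldm_LargeDependenceEmphasis"]],
    (4 * 16 + 4 * 36 + 81) / 9
  )
})

test_that("90-degree rotations leave direction-averaged features unchanged", {
  roi <- random_roi(42, n_max = 80)
  disc <- discretize_roi(roi$x)
  base <- c(
    glcm_features(roi$coords, disc), glrlm_features(roi$coords, disc),
    glszm_features(roi$coords, disc), gldm_features(roi$coords, disc)
  )
  mx <- max(roi$coords[, 1])
  rot <- cbind(roi$coords[, 2], mx - roi$coords[, 1], roi$coords[, 3])
  rot_f <- c(
    glcm_features(rot, disc), glrlm_features(rot, disc),
    glszm_features(rot, disc), gldm_features(rot, disc)
  )
  expect_equal(base, rot_f, tolerance = 1e-9)
  sb <- shape_features(roi$coords)
  sr <- shape_features(rot)
  exact <- paste0("shape_", c(
    "VoxelVolume", "Maximum3DDiameter", "MajorAxisLength", "Elongation",
    "Flatness"
  ))
  expect_equal(sb[exact], sr[exact], tolerance = 1e-9)
  # mesh quantities are only approximately equivariant: the tetrahedral
  # decomposition has a preferred cube diagonal
  expect_equal(sb[["shape_MeshVolume"]], sr[["shape_MeshVolume"]],
    tolerance = 0.05
  )
  expect_equal(sb[["shape_SurfaceArea"]], sr[["shape_SurfaceArea"]],
    tolerance = 0.05
  )
})

test_that("planted noise SD increases GLCM contrast in expectation", {
  coords <- as.matrix(expand.grid(0:5, 0:5, 0:5))
  storage.mode(coords) <- "integer"
  mean_contrast <- function(s) {
    mean(vapply(1:6, function(i) {
      set.seed(1000 * s + i)
      x <- rnorm(nrow(coords), 100, s)
      glcm_features(coords, discretize_roi(x))[["glcm_Contrast"]]
    }, 1.0))
  }
  c10 <- mean_contrast(10)
  c20 <- mean_contrast(20)
  c40 <- mean_contrast(40)
  expect_lt(c10, c20)
  expect_lt(c20, c40)
})
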