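subject_with_score <- function(mf_norm, id = "S001") {
  tibble::tibble(subject_id = id, grade = 4L, age = 9.5, sex = "F",
    mf_raw = NA_integer_, mf_norm = mf_norm)
}

test_that("label volume contains exactly the specified disjoint ROIs", {
  spec <- phantom_spec(shape = c(32, 32, 32), n_roi = 3)
  ph <- generate_phantom(subject_with_score(0.5), spec, seed = 1)
  tab <- table(ph$label[ph$label > 0])
  expect_identical(sort(as.integer(names(tab))), 1:3)
  # voxel counts match a direct evaluation of the ellipsoid inequality
  g <- spec$geometry
  for (r in 1:3) {
    ax <- (seq_len(32) - 0.5)
    cnt <- sum(outer(outer(((ax - g$cx[r]) / g$rx[r])^2,
      ((ax - g$cy[r]) / g$ry[r])^2, `+`
    ), ((ax - g$cz[r]) / g$rz[r])^2, `+`) <= 1)
    expect_equal(unname(tab[as.character(r)]), cnt, ignore_attr = TRUE)
  }
})

test_that("overlapping ROI geometry is rejected", {
  geom <- tibble::tibble(
    roi_label = 1:2, cx = c(16, 18), cy = 16, cz = 16,
    rx = 5, ry = 5, rz = 5
  )
  spec <- phantom_spec(shape = c(32, 32, 32), geometry = geom)
  expect_error(
    generate_phantom(subject_with_score(0.5), spec, seed = 1),
    "overlapping"
  )
})

test_that("phantom generation is deterministic under a fixed seed", {
  spec <- phantom_spec(shape = c(24, 24, 24), n_roi = 2)
  a <- generate_phantom(subject_with_score(0.3), spec, seed = 9)
  b <- generate_phantom(subject_with_score(0.3), spec, seed = 9)
  expect_identical(a, b)
  c <- generate_phantom(subject_with_score(0.3), spec, seed = 10)
  expect_false(identical(a$intensity, c$intensity))
})

test_that("zero-effect ROIs are statistically identical across subjects", {
  spec <- phantom_spec(shape = c(24, 24, 24), n_roi = 2)
  rejections <- 0
  set.seed(99)
  for (s in 1:8) {
    lo <- generate_phantom(subject_with_score(0), spec, seed = 100 + s)
    hi <- generate_phantom(subject_with_score(1, "S002"), spec, seed = 200 + s)
    # subsample voxels so spatial correlation does not distort the KS null
    a <- sample(lo$intensity[lo$label == 1], 50)
    b <- sample(hi$intensity[hi$label == 1], 50)
    p <- suppressWarnings(stats::ks.test(a, b)$p.value)
    rejections <- rejections + (p < 0.05)
  }
  expect_lte(rejections, 3) # nominal rate only
})

test_that("texture-contrast effect scales the ROI noise SD as 1 + beta * score", {
  sig <- tibble::tibble(
    roi_label = 1L, property = "texture-contrast",
    test = "mf", beta = 2
  )
  spec <- phantom_spec(shape = c(32, 32, 32), n_roi = 2, signal = sig)
  ratios <- vapply(1:5, function(s) {
    lo <- generate_phantom(subject_with_score(0), spec, seed = 300 + s)
    hi <- generate_phantom(subject_with_score(1, "S002"), spec, seed = 400 + s)
    sd(hi$intensity[hi$label == 1]) / sd(lo$intensity[lo$label == 1])
  }, 1.0)
  expect_gt(mean(ratios), 2.6) # oracle: direct simulation, target ratio 3
  expect_lt(mean(ratios), 3.4)
  # untouched ROI keeps its SD
  lo <- generate_phantom(subject_with_score(0), spec, seed = 301)
  hi <- generate_phantom(subject_with_score(1, "S002"), spec, seed = 401)
  r2 <- sd(hi$intensity[hi$label == 2]) / sd(lo$intensity[lo$label == 2])
  expect_lt(abs(r2 - 1), 0.35)
})

test_that("volume and mean-intensity effects act on the stated properties", {
  sigv <- tibble::tibble(
    roi_label = 1L, property = "volume",
    test = "mf", beta = 1
  )
  spec <- phantom_spec(shape = c(32, 32, 32), n_roi = 2, signal = sigv)
  lo <- generate_phantom(subject_with_score(0), spec, seed = 7)
  hi <- generate_phantom(subject_with_score(1, "S002"), spec, seed = 7)
  vr <- sum(hi$label == 1) / sum(lo$label == 1)
  expect_lt(abs(vr - 2), 0.25) # volume doubles (up to digitization)

  sigm <- tibble::tibble(
    roi_label = 1L, property = "mean-intensity",
    test = "mf", beta = 0.5
  )
  spec2 <- phantom_spec(shape = c(32, 32, 32), n_roi = 2, signal = sigm)
  lo <- generate_phantom(subject_with_score(0), spec2, seed = 8)
  hi <- generate_phantom(subject_with_score(1, "S002"), spec2, seed = 8)
  mr <- mean(hi$intensity[hi$label == 1]) / mean(lo$intensity[lo$label == 1])
  expect_lt(abs(mr - 1.5), 0.1)
})

test_that("fixture sets round-trip and refuse mismatched overwrites", {
  co <- generate_cohort(cohort_spec(), seed = 1)[1:3, ]
  spec <- phantom_spec(shape = c(20, 20, 20), n_roi = 2)
  dir1 <- withr::local_tempdir()
  man <- write_fixture_set(co, spec, dir1, seed = 5)
  files <- list.files(dir1)
  expect_length(grep("\\.nii\\.gz$", files), 6) # intensity + labels x 3
  expect_true("cohort.csv" %in% files)
  expect_true("manifest.json" %in% files)

  # read-back equals the in-memory volumes (labels exactly; intensity after
  # one float32 quantization, then byte-stable)
  ph <- generate_phantom(co[1, ], spec, seed = 5 + 1)
  lab <- read_nifti(file.path(dir1, paste0(co$subject_id[1], "_labels.nii.gz")))
  expect_identical(lab$data, ph$label)
  img <- read_nifti(file.path(
    dir1,
    paste0(co$subject_id[1], "_intensity.nii.gz")
  ))
  expect_equal(img$data, ph$intensity, tolerance = 1e-6)
  expect_identical(img$spacing, spec$spacing)

  # manifest spec hash is reproducible across runs
  dir2 <- withr::local_tempdir()
  man2 <- write_fixture_set(co, spec, dir2, seed = 5)
  expect_identical(man$spec_hash, man2$spec_hash)
  # same spec: overwrite allowed; different spec: refused
  expect_silent(write_fixture_set(co, spec, dir1, seed = 5))
  spec_b <- phantom_spec(shape = c(20, 20, 20), n_roi = 1)
  expect_error(write_fixture_set(co, spec_b, dir1, seed = 5), "refusing")
})
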