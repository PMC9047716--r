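test_that("fixed-bin-width discretization follows the floor rule", {
  d <- discretize_roi(c(0, 24, 25, 50), 25)
  expect_identical(d$bins, c(1L, 1L, 2L, 3L))
  expect_identical(d$n_levels, 3L)
  d2 <- discretize_roi(c(10, 40, 95), 25)
  expect_identical(d2$bins, c(1L, 2L, 4L))
  expect_identical(d2$n_levels, 4L)
  dc <- discretize_roi(rep(7.3, 10), 25)
  expect_true(all(dc$bins == 1L))
  expect_identical(dc$n_levels, 1L)
  expect_error(discretize_roi(numeric(0)), "empty")
  expect_error(discretize_roi(1:3, bin_width = 0))
})

test_that("histogram matching maps the input onto the reference distribution", {
  set.seed(1)
  x <- array(rnorm(4000, 50, 10), dim = c(20, 20, 10))
  # identity: matching a volume to itself returns it unchanged
  expect_equal(histogram_match(x, x), x, tolerance = 1e-12)
  # matching X to g(X) for strictly increasing g recovers g(X)'s histogram
  g <- function(v) v^3 / 1000
  out <- histogram_match(x, g(x))
  expect_equal(sort(as.numeric(out)), sort(as.numeric(g(x))),
    tolerance = 1e-9
  )
  expect_identical(dim(out), dim(x))
  # two-valued input to a two-valued reference with equal proportions
  xi <- rep(c(0, 100), each = 50)
  ref <- rep(c(10, 20), each = 50)
  expect_true(all(histogram_match(xi, ref) %in% c(10, 20)))
  expect_equal(unique(histogram_match(xi, ref)[xi == 0]), 10)
  expect_equal(unique(histogram_match(xi, ref)[xi == 100]), 20)
  # matching preserves ranks
  expect_identical(order(out), order(as.numeric(x)))
  expect_error(histogram_match(x, array(5, dim = c(2, 2, 2))), "constant")
})

test_that("first-order features of a constant ROI take degenerate values", {
  x <- rep(42, 20)
  f <- first_order_features(x)
  expect_equal(f[["firstorder_Variance"]], 0)
  expect_equal(f[["firstorder_Entropy"]], 0)
  expect_equal(f[["firstorder_Uniformity"]], 1)
  expect_equal(f[["firstorder_Range"]], 0)
  expect_equal(f[["firstorder_Skewness"]], 0)
  expect_equal(f[["firstorder_Kurtosis"]], 0)
  expect_equal(f[["firstorder_Mean"]], 42)
})

test_that("first-order features match hand-computed values on 1,2,3,4", {
  x <- c(1, 2, 3, 4)
  f <- first_order_features(x, voxel_volume = 2)
  # percentiles by linear interpolation between order statistics:
  # P10 = 1.3, P25 = 1.75, P50 = 2.5, P75 = 3.25, P90 = 3.7
  expect_equal(f[["firstorder_Mean"]], 2.5)
  expect_equal(f[["firstorder_Median"]], 2.5)
  expect_equal(f[["firstorder_Range"]], 3)
  expect_equal(f[["firstorder_InterquartileRange"]], 1.5)
  expect_equal(f[["firstorder_TenthPercentile"]], 1.3)
  expect_equal(f[["firstorder_NinetiethPercentile"]], 3.7)
  expect_equal(f[["firstorder_Energy"]], 30)
  expect_equal(f[["firstorder_TotalEnergy"]], 60)
  expect_equal(f[["firstorder_RootMeanSquared"]], sqrt(30 / 4))
  expect_equal(f[["firstorder_MeanAbsoluteDeviation"]], 1)
  # values within [P10, P90] are {2, 3}: robust MAD = 0.5
  expect_equal(f[["firstorder_RobustMeanAbsoluteDeviation"]], 0.5)
  expect_equal(f[["firstorder_Variance"]], 1.25)
})

test_that("symmetric intensities have zero skewness", {
  x <- c(-1, 0, 1) + 10
  expect_equal(first_order_features(x)[["firstorder_Skewness"]], 0)
})

test_that("adding a constant shifts location features only", {
  set.seed(8)
  x <- rnorm(60, 100, 20)
  a <- first_order_features(x)
  b <- first_order_features(x + 500)
  invariant <- paste0("firstorder_", c(
    "Entropy", "Uniformity", "InterquartileRange", "Range",
    "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
    "Skewness", "Kurtosis", "Variance"
  ))
  expect_equal(a[invariant], b[invariant], tolerance = 1e-9)
  expect_equal(b[["firstorder_Mean"]], a[["firstorder_Mean"]] + 500)
})
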