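demo_lite <- function() {
  ranking_config("demo",
    n_partitions = 3, models_per_partition = 2,
    n_trees = 15
  )
}

test_that("mae matches its definition", {
  expect_equal(mae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mae(c(0, 0), c(0.2, 0.4)), 0.3)
  set.seed(1)
  y <- runif(50)
  # constant-mean predictor: MAE equals mean absolute deviation about mean
  expect_equal(mae(rep(mean(y), 50), y), mean(abs(y - mean(y))))
  expect_error(mae(numeric(0), numeric(0)), "empty")
  expect_error(mae(1:3, 1:4), "mismatch")
})

test_that("the improvement statistic reproduces the printed reductions", {
  expect_equal(round(mae_improvement(0.257, 0.210)), 18)
  expect_equal(round(mae_improvement(0.112, 0.106)), 5)
  expect_equal(mae_improvement(0.2, 0.2), 0)
})

test_that("a deterministic feature drives the hold-out error far below baseline", {
  co <- small_cohort(n = 50, seed = 10)
  feats <- noise_features(co, p = 8, seed = 11)
  feats$f001 <- co$mf_norm # perfect predictor, catalogue position 1
  rk <- rank_area(feats, co, "mf", demo_lite(), seed = 1)
  base <- baseline_mae(co, "mf", demo_lite(), seed = 1)
  expect_lt(rk$median_mae, 0.6 * base)
  expect_lt(rk$median_mae, 0.08)
})

test_that("pure-noise features land inside the randomization-test null", {
  co <- small_cohort(n = 50, seed = 20)
  feats <- noise_features(co, p = 15, seed = 21)
  rk <- rank_area(feats, co, "mf", demo_lite(), seed = 2)
  nz <- noise_mae_distribution(co, "mf", demo_lite(),
    n_features = 15,
    n_replicates = 30, seed = 3
  )
  z <- (rk$median_mae - nz$mu) / nz$sigma
  expect_lt(abs(z), 3)
})

test_that("the ranking protocol is reproducible from (seed, config)", {
  co <- small_cohort(n = 40, seed = 30)
  feats <- noise_features(co, p = 10, seed = 31)
  a <- rank_area(feats, co, "mf", demo_lite(), seed = 5)
  b <- rank_area(feats, co, "mf", demo_lite(), seed = 5)
  expect_identical(a$partition_mae, b$partition_mae)
  expect_identical(a$importances, b$importances)
  c <- rank_area(feats, co, "mf", demo_lite(), seed = 6)
  expect_false(identical(a$partition_mae, c$partition_mae))
  expect_equal(a$median_mae, median(a$partition_mae))
})

test_that("per-model importances conserve to one and cover dropped features", {
  co <- small_cohort(n = 50, seed = 40)
  feats <- noise_features(co, p = 6, seed = 41)
  feats$f001 <- co$mf_norm + rnorm(50, sd = 0.05)
  feats$f002 <- feats$f001 * 2 # exact copy: dropped by selection
  rk <- rank_area(feats, co, "mf", demo_lite(), seed = 7)
  expect_identical(
    colnames(rk$importances),
    c("age", sprintf("f%03d", 1:6))
  )
  expect_equal(unname(rowSums(rk$importances)), rep(1, nrow(rk$importances)),
    tolerance = 1e-9
  )
  expect_true(all(rk$importances[, "f002"] == 0)) # dropped in every partition
})

test_that("rank_areas orders areas and reuses one baseline", {
  co <- small_cohort(n = 45, seed = 50)
  f1 <- noise_features(co, p = 6, seed = 51, roi_label = 1L)
  f1$f001 <- co$mf_norm + rnorm(45, sd = 0.02)
  f2 <- noise_features(co, p = 6, seed = 52, roi_label = 2L)
  f3 <- noise_features(co, p = 6, seed = 53, roi_label = 3L)
  rks <- rank_areas(dplyr::bind_rows(f1, f2, f3), co, "mf", demo_lite(),
    seed = 8
  )
  td <- tidy(rks)
  expect_identical(td$roi_label[1], 1L) # planted area ranks first
  expect_true(!is.unsorted(td$median_mae))
  expect_identical(length(unique(td$baseline_mae)), 1L)
  gl <- glance(rks)
  expect_identical(gl$best_roi, 1L)
  expect_identical(gl$n_areas, 3L)

  single <- rank_areas(f2, co, "mf", demo_lite(), seed = 8)
  expect_identical(nrow(tidy(single)), 1L)
})

test_that("misaligned inputs and degenerate splits are rejected", {
  co <- small_cohort(n = 40, seed = 60)
  feats <- noise_features(co, p = 5, seed = 61)
  expect_error(
    rank_area(feats[-3, ], co, "mf", demo_lite(), seed = 1),
    "missing for subjects"
  )
  tiny <- small_cohort(n = 8, seed = 62)
  cfg <- ranking_config("demo", train_fraction = 0.9)
  expect_error(
    rank_area(noise_features(tiny, p = 3, seed = 63), tiny, "mf", cfg,
      seed = 1
    ),
    "test split"
  )
})
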