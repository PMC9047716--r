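test_that("generated cohorts recover the per-grade means and SDs", {
  spec <- cohort_spec()
  co <- generate_cohort(spec, seed = 42, n_per_grade = rep(10000, 4))
  g <- wj3_grade_table()
  for (t in wj3_tests()$test) {
    for (r in seq_len(nrow(g))) {
      x <- co[[paste0(t, "_raw")]][co$grade == g$grade[r]]
      m_target <- g[[paste0(t, "_mean")]][r]
      s_target <- g[[paste0(t, "_sd")]][r]
      se_mean <- s_target / sqrt(length(x))
      se_sd <- s_target / sqrt(2 * length(x))
      expect_lt(abs(mean(x) - m_target), 3 * se_mean)
      expect_lt(abs(sd(x) - s_target), 3 * se_sd)
    }
  }
})

test_that("ages are uniform within grade bands and sexes follow group ratios", {
  co <- generate_cohort(cohort_spec(), seed = 7, n_per_grade = rep(5000, 4))
  g <- wj3_grade_table()
  for (r in seq_len(nrow(g))) {
    a <- co$age[co$grade == g$grade[r]]
    half <- sqrt(3) * g$age_sd[r]
    expect_true(all(a >= g$age_mean[r] - half - 1e-9))
    expect_true(all(a <= g$age_mean[r] + half + 1e-9))
    expect_lt(abs(mean(a) - g$age_mean[r]), 0.02)
    expect_lt(abs(sd(a) - g$age_sd[r]), 0.02)
    p_boy <- mean(co$sex[co$grade == g$grade[r]] == "M")
    expect_lt(abs(p_boy - g$n_boys[r] / g$n[r]), 0.03)
  }
})

test_that("identity correlation target yields uncorrelated age-partialled scores", {
  spec <- cohort_spec(partial_cor = diag(4) |>
    `dimnames<-`(list(wj3_tests()$test, wj3_tests()$test)))
  co <- generate_cohort(spec, seed = 3, n_per_grade = rep(6000, 4))
  pc <- partial_correlations(co)
  expect_lt(max(abs(pc[upper.tri(pc)])), 0.03)
})

test_that("cohort generation is byte-identical under a fixed seed", {
  spec <- cohort_spec()
  expect_identical(
    generate_cohort(spec, seed = 11),
    generate_cohort(spec, seed = 11)
  )
  expect_false(identical(
    generate_cohort(spec, seed = 11)$mf_raw,
    generate_cohort(spec, seed = 12)$mf_raw
  ))
})

test_that("scores are integer item counts within test bounds", {
  co <- generate_cohort(cohort_spec(), seed = 5, n_per_grade = rep(2000, 4))
  tests <- wj3_tests()
  for (i in seq_len(nrow(tests))) {
    x <- co[[paste0(tests$test[i], "_raw")]]
    expect_true(all(x == round(x)))
    expect_gte(min(x), 0)
    expect_lte(max(x), tests$max_items[i])
    xn <- co[[paste0(tests$test[i], "_norm")]]
    expect_gte(min(xn), 0)
    expect_lte(max(xn), 1)
  }
})

test_that("a non-positive-semidefinite correlation target is rejected", {
  bad <- matrix(c(
    1, 0.9, -0.9, 0, 0.9, 1, 0.9, 0, -0.9, 0.9, 1, 0,
    0, 0, 0, 1
  ), 4)
  dimnames(bad) <- list(wj3_tests()$test, wj3_tests()$test)
  expect_error(cohort_spec(partial_cor = bad), "positive semidefinite")
})

test_that("partial correlation is invariant to adding a pure-age component", {
  set.seed(21)
  n <- 400
  age <- runif(n, 8, 12)
  co <- tibble::tibble(
    subject_id = as.character(seq_len(n)), age = age,
    a_raw = rnorm(n) + 0.5 * rnorm(n), b_raw = rnorm(n)
  )
  co$b_raw <- co$b_raw + 0.4 * (co$a_raw - mean(co$a_raw)) # shared part
  base <- partial_correlations(co, c("a_raw", "b_raw"))["a_raw", "b_raw"]
  co2 <- co
  co2$a_raw <- co2$a_raw + 3 * age
  co2$b_raw <- co2$b_raw - 2 * age
  shifted <- partial_correlations(co2, c("a_raw", "b_raw"))["a_raw", "b_raw"]
  expect_equal(base, shifted, tolerance = 1e-10)
})

test_that("partial_correlations validates its input", {
  co <- generate_cohort(cohort_spec(), seed = 1)
  expect_error(partial_correlations(co[1:3, ]), "at least 4")
  co$flat_raw <- 2 * co$age # zero residual variance after age regression
  expect_warning(
    partial_correlations(co, c("mf_raw", "flat_raw")),
    "zero-variance"
  )
})
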