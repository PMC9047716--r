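# literal reimplementation of the stated sequential loop, used as oracle
oracle_decorrelate <- function(df, thr) {
  feats <- names(df)
  const <- feats[vapply(feats, function(f) stats::var(df[[f]]) == 0, TRUE)]
  kept <- setdiff(feats, const)
  i <- 1
  while (i <= length(kept)) {
    f <- kept[i]
    j <- i + 1
    while (j <= length(kept)) {
      r2 <- stats::cor(df[[f]], df[[kept[j]]])^2
      if (r2 > thr) kept <- kept[-j] else j <- j + 1
    }
    i <- i + 1
  }
  kept
}

test_that("an exact linear copy is dropped with its cause recorded", {
  set.seed(1)
  d <- tibble::tibble(f1 = rnorm(30))
  d$f2 <- 2 * d$f1
  d$f3 <- rnorm(30)
  sel <- decorrelate(d)
  expect_identical(sel$kept, c("f1", "f3"))
  expect_identical(sel$dropped, c(f2 = "f1"))
  expect_equal(sel$retention, 2 / 3)
})

test_that("the squared-correlation threshold is strictly greater-than", {
  set.seed(2)
  n <- 100
  f1 <- rnorm(n)
  e <- stats::residuals(stats::lm(rnorm(n) ~ f1))
  z1 <- (f1 - mean(f1)) / sd(f1)
  z2 <- e / sd(e)
  f2 <- sqrt(0.8) * z1 + sqrt(0.2) * z2
  r2 <- stats::cor(f1, f2)^2 # realized sample value, ~0.8
  d <- tibble::tibble(f1 = f1, f2 = f2)
  # at exactly the realized r2 both survive (strict inequality) ...
  expect_identical(decorrelate(d, threshold_r2 = r2)$kept, c("f1", "f2"))
  # ... while any lower threshold removes the later feature
  expect_identical(
    decorrelate(d, threshold_r2 = r2 - 1e-9)$dropped,
    c(f2 = "f1")
  )
})

test_that("the sequential rule matches the literal loop on correlated chains", {
  set.seed(3)
  n <- 300
  base <- rnorm(n)
  d <- tibble::tibble(
    f1 = base + rnorm(n, sd = 0.25),
    f2 = base + rnorm(n, sd = 0.25),
    f3 = base + rnorm(n, sd = 0.25),
    f4 = rnorm(n)
  )
  sel <- decorrelate(d)
  expect_identical(sel$kept, oracle_decorrelate(d, 0.8))
  expect_identical(sel$kept, c("f1", "f4"))
  expect_true(all(sel$dropped[c("f2", "f3")] == "f1"))
  # surviving pairs satisfy the threshold on the data used
  r2 <- stats::cor(as.matrix(d[sel$kept]))^2
  expect_true(all(r2[upper.tri(r2)] <= 0.8))
})

test_that("selection is idempotent on its own kept set", {
  set.seed(4)
  d <- tibble::as_tibble(matrix(rnorm(40 * 8), 40,
    dimnames = list(NULL, paste0("f", 1:8))
  ))
  d$f2 <- d$f1 + rnorm(40, sd = 0.1)
  sel <- decorrelate(d)
  again <- decorrelate(d[sel$kept])
  expect_identical(again$kept, sel$kept)
  expect_length(again$dropped, 0)
})

test_that("catalogue order decides which of two correlated features survives", {
  set.seed(5)
  n <- 200
  hub <- rnorm(n)
  e <- rnorm(n, sd = sqrt(0.2))
  d <- tibble::tibble(f1 = hub + e, f2 = hub, f3 = hub - e)
  r2_12 <- stats::cor(d$f1, d$f2)^2
  r2_13 <- stats::cor(d$f1, d$f3)^2
  skip_if_not(r2_12 > 0.8 && r2_13 < 0.8, "draw did not realize the pattern")
  expect_identical(decorrelate(d)$kept, c("f1", "f3"))
  expect_identical(decorrelate(d[c("f2", "f1", "f3")])$kept, "f2")
})

test_that("duplicated feature blocks collapse to one representative each", {
  set.seed(6)
  n <- 60
  blocks <- replicate(3, rnorm(n))
  d <- tibble::as_tibble(cbind(
    blocks[, rep(1:3, each = 4)] + rnorm(n * 12, sd = 1e-3),
    indep = rnorm(n)
  ), .name_repair = function(x) c(sprintf("b%02d", 1:12), "indep"))
  sel <- decorrelate(d)
  expect_length(sel$kept, 4) # 3 blocks + 1 independent
})

test_that("constants drop first and protected columns are untouchable", {
  set.seed(7)
  d <- tibble::tibble(
    subject_id = as.character(1:30), age = rnorm(30, 10),
    f1 = rnorm(30), f2 = rep(3, 30)
  )
  d$f3 <- d$age * 2 + rnorm(30, sd = 1e-6) # collinear with age
  sel <- decorrelate(d)
  expect_identical(unname(sel$dropped["f2"]), "constant")
  expect_true("f3" %in% sel$kept) # age never causes a removal
  expect_false("age" %in% c(sel$kept, names(sel$dropped)))
  expect_error(decorrelate(d[1:2, ]), "at least 3")
  td <- tidy(sel)
  expect_identical(nrow(td), 3L)
  expect_identical(td$cause[td$feature == "f2"], "constant")
})
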