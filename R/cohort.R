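#' Woodcock-Johnson III test metadata
#'
#' The four mathematical achievement tests the pipeline predicts, with their
#' maximum attainable raw scores (one point per item): Math fluency (160
#' items), Calculation (46), Applied problems (62), Quantitative concepts
#' (57).
#'
#' @return A tibble with columns `test`, `label`, `max_items`.
#' @export
wj3_tests <- function() {
  tibble::tibble(
    test = c("mf", "calc", "ap", "qc"),
    label = c(
      "Math fluency", "Calculation", "Applied problems",
      "Quantitative concepts"
    ),
    max_items = c(160L, 46L, 62L, 57L)
  )
}

#' Published per-grade cohort statistics
#'
#' Per-grade group sizes, boys/girls counts, age means/SDs and raw-score
#' means/SDs of the four tests for the reference cohort of 77 children in
#' grades 3-6 that the synthetic generator is calibrated to.
#'
#' @return A tibble with one row per grade.
#' @export
wj3_grade_table <- function() {
  tibble::tibble(
    grade = 3:6,
    n = c(24L, 24L, 17L, 12L),
    n_boys = c(9L, 15L, 12L, 7L),
    age_mean = c(8.5, 9.4, 10.6, 11.6),
    age_sd = c(0.33, 0.39, 0.37, 0.27),
    mf_mean = c(37.6, 46.5, 62.4, 63.3),
    mf_sd = c(6.9, 11.3, 18.6, 19.6),
    calc_mean = c(13.0, 16.8, 18.4, 19.3),
    calc_sd = c(2.4, 2.1, 1.8, 2.1),
    ap_mean = c(29.7, 33.8, 35.8, 39.3),
    ap_sd = c(3.0, 4.4, 3.5, 5.2),
    qc_mean = c(16.9, 19.4, 20.6, 22.8),
    qc_sd = c(2.1, 2.8, 1.6, 2.1)
  )
}

#' Published age-partialled inter-test correlations
#'
#' Target partial correlations (controlled by age) between the four test
#' scores for the reference cohort.
#'
#' @return A symmetric 4x4 correlation matrix with dimnames
#'   `c("mf","calc","ap","qc")`.
#' @export
wj3_partial_cor <- function() {
  tests <- wj3_tests()$test
  r <- diag(4)
  r[upper.tri(r)] <- c(0.386, 0.344, 0.503, 0.360, 0.498, 0.686)
  r[lower.tri(r)] <- t(r)[lower.tri(r)]
  dimnames(r) <- list(tests, tests)
  r
}

#' Specify a synthetic cohort
#'
#' Builds a cohort specification: per-grade group sizes, age bands, raw-score
#' means/SDs per test, and the target matrix of inter-test correlations
#' *after partialling out age*. The generator model is:
#' \deqn{X_{t} = m_t(g) + s'_t(g)\, z_t,\qquad z \sim N(0, R_z),}
#' with age uniform within grade-specific bands, scores rounded to integer
#' item counts and clipped to `[0, max_items]`.
#'
#' Because grade means are a non-linear function of age, residualizing on age
#' leaves a shared between-grade component in every pair of tests, and
#' integer rounding adds variance 1/12 to each marginal. When
#' `calibrate = TRUE` (the default) the latent correlation matrix \eqn{R_z}
#' and latent SDs \eqn{s'} are solved in closed form from the grade table so
#' that the *observed* age-partialled correlations and per-grade SDs converge
#' to the requested targets; with `calibrate = FALSE` the targets are used
#' verbatim as the latent parameters.
#'
#' @param grades Tibble like [wj3_grade_table()].
#' @param partial_cor Symmetric positive-semidefinite target correlation
#'   matrix over the tests (unit diagonal), as from [wj3_partial_cor()].
#' @param tests Test metadata tibble, see [wj3_tests()].
#' @param calibrate Solve for latent parameters so the generated data meet
#'   the targets (default `TRUE`).
#' @param seed Default integer seed stored in the spec (can be overridden in
#'   [generate_cohort()]).
#' @return An object of class `cohort_spec`.
#' @export
#' @examples
#' spec <- cohort_spec()
#' cohort <- generate_cohort(spec, seed = 1)
#' dplyr::count(cohort, grade)
cohort_spec <- function(grades = wj3_grade_table(),
                        partial_cor = wj3_partial_cor(),
                        tests = wj3_tests(),
                        calibrate = TRUE,
                        seed = 1L) {
  stopifnot(is.data.frame(grades), nrow(grades) >= 1, all(grades$n >= 1))
  tn <- tests$test
  need <- c("grade", "n", "age_mean", "age_sd", paste0(
    rep(tn, each = 2), c("_mean", "_sd")
  ))
  missing_cols <- setdiff(need, names(grades))
  if (length(missing_cols) > 0) {
    stop("grade table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!isTRUE(all.equal(partial_cor, t(partial_cor))) ||
    !isTRUE(all.equal(unname(diag(partial_cor)), rep(1, length(tn))))) {
    stop("partial_cor must be symmetric with unit diagonal")
  }
  ev <- eigen(partial_cor, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop(
      "partial_cor is not positive semidefinite (min eigenvalue ",
      format(min(ev)), ")"
    )
  }
  spec <- structure(
    list(
      grades = tibble::as_tibble(grades), partial_cor = partial_cor,
      tests = tests, calibrate = calibrate, seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
  spec$latent <- .solve_latent(spec)
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(
    "<cohort_spec> ", sum(x$grades$n), " subjects, grades ",
    paste(range(x$grades$grade), collapse = "-"), ", ",
    nrow(x$tests), " tests",
    if (x$calibrate) ", latent-calibrated" else "", "\n",
    sep = ""
  )
  invisible(x)
}

# Closed-form latent parameters (see the methods vignette).
# Population moments under the stated model, with grade weights w_g:
#   Var(A)  = Var_w(alpha) + sum_g w_g sigma_g^2          (age)
#   beta_t  = Cov_w(m_t, alpha) / Var(A)                  (age slope of test t)
#   G_ab    = Cov_w(m_a, m_b) - beta_a beta_b Var(A)      (grade residual part)
#   S_ab    = sum_g w_g s'_a(g) s'_b(g)                   (latent noise part)
# and the observed age-partialled correlation is
#   rho_obs = (G_ab + rho_z S_ab) / sqrt(V_a V_b),  V_t = G_tt + S_tt + 1/12,
# which is solved for rho_z given the target rho_obs. Rounding contributes
# the 1/12 terms; latent SDs are deconvolved as s'^2 = s^2 - 1/12.
.solve_latent <- function(spec) {
  g <- spec$grades
  tn <- spec$tests$test
  w <- g$n / sum(g$n)
  wcov <- function(a, b) sum(w * a * b) - sum(w * a) * sum(w * b)
  var_age <- wcov(g$age_mean, g$age_mean) + sum(w * g$age_sd^2)
  means <- as.matrix(g[paste0(tn, "_mean")])
  sds <- as.matrix(g[paste0(tn, "_sd")])
  if (spec$calibrate) {
    lat_sd2 <- pmax(sds^2 - 1 / 12, 1e-8)
  } else {
    lat_sd2 <- sds^2
  }
  lat_sd <- sqrt(lat_sd2)
  k <- length(tn)
  beta <- vapply(
    seq_len(k), function(t) wcov(means[, t], g$age_mean) / var_age, 0
  )
  G <- matrix(0, k, k)
  S <- matrix(0, k, k)
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      G[a, b] <- wcov(means[, a], means[, b]) - beta[a] * beta[b] * var_age
      S[a, b] <- sum(w * lat_sd[, a] * lat_sd[, b])
    }
  }
  if (!spec$calibrate) {
    rz <- spec$partial_cor
  } else {
    round_var <- 1 / 12
    v <- diag(G) + diag(S) + round_var
    rz <- diag(k)
    for (a in seq_len(k)) {
      for (b in seq_len(k)) {
        if (a != b) {
          rz[a, b] <-
            (spec$partial_cor[a, b] * sqrt(v[a] * v[b]) - G[a, b]) / S[a, b]
        }
      }
    }
    if (max(abs(rz[upper.tri(rz)])) > 1) {
      stop("latent calibration infeasible: implied |correlation| > 1")
    }
    ev <- eigen(rz, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      stop(
        "latent calibration infeasible: implied latent correlation matrix ",
        "is not positive semidefinite"
      )
    }
    # tiny negative eigenvalues from numerical solving: project back
    if (min(ev) < 0) {
      e <- eigen(rz, symmetric = TRUE)
      rz <- e$vectors %*% diag(pmax(e$values, 0)) %*% t(e$vectors)
      d <- sqrt(diag(rz))
      rz <- rz / tcrossprod(d)
    }
  }
  dimnames(rz) <- dimnames(spec$partial_cor)
  list(cor_z = rz, lat_sd = lat_sd, beta = beta, var_age = var_age)
}

#' Generate a synthetic cohort
#'
#' Draws a cohort of subjects from a [cohort_spec()]: grade, age (uniform
#' within the grade band), sex (binomial at the grade's boys proportion, kept
#' for realism but unused by the models), integer raw scores per test, and
#' per-test min-max normalized scores `*_norm` in `[0, 1]`.
#'
#' @param spec A `cohort_spec`.
#' @param seed Integer seed; defaults to the seed stored in the spec.
#'   The same seed gives a byte-identical cohort.
#' @param n_per_grade Optional integer vector overriding the per-grade group
#'   sizes (recycled to the number of grades), e.g. for large calibration
#'   runs.
#' @return A tibble with one row per subject: `subject_id`, `grade`, `age`,
#'   `sex`, `<test>_raw` and `<test>_norm` columns.
#' @export
generate_cohort <- function(spec, seed = NULL, n_per_grade = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(seed)) seed <- spec$seed
  g <- spec$grades
  tn <- spec$tests$test
  n_g <- if (is.null(n_per_grade)) {
    g$n
  } else {
    rep_len(as.integer(n_per_grade), nrow(g))
  }
  n <- sum(n_g)
  gi <- rep(seq_len(nrow(g)), n_g) # grade row index per subject

  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))

  half <- sqrt(3) * g$age_sd[gi]
  age <- g$age_mean[gi] + (stats::runif(n) - 0.5) * 2 * half
  p_boy <- if ("n_boys" %in% names(g)) g$n_boys / g$n else rep(0.5, nrow(g))
  sex <- ifelse(stats::runif(n) < p_boy[gi], "M", "F")

  cl <- chol(spec$latent$cor_z)
  z <- matrix(stats::rnorm(n * length(tn)), n) %*% cl
  raw <- matrix(0L, n, length(tn), dimnames = list(NULL, paste0(tn, "_raw")))
  for (t in seq_along(tn)) {
    x <- g[[paste0(tn[t], "_mean")]][gi] + spec$latent$lat_sd[gi, t] * z[, t]
    x <- round(pmin(pmax(x, 0), spec$tests$max_items[t]))
    raw[, t] <- as.integer(x)
  }
  out <- tibble::tibble(
    subject_id = sprintf("S%0*d", max(3L, nchar(n)), seq_len(n)),
    grade = g$grade[gi],
    age = age,
    sex = sex
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(raw))
  normalize_scores(out, tests = tn)
}

# Preserve caller RNG state so generators are self-contained.
.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_rng_state <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Add min-max normalized score columns
#'
#' Normalizes each `<test>_raw` column to `[0, 1]` by the cohort minimum and
#' maximum (the scale on which all MAEs are reported). A degenerate constant
#' score maps to 0.5.
#'
#' @param cohort Cohort tibble with `<test>_raw` columns.
#' @param tests Character vector of test codes (default the WJ-III four).
#' @return The cohort with `<test>_norm` columns added/replaced.
#' @export
normalize_scores <- function(cohort, tests = wj3_tests()$test) {
  for (t in tests) {
    x <- cohort[[paste0(t, "_raw")]]
    if (is.null(x)) stop("missing score column: ", paste0(t, "_raw"))
    rng <- range(x)
    cohort[[paste0(t, "_norm")]] <- if (diff(rng) == 0) {
      rep(0.5, length(x))
    } else {
      (x - rng[1]) / diff(rng)
    }
  }
  cohort
}

#' Age-partialled correlations between test scores
#'
#' Pearson correlations between the residuals of each score column after
#' linear regression on a control variable (age by default) — the statistic
#' the cohort generator is calibrated to.
#'
#' @param cohort Cohort tibble.
#' @param score_cols Score columns to correlate (default the four raw
#'   scores).
#' @param control Name of the control column (default `"age"`).
#' @return Symmetric correlation matrix; entries involving a zero-variance
#'   residual are `NA` (with a warning).
#' @export
#' @examples
#' co <- generate_cohort(cohort_spec(), seed = 1)
#' partial_correlations(co)["mf_raw", "calc_raw"]
partial_correlations <- function(cohort,
                                 score_cols = paste0(wj3_tests()$test, "_raw"),
                                 control = "age") {
  stopifnot(all(score_cols %in% names(cohort)), control %in% names(cohort))
  if (nrow(cohort) < 4) stop("need at least 4 subjects")
  a <- cohort[[control]]
  design <- cbind(1, a)
  res <- vapply(score_cols, function(cl) {
    stats::.lm.fit(design, cohort[[cl]])$residuals
  }, numeric(nrow(cohort)))
  sds <- apply(res, 2, stats::sd)
  sds[sds < 1e-10] <- 0 # residuals that vanish up to numerical noise
  if (any(sds == 0)) {
    warning("zero-variance residuals for: ", paste(
      score_cols[sds == 0],
      collapse = ", "
    ))
  }
  suppressWarnings(stats::cor(res))
}
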