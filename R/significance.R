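#' Two-sigma selection of "most relevant" areas
#'
#' Flags the values lying more than two sample standard deviations *below*
#' the mean of the supplied values — the rule used to pick the most
#' predictive areas out of the per-area MAE distribution. Under normality
#' the nominal lower-tail probability of this rule is `pnorm(-2)`, i.e.
#' 0.022 when truncated to three decimals (see [two_sigma_tail()]).
#'
#' @param values Numeric vector of length >= 3 (per-area MAEs).
#' @return Logical vector: `values < mean - 2 * sd` (sample SD). If the SD
#'   is zero no value is flagged, with a warning.
#' @export
#' @examples
#' two_sigma_flags(c(0.1, rep(0.2, 99)))
two_sigma_flags <- function(values) {
  if (length(values) < 3) stop("need at least 3 values")
  s <- stats::sd(values)
  if (s == 0) {
    warning("zero spread: no values flagged")
    return(rep(FALSE, length(values)))
  }
  values < mean(values) - 2 * s
}

#' Nominal tail probability of the two-sigma rule
#'
#' @param digits Truncation precision (default 3).
#' @return `pnorm(-2)` truncated (not rounded) to `digits` decimals: 0.022.
#' @export
two_sigma_tail <- function(digits = 3) {
  trunc(stats::pnorm(-2) * 10^digits) / 10^digits
}

#' Noise distribution of the ranking protocol (randomization test)
#'
#' Re-runs the identical area-ranking protocol on purely random inputs to
#' obtain the null distribution of the median hold-out MAE: each replicate
#' draws i.i.d. standard-normal features of the same dimensionality as a
#' typical post-selection area, runs [rank_area()] on them (with age, as for
#' real areas), and contributes one median MAE. The null is summarized by a
#' normal fit (mean and SD of the replicates).
#'
#' @param cohort Cohort tibble.
#' @param test Test code.
#' @param config A [ranking_config()].
#' @param n_features Number of random features per replicate (use the
#'   median post-selection feature count of the real areas).
#' @param n_replicates Number of replicates (>= 30; default 100).
#' @param seed Master seed.
#' @return An object of class `noise_distribution`: `mu`, `sigma`,
#'   `replicate_mae`, `n_features`.
#' @export
noise_mae_distribution <- function(cohort, test, config = ranking_config(),
                                   n_features = 30L, n_replicates = 100L,
                                   seed = 1L) {
  if (n_replicates < 30) stop("need at least 30 replicates")
  if (nrow(cohort) < 10 || stats::sd(cohort[[paste0(test, "_norm")]]) == 0) {
    stop("degenerate cohort for noise estimation")
  }
  reps <- vapply(seq_len(n_replicates), function(r) {
    rs <- .derive_seed(seed, 104729, r)
    old <- .save_rng_state()
    on.exit(.restore_rng_state(old), add = TRUE)
    set.seed(rs)
    X <- matrix(stats::rnorm(nrow(cohort) * n_features), nrow(cohort))
    colnames(X) <- sprintf("noise_%03d", seq_len(n_features))
    feats <- dplyr::bind_cols(
      tibble::tibble(subject_id = cohort$subject_id, roi_label = -1L),
      tibble::as_tibble(X)
    )
    rank_area(feats, cohort, test, config, seed = rs)$median_mae
  }, 1.0)
  sigma <- stats::sd(reps)
  if (sigma == 0) stop("degenerate noise distribution (zero spread)")
  structure(
    list(
      mu = mean(reps), sigma = sigma, replicate_mae = reps,
      n_features = as.integer(n_features), test = test, seed = seed
    ),
    class = "noise_distribution"
  )
}

#' @export
print.noise_distribution <- function(x, ...) {
  cat("<noise_distribution> ", length(x$replicate_mae), " replicates (",
    x$test, "): mu ", signif(x$mu, 4), ", sigma ", signif(x$sigma, 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' Area significance against the noise distribution
#'
#' Standardizes each area's median MAE against the randomization-test null:
#' `z = (median_mae - mu_noise) / sigma_noise`, lower-tail p-value
#' `p = pnorm(z)` (a smaller MAE than noise is better), `significant` if
#' `z < -2`. The `relevant` flag is the across-area two-sigma rule of
#' [two_sigma_flags()]. No multiple-testing correction is applied, matching
#' the protocol's single-area hypotheses.
#'
#' @param ranking An `area_ranking_set` from [rank_areas()] (or a tibble
#'   with `roi_label` and `median_mae`).
#' @param noise A [noise_mae_distribution()] result.
#' @return A tibble: `roi_label`, `median_mae`, `z`, `p_value`, `relevant`,
#'   `significant`, ordered by `median_mae`.
#' @export
area_significance <- function(ranking, noise) {
  stopifnot(inherits(noise, "noise_distribution"))
  if (noise$sigma <= 0) stop("noise distribution has zero spread")
  tbl <- if (inherits(ranking, "area_ranking_set")) {
    ranking$summary
  } else {
    tibble::as_tibble(ranking)
  }
  z <- (tbl$median_mae - noise$mu) / noise$sigma
  tibble::tibble(
    roi_label = tbl$roi_label,
    median_mae = tbl$median_mae,
    z = z,
    p_value = stats::pnorm(z),
    relevant = two_sigma_flags(tbl$median_mae),
    significant = z < -2
  ) |> dplyr::arrange(.data$median_mae, .data$roi_label)
}
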