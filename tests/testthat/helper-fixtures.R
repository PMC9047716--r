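# Shared fixture builders for the test suite (everything generated in code).

# random ROI of up to n_max voxels in a small box, unique 0-based coords
random_roi <- function(seed, n_max = 100, box = 6, spacing = NULL) {
  set.seed(seed)
  n <- sample(3:n_max, 1)
  coords <- unique(matrix(sample(0:(box - 1), 3 * (n + 30), TRUE), ncol = 3))
  coords <- coords[seq_len(min(n, nrow(coords))), , drop = FALSE]
  storage.mode(coords) <- "integer"
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  list(
    coords = coords,
    x = round(stats::rnorm(nrow(coords), 100, 30), 2),
    spacing = spacing
  )
}

# tiny cohort for fast model-protocol tests
small_cohort <- function(n = 40, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    grade = sample(3:6, n, TRUE),
    age = stats::runif(n, 8, 12),
    sex = sample(c("M", "F"), n, TRUE),
    mf_raw = pmin(pmax(round(20 + 5 * (stats::runif(n, 8, 12)) +
      stats::rnorm(n, 0, 8)), 0), 160)
  ) |> normalize_scores(tests = "mf")
}

# feature tibble with pure-noise columns for one pseudo-ROI
noise_features <- function(cohort, p = 20, seed = 1, roi_label = 1L) {
  set.seed(seed)
  X <- matrix(stats::rnorm(nrow(cohort) * p), nrow(cohort))
  colnames(X) <- sprintf("f%03d", seq_len(p))
  dplyr::bind_cols(
    tibble::tibble(subject_id = cohort$subject_id, roi_label = roi_label),
    tibble::as_tibble(X)
  )
}
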