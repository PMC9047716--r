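#' Mean absolute error
#'
#' @param pred,actual Equal-length numeric vectors (length >= 1).
#' @return `mean(abs(pred - actual))`.
#' @export
#' @examples
#' mae(c(0, 0), c(0.2, 0.4)) # 0.3
mae <- function(pred, actual) {
  if (length(pred) == 0) stop("empty input")
  if (length(pred) != length(actual)) stop("length mismatch")
  mean(abs(pred - actual))
}

#' Relative MAE improvement over a baseline, in percent
#'
#' The reporting statistic `100 * (baseline - mae) / baseline`: how much the
#' radiomics model reduces the prediction error relative to the age-only
#' baseline.
#'
#' @param baseline Baseline MAE (> 0).
#' @param value Model MAE.
#' @return Percentage improvement.
#' @export
#' @examples
#' round(mae_improvement(0.257, 0.210)) # 18
mae_improvement <- function(baseline, value) {
  stopifnot(all(baseline > 0))
  100 * (baseline - value) / baseline
}

#' Configuration for the area-ranking protocol
#'
#' The full protocol (`profile = "paper"`) is: 20 random 80/20
#' train/test partitions of the cohort; on each partition, feature selection
#' on the training split, then 100 random-forest regressors (100 trees,
#' depth at most 5, all features considered per split) differing only by
#' seed; the partition's MAE is the mean over its 100 models' hold-out MAEs
#' and the area's MAE is the median over the 20 partitions.
#' `profile = "demo"` is a scaled-down configuration (4 partitions x 3
#' models x 25 trees) for desk-scale runs and tests; the statistical
#' structure of the protocol is unchanged.
#'
#' @param profile `"paper"` or `"demo"` preset.
#' @param n_partitions,train_fraction,models_per_partition,n_trees,max_depth
#'   Protocol sizes (see above).
#' @param threshold_r2 Selection threshold, see [decorrelate()].
#' @param mtry Features considered per split; `NULL` = all.
#' @param min_split Minimum node size to attempt a split.
#' @param selection_scope `"per-partition"` (fit selection on each training
#'   split, the default, leakage-free) or `"global"` (selection once on all
#'   rows of the area).
#' @return A list of class `ranking_config`.
#' @export
ranking_config <- function(profile = c("paper", "demo"),
                           n_partitions = NULL,
                           train_fraction = 0.8,
                           models_per_partition = NULL,
                           n_trees = NULL,
                           max_depth = 5,
                           threshold_r2 = 0.8,
                           mtry = NULL,
                           min_split = 2,
                           selection_scope = c("per-partition", "global")) {
  profile <- match.arg(profile)
  defaults <- switch(profile,
    paper = list(n_partitions = 20L, models_per_partition = 100L, n_trees = 100L),
    demo = list(n_partitions = 4L, models_per_partition = 3L, n_trees = 25L)
  )
  cfg <- list(
    profile = profile,
    n_partitions = as.integer(n_partitions %||% defaults$n_partitions),
    train_fraction = train_fraction,
    models_per_partition =
      as.integer(models_per_partition %||% defaults$models_per_partition),
    n_trees = as.integer(n_trees %||% defaults$n_trees),
    max_depth = as.integer(max_depth),
    threshold_r2 = threshold_r2,
    mtry = if (is.null(mtry)) NULL else as.integer(mtry),
    min_split = as.integer(min_split),
    selection_scope = match.arg(selection_scope)
  )
  stopifnot(
    cfg$n_partitions >= 1, cfg$models_per_partition >= 1, cfg$n_trees >= 1,
    cfg$max_depth >= 1, cfg$train_fraction > 0, cfg$train_fraction < 1
  )
  structure(cfg, class = "ranking_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic per-(partition, model) seeds from the master seed;
# kept below 2^31
.derive_seed <- function(master, partition, model = 0L) {
  (((as.double(master) %% 1e6) * 2099 + partition * 15486047 +
    model * 7919) %% 2147483629) + 1
}

# train/test row indices for partition p
.partition_rows <- function(n, config, seed, p) {
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(.derive_seed(seed, p))
  n_train <- floor(n * config$train_fraction)
  if (n - n_train < 2) stop("test split smaller than 2; adjust config")
  train <- sort(sample.int(n, n_train))
  list(train = train, test = setdiff(seq_len(n), train))
}

# fit one forest and return hold-out predictions + importances
.fit_model <- function(X_train, y_train, X_test, config, seed) {
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(seed)
  mtry <- config$mtry %||% ncol(X_train)
  cpp_rf(
    X_train, y_train, X_test, config$n_trees, config$max_depth,
    mtry, config$min_split
  )
}

#' Rank one brain area: median hold-out MAE of the radiomics model
#'
#' Runs the repeated-partition random-forest protocol (see
#' [ranking_config()]) for a single area: per partition, correlation-based
#' selection on the training split, then `models_per_partition` forests on
#' the kept features plus age, predicting the min-max normalized score of
#' `test`; the partition MAE is the model average on the hold-out split and
#' the area MAE the median over partitions. Fully reproducible from
#' `(seed, config)`.
#'
#' @param features Feature tibble for one area (one row per subject, columns
#'   `subject_id`, `roi_label`, features).
#' @param cohort Cohort tibble (provides `age` and `<test>_norm`).
#' @param test Test code (`"mf"`, `"calc"`, `"ap"`, `"qc"`).
#' @param config A [ranking_config()].
#' @param seed Master seed.
#' @return An object of class `area_ranking`: `roi_label`,
#'   `partition_mae`, `median_mae`, `importances` (models x features
#'   matrix over age + the area's feature columns; features dropped by
#'   selection score 0 in that model), `kept` (per-partition kept sets),
#'   `n_selected` (median kept-feature count), `test`, `seed`.
#' @export
rank_area <- function(features, cohort, test, config = ranking_config(),
                      seed = 1L) {
  stopifnot(inherits(config, "ranking_config"))
  roi_label <- unique(features$roi_label) %||% NA_integer_
  if (length(roi_label) != 1) stop("features must cover exactly one ROI")
  miss <- setdiff(cohort$subject_id, features$subject_id)
  if (length(miss) > 0) {
    stop(
      "feature rows missing for subjects: ",
      paste(utils::head(miss, 5), collapse = ", ")
    )
  }
  features <- features[match(cohort$subject_id, features$subject_id), ]
  ycol <- paste0(test, "_norm")
  if (is.null(cohort[[ycol]])) stop("cohort lacks column ", ycol)
  y <- cohort[[ycol]]
  n <- nrow(cohort)

  feat_cols <- setdiff(names(features), c("subject_id", "roi_label", "age"))
  X_all <- as.matrix(features[feat_cols])
  storage.mode(X_all) <- "double"
  age <- cohort$age
  all_cols <- c("age", feat_cols)

  sel_global <- if (config$selection_scope == "global") {
    decorrelate(features[feat_cols], config$threshold_r2)
  } else {
    NULL
  }

  nm <- config$n_partitions * config$models_per_partition
  importances <- matrix(0, nm, length(all_cols),
    dimnames = list(NULL, all_cols)
  )
  partition_mae <- numeric(config$n_partitions)
  kept_sets <- vector("list", config$n_partitions)
  row <- 0
  for (p in seq_len(config$n_partitions)) {
    idx <- .partition_rows(n, config, seed, p)
    sel <- sel_global %||% decorrelate(
      features[idx$train, feat_cols],
      config$threshold_r2
    )
    kept_sets[[p]] <- sel$kept
    cols <- c("age", sel$kept)
    X_train <- cbind(age = age[idx$train], X_all[idx$train, sel$kept, drop = FALSE])
    X_test <- cbind(age = age[idx$test], X_all[idx$test, sel$kept, drop = FALSE])
    m_mae <- numeric(config$models_per_partition)
    for (m in seq_len(config$models_per_partition)) {
      fit <- .fit_model(
        X_train, y[idx$train], X_test, config,
        .derive_seed(seed, p, m)
      )
      m_mae[m] <- mae(fit$pred, y[idx$test])
      row <- row + 1
      importances[row, cols] <- fit$importance
    }
    partition_mae[p] <- mean(m_mae)
  }
  structure(
    list(
      roi_label = roi_label,
      partition_mae = partition_mae,
      median_mae = stats::median(partition_mae),
      importances = importances,
      kept = kept_sets,
      n_selected = stats::median(lengths(kept_sets)),
      test = test,
      seed = seed,
      config = config
    ),
    class = "area_ranking"
  )
}

#' @export
print.area_ranking <- function(x, ...) {
  cat("<area_ranking> ROI ", x$roi_label, " (", x$test, "): median MAE ",
    signif(x$median_mae, 4), " over ", length(x$partition_mae),
    " partitions\n",
    sep = ""
  )
  invisible(x)
}

#' Age-only baseline MAE
#'
#' The identical protocol with age as the only input variable; invariant to
#' the ROI, so it is computed once per test and reused.
#'
#' @inheritParams rank_area
#' @return Median hold-out MAE of the age-only model.
#' @export
baseline_mae <- function(cohort, test, config = ranking_config(), seed = 1L) {
  feats <- tibble::tibble(
    subject_id = cohort$subject_id,
    roi_label = 0L
  )
  rank_area(feats, cohort, test, config, seed)$median_mae
}

#' Rank all brain areas of a feature table
#'
#' Applies [rank_area()] to every ROI of a feature table (same partitions
#' for every area), computes the age-only [baseline_mae()] once, and orders
#' areas from most to least predictive (ascending median MAE, ties broken by
#' ROI label).
#'
#' @param features Feature tibble covering all ROIs (rows = subject x ROI).
#' @inheritParams rank_area
#' @return An object of class `area_ranking_set` with `areas` (list of
#'   `area_ranking`), `summary` (ordered tibble), `baseline_mae`, `test`.
#'   Use [tidy()] for the summary tibble.
#' @export
rank_areas <- function(features, cohort, test, config = ranking_config(),
                       seed = 1L) {
  labs <- sort(unique(features$roi_label))
  areas <- lapply(labs, function(lb) {
    rank_area(
      dplyr::filter(features, .data$roi_label == lb),
      cohort, test, config, seed
    )
  })
  names(areas) <- labs
  base <- baseline_mae(cohort, test, config, seed)
  med <- unname(vapply(areas, function(a) a$median_mae, 1.0))
  summary <- tibble::tibble(
    roi_label = unname(vapply(areas, function(a) as.integer(a$roi_label), 1L)),
    median_mae = med,
    baseline_mae = base,
    n_selected = unname(vapply(areas, function(a) as.double(a$n_selected), 1.0)),
    improvement_pct = mae_improvement(base, med)
  )
  summary <- dplyr::arrange(summary, .data$median_mae, .data$roi_label)
  structure(
    list(
      areas = areas, summary = summary, baseline_mae = base,
      test = test, config = config, seed = seed
    ),
    class = "area_ranking_set"
  )
}

#' @export
print.area_ranking_set <- function(x, ...) {
  cat("<area_ranking_set> ", length(x$areas), " areas (", x$test,
    "), baseline MAE ", signif(x$baseline_mae, 4), "\n",
    sep = ""
  )
  print(utils::head(x$summary, 5))
  invisible(x)
}

#' @export
#' @rdname rank_areas
#' @param x An `area_ranking_set`.
#' @param ... Unused.
tidy.area_ranking_set <- function(x, ...) x$summary

#' @export
#' @rdname rank_areas
glance.area_ranking_set <- function(x, ...) {
  tibble::tibble(
    test = x$test,
    n_areas = length(x$areas),
    baseline_mae = x$baseline_mae,
    best_roi = x$summary$roi_label[1],
    best_mae = x$summary$median_mae[1],
    best_improvement_pct = x$summary$improvement_pct[1]
  )
}

#' @export
#' @rdname rank_area
#' @param x An `area_ranking`.
#' @param ... Unused.
tidy.area_ranking <- function(x, ...) {
  tibble::tibble(
    roi_label = as.integer(x$roi_label),
    partition = seq_along(x$partition_mae),
    mae = x$partition_mae
  )
}
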