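#' Feature-family importance breakdown of an area's models
#'
#' Aggregates the per-model Gini (mean decrease of impurity) importances of
#' all forests fitted for an area into relative family contributions: each
#' feature's importance is averaged over the models (features removed by
#' selection in a model count 0 there, keeping family shares comparable
#' across partitions with different kept sets), summed by family
#' (age / volume / shape / intensity / texture) and rescaled to 100%.
#' Features whose importance SD across models is an outlier (see
#' [flag_unstable()]) are flagged as high-variability.
#'
#' @param x An `area_ranking` from [rank_area()], or a models x features
#'   importance matrix with feature column names.
#' @param families Feature-to-family map, see [feature_families()].
#'   Features absent from the map cause an error.
#' @return An object of class `importance_breakdown`: `family` (tibble with
#'   `family`, `share_pct`), `feature` (tibble with per-feature mean, sd,
#'   family, flagged), `roi_label` if known.
#' @export
family_importance <- function(x, families = feature_families()) {
  roi <- NULL
  if (inherits(x, "area_ranking")) {
    roi <- x$roi_label
    x <- x$importances
  }
  stopifnot(is.matrix(x), !is.null(colnames(x)), all(x >= 0))
  unknown <- setdiff(colnames(x), families$feature)
  if (length(unknown) > 0) {
    stop("unknown feature names: ", paste(utils::head(unknown, 5),
      collapse = ", "
    ))
  }
  fam <- families$family[match(colnames(x), families$feature)]
  mean_imp <- colMeans(x)
  sd_imp <- apply(x, 2, stats::sd)
  flagged_names <- flag_unstable(stats::setNames(sd_imp, colnames(x)))
  feature <- tibble::tibble(
    feature = colnames(x),
    family = fam,
    mean_importance = mean_imp,
    sd_importance = sd_imp,
    flagged = colnames(x) %in% flagged_names
  )
  fam_sum <- tapply(mean_imp, fam, sum, default = 0)
  fam_sum[is.na(fam_sum)] <- 0
  total <- sum(fam_sum)
  share <- if (total > 0) 100 * fam_sum / total else fam_sum * 0
  family <- tibble::tibble(
    family = factor(names(share), levels = levels(families$family)),
    share_pct = as.numeric(share)
  )
  structure(
    list(family = family, feature = feature, roi_label = roi),
    class = "importance_breakdown"
  )
}

#' @export
print.importance_breakdown <- function(x, ...) {
  cat("<importance_breakdown>",
    if (!is.null(x$roi_label)) paste0(" ROI ", x$roi_label), "\n",
    sep = ""
  )
  print(x$family)
  fl <- x$feature$feature[x$feature$flagged]
  if (length(fl) > 0) {
    cat("high-variability features:", paste(fl, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
#' @rdname family_importance
#' @param ... Unused.
tidy.importance_breakdown <- function(x, ...) x$family

#' Flag features with outlying importance variability
#'
#' A feature is flagged when its importance SD across models exceeds the
#' mean of all SDs by more than two (population) standard deviations of the
#' SDs — a proxy for unstable features whose contribution depends strongly
#' on the model realization.
#'
#' @param sds Named numeric vector of per-feature importance SDs
#'   (length >= 3).
#' @return Character vector of flagged feature names.
#' @export
#' @examples
#' flag_unstable(c(a = 1, b = 1, c = 1, d = 10)) # "d"
flag_unstable <- function(sds) {
  if (length(sds) < 3) stop("need at least 3 features")
  mu <- mean(sds)
  pop_sd <- sqrt(mean((sds - mu)^2))
  names(sds)[sds > mu + 2 * pop_sd]
}
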