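#' Sequential correlation-based feature elimination
#'
#' Walks the feature columns front to back in the order given (the canonical
#' catalogue order puts shape features first, so correlated texture features
#' are removed in their favour): at step `i`, if feature `i` is still kept,
#' every later surviving feature whose squared Pearson correlation with it
#' is *strictly* greater than `threshold_r2` is dropped, recording feature
#' `i` as the cause. Zero-variance features are dropped first with cause
#' `"constant"`. Identifier columns and protected columns (age) are never
#' candidates for removal and never cause removals.
#'
#' The procedure is order-dependent by construction: permuting the columns
#' may change the kept set. It is idempotent: re-running on the kept set
#' keeps everything.
#'
#' @param features Data frame of feature columns (rows = subjects). Columns
#'   named in `ignore` or `protect` are skipped.
#' @param threshold_r2 Squared-correlation threshold (default 0.8,
#'   corresponding to |rho| ~ 0.9; the comparison is strict).
#' @param protect Columns never removed nor used as causes (default
#'   `"age"`).
#' @param ignore Identifier columns to skip (default
#'   `c("subject_id", "roi_label")`).
#' @return An object of class `selection_result`: list with `kept` (ordered
#'   names), `dropped` (named character vector, dropped -> cause),
#'   `retention` (fraction kept) and `threshold_r2`.
#' @export
#' @examples
#' set.seed(1)
#' d <- tibble::tibble(f1 = rnorm(20), f2 = NA, f3 = rnorm(20))
#' d$f2 <- 2 * d$f1
#' decorrelate(d)$dropped # f2 dropped, cause f1
decorrelate <- function(features, threshold_r2 = 0.8, protect = "age",
                        ignore = c("subject_id", "roi_label")) {
  stopifnot(threshold_r2 >= 0)
  cand <- setdiff(names(features), c(protect, ignore))
  if (nrow(features) < 3) {
    stop("need at least 3 rows to estimate correlations")
  }
  if (length(cand) == 0) {
    return(structure(
      list(
        kept = character(), dropped = stats::setNames(character(), character()),
        retention = NaN, threshold_r2 = threshold_r2
      ),
      class = "selection_result"
    ))
  }
  x <- as.matrix(features[cand])
  storage.mode(x) <- "double"

  dropped <- character()
  cause <- character()
  const <- cand[apply(x, 2, stats::var) == 0]
  if (length(const) > 0) {
    dropped <- const
    cause <- rep("constant", length(const))
  }
  kept <- setdiff(cand, const)
  i <- 1
  while (i < length(kept)) {
    f <- kept[i]
    later <- kept[(i + 1):length(kept)]
    r2 <- drop(stats::cor(x[, f], x[, later, drop = FALSE]))^2
    out <- later[r2 > threshold_r2]
    if (length(out) > 0) {
      dropped <- c(dropped, out)
      cause <- c(cause, rep(f, length(out)))
      kept <- setdiff(kept, out)
    }
    i <- i + 1
  }
  structure(
    list(
      kept = kept,
      dropped = stats::setNames(cause, dropped),
      retention = length(kept) / length(cand),
      threshold_r2 = threshold_r2
    ),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(
    "<selection_result> kept ", length(x$kept), "/",
    length(x$kept) + length(x$dropped), " features (",
    round(100 * x$retention), "%), threshold rho^2 > ", x$threshold_r2,
    "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
#' @rdname decorrelate
#' @param x A `selection_result`.
#' @param ... Unused.
tidy.selection_result <- function(x, ...) {
  tibble::tibble(
    feature = c(x$kept, names(x$dropped)),
    kept = c(rep(TRUE, length(x$kept)), rep(FALSE, length(x$dropped))),
    cause = c(rep(NA_character_, length(x$kept)), unname(x$dropped))
  )
}
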