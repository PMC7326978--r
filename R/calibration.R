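# Linear calibration of detected berry counts against destructive ground
# truth. Counts from a single 2D view systematically undercount (hidden
# berries), so the correction maps detected -> true: truth ~ a + b * detected.

#' Fit the detected-count to true-count linear correction
#'
#' Ordinary least squares of ground truth on detected count
#' (`truth = intercept + slope * detected`), with in-sample R-squared and
#' RMSE (in berries).
#'
#' @param detected Numeric vector of detected counts (x).
#' @param truth Numeric vector of true counts (y), same length.
#' @param group Group label for the fit (a cultivar name, or `"pooled"`).
#' @return A list of class `"regression_fit"`: `intercept`, `slope`,
#'   `r_squared`, `rmse`, `n`, `group`, and the underlying `lm` object.
#' @export
fit_linear <- function(detected, truth, group = "pooled") {
  if (length(detected) != length(truth)) stop("detected and truth must have equal length")
  n <- length(detected)
  if (n < 3L) stop("need at least 3 observations for a fit")
  if (stats::var(detected) == 0) stop("detected counts are all identical: slope undefined")
  fit <- stats::lm(truth ~ detected)
  res <- stats::residuals(fit)
  sst <- sum((truth - mean(truth))^2)
  r2 <- if (sst == 0) 0 else 1 - sum(res^2) / sst
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 r_squared = r2,
                 rmse = sqrt(mean(res^2)),
                 n = n, group = as.character(group), lm = fit),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("[%s] truth = %.3f + %.3f x detected  (R2 %.3f, RMSE %.3f, n %d)\n",
              x$group, x$intercept, x$slope, x$r_squared, x$rmse, x$n))
  invisible(x)
}

#' Apply a count calibration
#' @param fit A `"regression_fit"` (or any list with `intercept`, `slope`).
#' @param detected_count Detected count(s).
#' @return Calibrated count estimate(s), unrounded.
#' @export
apply_fit <- function(fit, detected_count) {
  fit$intercept + fit$slope * detected_count
}

#' Pooled and per-group count calibration table
#'
#' Fits the pooled model and one model per group (groups with fewer than
#' 3 observations are skipped with a warning).
#'
#' @param detected,truth Numeric vectors.
#' @param groups Group labels (e.g. cultivar), same length.
#' @return A list of `"regression_fit"`s, named by group, `"pooled"` first.
#' @export
calibrate_counts <- function(detected, truth, groups = NULL) {
  fits <- list(pooled = fit_linear(detected, truth, "pooled"))
  if (!is.null(groups)) {
    for (g in sort(unique(groups))) {
      sel <- groups == g
      if (sum(sel) < 3L) {
        warning("group '", g, "' has fewer than 3 observations; skipped")
        next
      }
      fits[[g]] <- fit_linear(detected[sel], truth[sel], g)
    }
  }
  fits
}

#' Write a calibration table as CSV
#' @param fits A list of `"regression_fit"`s from [calibrate_counts()].
#' @param path Output CSV path; if `NULL` the data.frame is returned.
#' @return The data.frame (invisibly when written).
#' @export
write_calibration_csv <- function(fits, path = NULL) {
  df <- do.call(rbind, lapply(fits, function(f)
    data.frame(group = f$group, intercept = f$intercept, slope = f$slope,
               r_squared = f$r_squared, rmse = f$rmse, n = f$n)))
  rownames(df) <- NULL
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    return(invisible(df))
  }
  df
}
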