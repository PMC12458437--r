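#' Paired measured and predicted microbial loads
#'
#' Container for per-sample measured and predicted loads on the log10
#' scale, the scale on which all prediction-evaluation metrics operate.
#' Linear-scale inputs are converted with `scale = "linear"` (non-positive
#' values are rejected, since their logarithm is undefined).
#'
#' @param measured,predicted Numeric vectors of equal length (>= 2).
#' @param sample_id Optional sample identifiers.
#' @param modality Optional measurement-modality tag (e.g.
#'   `"flow cytometry"`, `"qPCR"`).
#' @param scale `"log10"` (default) or `"linear"`.
#' @return Object of class `paired_loads` with elements `measured_log10`,
#'   `predicted_log10`, `sample_id`, `modality`.
#' @export
paired_loads <- function(measured, predicted, sample_id = NULL,
                         modality = NULL, scale = c("log10", "linear")) {
  scale <- match.arg(scale)
  if (!is.numeric(measured) || !is.numeric(predicted))
    stop("`measured` and `predicted` must be numeric", call. = FALSE)
  if (length(measured) != length(predicted))
    stop("`measured` and `predicted` must have equal length", call. = FALSE)
  if (length(measured) < 2L)
    stop("at least two samples are required", call. = FALSE)
  if (scale == "linear") {
    if (any(measured <= 0) || any(predicted <= 0))
      stop("linear-scale loads must be positive to take log10",
           call. = FALSE)
    measured <- log10(measured)
    predicted <- log10(predicted)
  }
  if (!all(is.finite(measured)) || !all(is.finite(predicted)))
    stop("loads must be finite", call. = FALSE)
  if (is.null(sample_id)) sample_id <- seq_along(measured)
  structure(list(measured_log10 = measured, predicted_log10 = predicted,
                 sample_id = sample_id, modality = modality),
            class = "paired_loads")
}

.as_paired <- function(pair) {
  if (!inherits(pair, "paired_loads"))
    stop("expected a paired_loads object", call. = FALSE)
  pair
}

#' Sample correlation between measured and predicted loads
#'
#' Pearson correlation of the log10 vectors. Correlation only measures
#' monotone association: it can be near 1 even when predictions span a far
#' narrower range than the measurements, which is why
#' [mean_centered_r2()] is the recommended headline metric.
#'
#' @param pair A [paired_loads()] object.
#' @return Correlation in `[-1, 1]`, or `NaN` (with a warning) when either
#'   vector has zero variance.
#' @export
sample_correlation <- function(pair) {
  pair <- .as_paired(pair)
  y <- pair$measured_log10; yhat <- pair$predicted_log10
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0) {
    warning("zero variance in measured or predicted loads; ",
            "correlation undefined", call. = FALSE)
    return(NaN)
  }
  stats::cor(y, yhat)
}

#' Mean-centered coefficient of determination
#'
#' Variance-partitioning R-squared after centering both vectors by their
#' own means: `R2 = 1 - sum((y' - yhat')^2) / sum(y'^2)`. Centering removes
#' systematic offsets between measurement modalities; unlike correlation,
#' R-squared penalizes compressed (low-variance) predictions. A predictor
#' that always returns a constant scores exactly 0; negative values mean
#' worse than predicting the mean.
#'
#' @inheritParams sample_correlation
#' @return R-squared (at most 1, possibly negative), or `NaN` with a
#'   warning when the measured vector has zero variance.
#' @examples
#' p <- paired_loads(c(1, 2, 3, 4), c(1, 2, 3, 5))
#' mean_centered_r2(p)  # 0.85
#' @export
mean_centered_r2 <- function(pair) {
  pair <- .as_paired(pair)
  yc <- pair$measured_log10 - mean(pair$measured_log10)
  pc <- pair$predicted_log10 - mean(pair$predicted_log10)
  sst <- sum(yc^2)
  if (sst == 0) {
    warning("measured loads have zero variance; R2 undefined",
            call. = FALSE)
    return(NaN)
  }
  1 - sum((yc - pc)^2) / sst
}

#' Absolute mean-centered log10 residuals
#'
#' Per-sample `|y' - yhat'|` after centering both vectors by their own
#' means, a per-sample view of prediction error that is invariant to
#' modality offsets.
#'
#' @inheritParams sample_correlation
#' @return Non-negative numeric vector, one entry per sample.
#' @export
centered_abs_residuals <- function(pair) {
  pair <- .as_paired(pair)
  yc <- pair$measured_log10 - mean(pair$measured_log10)
  pc <- pair$predicted_log10 - mean(pair$predicted_log10)
  abs(yc - pc)
}

#' Align a taxonomic profile to a model's expected feature list
#'
#' Reproduces the silent input handling of fixed-input load predictors:
#' the output contains exactly the expected features in the expected order,
#' features absent from the data are filled with zero rows, and features
#' present in the data but not expected are dropped. No renormalization is
#' performed by default, so column sums may fall below 1 after dropping —
#' exactly the behavior that drives prediction collapse under covariate
#' shift.
#'
#' @param profile Numeric matrix, features in rows (rownames required),
#'   samples in columns.
#' @param expected Character vector of unique expected feature identifiers.
#' @param renormalize Rescale each column of the aligned matrix to sum to 1
#'   (columns with zero sum are left as zeros).
#' @return List with `matrix` (aligned profile) and `report`, an
#'   `alignment_report` with fields `n_expected`, `n_shared`,
#'   `shared_fraction`, `dropped_features`, `zero_filled`.
#' @export
align_features <- function(profile, expected, renormalize = FALSE) {
  if (!is.matrix(profile) || is.null(rownames(profile)))
    stop("`profile` must be a matrix with feature rownames", call. = FALSE)
  if (!is.character(expected) || length(expected) < 1L)
    stop("`expected` must be a non-empty character vector", call. = FALSE)
  if (anyDuplicated(expected))
    stop("duplicate identifiers in `expected`", call. = FALSE)
  if (anyDuplicated(rownames(profile)))
    stop("duplicate identifiers in `profile`", call. = FALSE)
  present <- rownames(profile)
  shared <- intersect(expected, present)
  zero_filled <- setdiff(expected, present)
  dropped <- setdiff(present, expected)
  out <- matrix(0, nrow = length(expected), ncol = ncol(profile),
                dimnames = list(expected, colnames(profile)))
  out[shared, ] <- profile[shared, , drop = FALSE]
  if (renormalize) {
    cs <- colSums(out)
    nz <- cs > 0
    out[, nz] <- sweep(out[, nz, drop = FALSE], 2, cs[nz], `/`)
  }
  report <- structure(
    list(n_expected = length(expected), n_shared = length(shared),
         shared_fraction = length(shared) / length(expected),
         dropped_features = dropped, zero_filled = zero_filled),
    class = "alignment_report")
  list(matrix = out, report = report)
}

#' @export
print.alignment_report <- function(x, ...) {
  cat("alignment_report: ", x$n_shared, "/", x$n_expected,
      " expected features present (", round(100 * x$shared_fraction, 1),
      "%); ", length(x$zero_filled), " zero-filled, ",
      length(x$dropped_features), " dropped\n", sep = "")
  invisible(x)
}

#' Frequency of the most common predicted value
#'
#' Prediction-collapse diagnostic: the fraction of samples assigned the
#' single most frequent predicted value, after rounding to `decimals`
#' places to define equality of floating-point predictions. A healthy
#' predictor on continuous loads scores near `1/n`; a collapsed predictor
#' approaches 1.
#'
#' @param predictions Non-empty numeric vector.
#' @param decimals Rounding used to group values (default 6).
#' @return Fraction in `(0, 1]`.
#' @export
mode_frequency <- function(predictions, decimals = 6) {
  if (!is.numeric(predictions) || length(predictions) < 1L)
    stop("`predictions` must be a non-empty numeric vector", call. = FALSE)
  decimals <- .assert_count(decimals, "decimals", min = 0L)
  max(table(round(predictions, decimals))) / length(predictions)
}

#' Evaluate load predictions with all metrics at once
#'
#' @inheritParams sample_correlation
#' @param decimals Rounding for [mode_frequency()].
#' @return One-row `data.frame` with `n`, `r`, `r2`,
#'   `mean_abs_centered_residual`, `mode_frequency`.
#' @export
evaluate_predictions <- function(pair, decimals = 6) {
  pair <- .as_paired(pair)
  data.frame(
    n = length(pair$measured_log10),
    r = suppressWarnings(sample_correlation(pair)),
    r2 = suppressWarnings(mean_centered_r2(pair)),
    mean_abs_centered_residual = mean(centered_abs_residuals(pair)),
    mode_frequency = mode_frequency(pair$predicted_log10, decimals))
}
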