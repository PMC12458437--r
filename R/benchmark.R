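#' Load-anchored ground truth for differential abundance
#'
#' Runs the engine with an external-measurement scale model: measured log2
#' loads are treated as the mean of a normal distribution with standard
#' deviation `gamma` (default 0.5) to account for measurement uncertainty.
#' The resulting calls serve as the reference against which other methods
#' are scored.
#'
#' @inheritParams run_da
#' @param measured_log2 Per-sample measured log2 loads (one per sample).
#' @param gamma Measurement-uncertainty sd in log2 units (default 0.5).
#' @return A `da_result` with attribute `reference = TRUE`.
#' @export
ground_truth <- function(counts, measured_log2, condition = NULL,
                         n_replicates = 128, alpha = 0.05, seed = 1,
                         gamma = 0.5, prior_mass = 0.5) {
  res <- run_da(counts, condition = condition,
                scale_model = scale_model("external", gamma = gamma,
                                          measured_log2 = measured_log2),
                n_replicates = n_replicates, alpha = alpha,
                prior_mass = prior_mass, seed = seed)
  attr(res, "reference") <- TRUE
  res
}

#' Score a differential-abundance result against a reference
#'
#' Per taxon: a true positive requires both calls significant with the same
#' (nonzero) direction; a method call that is significant while the
#' reference is not, or that disagrees in direction, is a false positive;
#' a reference positive the method misses is a false negative; and taxa
#' called by neither are true negatives. Counts always partition the taxon
#' set. PPV, NPV and FDR follow, `NaN` when a denominator is zero.
#'
#' @param method,truth `da_result` objects (or data.frames with columns
#'   `taxon`, `significant`, `direction`) over the same taxon set.
#' @return Object of class `confusion_counts`: list with `tp`, `fp`, `tn`,
#'   `fn`, `ppv`, `npv`, `fdr`, `n_taxa`.
#' @examples
#' ds <- generate_paired_dataset(sim_config(n_taxa = 15, n_per_group = 5))
#' truth <- ground_truth(ds$counts, ds$measured_loads_log2,
#'                       n_replicates = 8, seed = 1)
#' score_against_truth(truth, truth)  # perfect self-agreement
#' @export
score_against_truth <- function(method, truth) {
  for (nm in c("taxon", "significant", "direction")) {
    if (!nm %in% names(method) || !nm %in% names(truth))
      stop("both results need columns taxon/significant/direction",
           call. = FALSE)
  }
  extra <- setdiff(method$taxon, truth$taxon)
  missing <- setdiff(truth$taxon, method$taxon)
  if (length(extra) || length(missing))
    stop("taxon sets differ; only in method: [",
         paste(extra, collapse = ", "), "]; only in truth: [",
         paste(missing, collapse = ", "), "]", call. = FALSE)
  m <- method[match(truth$taxon, method$taxon), ]
  same_dir <- m$direction == truth$direction &
    m$direction != "0" & truth$direction != "0"
  tp <- sum(m$significant & truth$significant & same_dir)
  fp <- sum(m$significant & !(truth$significant & same_dir))
  fn <- sum(!m$significant & truth$significant)
  tn <- sum(!m$significant & !truth$significant)
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         ppv = if (tp + fp > 0) tp / (tp + fp) else NaN,
         npv = if (tn + fn > 0) tn / (tn + fn) else NaN,
         fdr = if (tp + fp > 0) fp / (tp + fp) else NaN,
         n_taxa = nrow(truth)),
    class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("confusion_counts: tp=", x$tp, " fp=", x$fp, " tn=", x$tn,
      " fn=", x$fn, " | ppv=", signif(x$ppv, 3), " npv=", signif(x$npv, 3),
      " fdr=", signif(x$fdr, 3), "\n", sep = "")
  invisible(x)
}

#' Benchmark scale models against load-anchored ground truth
#'
#' For each dataset, builds the external-measurement reference once, runs
#' every configured method, scores it, and reports per-dataset confusion
#' metrics plus across-dataset medians (computed over defined values only,
#' with the number of undefined values reported alongside).
#'
#' @param datasets List of `synthetic_dataset` objects, or lists with
#'   elements `counts` (a [count_table()]) and `measured_log2`.
#' @param methods Named list of [scale_model()] configurations. External
#'   and predicted configurations with `NULL` load vectors are completed
#'   with each dataset's measured loads.
#' @param n_replicates,alpha,prior_mass Passed to [run_da()].
#' @param seed Master seed; truth and method seeds are derived from it.
#'   Truth seeds are independent of method seeds unless
#'   `share_seed = TRUE` (useful to verify that an oracle method reproduces
#'   the reference exactly).
#' @param truth_gamma Measurement-uncertainty sd for the reference runs.
#' @param share_seed Use the truth seed for the method runs as well.
#' @return Object of class `benchmark_report`: list with `per_dataset`
#'   (data.frame of counts and metrics per dataset x method), `medians`
#'   (data.frame per method: median fdr/ppv/npv over defined values and
#'   `n_undefined_*` counts), and `params`.
#' @export
run_benchmark <- function(datasets, methods, n_replicates = 128,
                          alpha = 0.05, seed = 1, truth_gamma = 0.5,
                          prior_mass = 0.5, share_seed = FALSE) {
  if (!is.list(datasets) || length(datasets) < 1L)
    stop("`datasets` must be a non-empty list", call. = FALSE)
  if (!is.list(methods) || length(methods) < 1L)
    stop("`methods` must be a non-empty list", call. = FALSE)
  if (is.null(names(methods)) || any(names(methods) == ""))
    names(methods) <- paste0("method_", seq_along(methods))
  seed <- .assert_count(seed, "seed", min = -.Machine$integer.max)

  rows <- list()
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    counts <- if (inherits(d, "synthetic_dataset")) d$counts else d$counts
    measured <- if (inherits(d, "synthetic_dataset"))
      d$measured_loads_log2 else d$measured_log2
    ds_name <- if (!is.null(names(datasets)) && names(datasets)[i] != "")
      names(datasets)[i] else paste0("dataset_", i)
    truth_seed <- seed + 19000L + i
    truth <- tryCatch(
      ground_truth(counts, measured, n_replicates = n_replicates,
                   alpha = alpha, seed = truth_seed, gamma = truth_gamma,
                   prior_mass = prior_mass),
      error = function(e) e)
    if (inherits(truth, "error")) {
      message("benchmark: skipping ", ds_name, " (", conditionMessage(truth),
              ")")
      next
    }
    for (j in seq_along(methods)) {
      cfg <- methods[[j]]
      if (inherits(cfg, "scale_model_config")) {
        if (cfg$name == "external" && is.null(cfg$measured_log2))
          cfg$measured_log2 <- measured
        if (cfg$name == "predicted" && is.null(cfg$predicted_log2))
          cfg$predicted_log2 <- measured
      } else if (is.function(cfg)) {
        cfg <- cfg(d)
      } else stop("methods must be scale_model configurations or functions",
                  call. = FALSE)
      method_seed <- if (share_seed) truth_seed else seed + 100L * i + j
      fit <- tryCatch(
        run_da(counts, scale_model = cfg, n_replicates = n_replicates,
               alpha = alpha, prior_mass = prior_mass, seed = method_seed),
        error = function(e) e)
      if (inherits(fit, "error")) {
        message("benchmark: method ", names(methods)[j], " failed on ",
                ds_name, " (", conditionMessage(fit), ")")
        next
      }
      cc <- score_against_truth(fit, truth)
      rows[[length(rows) + 1L]] <- data.frame(
        dataset = ds_name, method = names(methods)[j],
        tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn,
        ppv = cc$ppv, npv = cc$npv, fdr = cc$fdr,
        stringsAsFactors = FALSE)
    }
  }
  per_dataset <- do.call(rbind, rows)
  if (is.null(per_dataset))
    stop("no benchmark results were produced", call. = FALSE)

  med_def <- function(x) if (any(is.finite(x))) median(x[is.finite(x)])
                         else NaN
  medians <- do.call(rbind, lapply(split(per_dataset, per_dataset$method),
    function(g) data.frame(
      method = g$method[1],
      median_fdr = med_def(g$fdr), n_undefined_fdr = sum(!is.finite(g$fdr)),
      median_ppv = med_def(g$ppv), n_undefined_ppv = sum(!is.finite(g$ppv)),
      median_npv = med_def(g$npv), n_undefined_npv = sum(!is.finite(g$npv)),
      n_datasets = nrow(g), stringsAsFactors = FALSE)))
  rownames(medians) <- NULL
  structure(
    list(per_dataset = per_dataset, medians = medians,
         params = list(n_replicates = n_replicates, alpha = alpha,
                       seed = seed, truth_gamma = truth_gamma,
                       prior_mass = prior_mass, share_seed = share_seed)),
    class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("benchmark_report over", length(unique(x$per_dataset$dataset)),
      "dataset(s) x", length(unique(x$per_dataset$method)), "method(s)\n")
  print(x$medians)
  invisible(x)
}
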