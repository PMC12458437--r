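#' Scale models: samplers for per-sample log2 total microbial load
#'
#' A scale model supplies, for each Monte Carlo replicate, a vector of log2
#' total loads for the samples. Combined with composition replicates it
#' turns relative information into (uncertain) absolute abundances. Four
#' variants are provided:
#'
#' * [tss_scale()] with `gamma = 0` — total-sum scaling: every sample is
#'   assigned log2 load 0, i.e. the assumption that total load does not
#'   differ between conditions.
#' * [tss_scale()] with `gamma > 0` — the Bayesian partially-identified
#'   scale prior generalizing TSS: each replicate draws one between-group
#'   shift `theta_perp ~ Normal(0, gamma^2)` shared by all condition-1
#'   samples. With the default `gamma = 1` (log2 units) the implied fold
#'   change between conditions lies within a factor of about 0.26–3.89 with
#'   95% probability.
#' * [external_scale()] — loads measured externally (flow cytometry, qPCR,
#'   ddPCR): per sample and replicate, `Normal(measured_log2, gamma^2)`.
#' * [predicted_scale()] — fixed model-predicted loads used as-is, with zero
#'   scale uncertainty (every replicate carries the identical vector).
#'
#' @name scale_models
#' @return Each sampler returns an object of class `scale_sample`: list with
#'   `log2_scale` (N x S matrix of log2 loads), `model_name`, `gamma`, and
#'   `condition` (when applicable).
NULL

.new_scale_sample <- function(log2_scale, model_name, gamma, condition) {
  stopifnot(all(is.finite(log2_scale)))
  structure(list(log2_scale = log2_scale, model_name = model_name,
                 gamma = gamma, condition = condition),
            class = "scale_sample")
}

#' @export
print.scale_sample <- function(x, ...) {
  cat("scale_sample [", x$model_name, "]: ", nrow(x$log2_scale),
      " samples x ", ncol(x$log2_scale), " replicates\n", sep = "")
  invisible(x)
}

#' @rdname scale_models
#' @param condition Binary 0/1 vector, one entry per sample.
#' @param n_replicates Number of replicates S.
#' @param gamma Scale-uncertainty standard deviation in log2 units
#'   (`gamma >= 0`). `gamma = 0` reduces [tss_scale()] to classic TSS and
#'   [external_scale()] to the measurements themselves.
#' @param seed Integer seed (draws are deterministic given the seed).
#' @export
tss_scale <- function(condition, n_replicates = 128, gamma = 1, seed = 1) {
  condition <- .assert_condition(condition)
  n_replicates <- .assert_count(n_replicates, "n_replicates")
  .assert_scalar_number(gamma, "gamma", min = 0)
  seed <- .assert_count(seed, "seed", min = -.Machine$integer.max)
  theta_perp <- withr::with_seed(seed, rnorm(n_replicates, 0, gamma))
  log2_scale <- outer(as.numeric(condition), theta_perp)  # N x S
  rownames(log2_scale) <- names(condition)
  .new_scale_sample(log2_scale,
                    model_name = if (gamma == 0) "tss" else "pim",
                    gamma = gamma, condition = condition)
}

#' @rdname scale_models
#' @param measured_log2 Per-sample measured log2 loads (named or positional;
#'   no missing values).
#' @export
external_scale <- function(measured_log2, n_replicates = 128, gamma = 0.5,
                           seed = 1) {
  n_replicates <- .assert_count(n_replicates, "n_replicates")
  .assert_scalar_number(gamma, "gamma", min = 0)
  seed <- .assert_count(seed, "seed", min = -.Machine$integer.max)
  if (!is.numeric(measured_log2) || length(measured_log2) < 1L)
    stop("`measured_log2` must be a numeric vector", call. = FALSE)
  bad <- !is.finite(measured_log2)
  if (any(bad)) {
    who <- if (is.null(names(measured_log2))) which(bad)
           else names(measured_log2)[bad]
    stop("missing load measurement for sample(s): ",
         paste(who, collapse = ", "), call. = FALSE)
  }
  N <- length(measured_log2)
  log2_scale <- withr::with_seed(
    seed, matrix(rnorm(N * n_replicates, mean = measured_log2, sd = gamma),
                 nrow = N, ncol = n_replicates))
  rownames(log2_scale) <- names(measured_log2)
  .new_scale_sample(log2_scale, "external", gamma, condition = NULL)
}

#' @rdname scale_models
#' @param predicted_log2 Per-sample predicted log2 loads, used as fixed
#'   values: replicate-to-replicate variance is exactly zero, mirroring the
#'   use of machine-learning load predictions that carry no error model.
#' @export
predicted_scale <- function(predicted_log2, n_replicates = 128) {
  n_replicates <- .assert_count(n_replicates, "n_replicates")
  if (!is.numeric(predicted_log2) || length(predicted_log2) < 1L)
    stop("`predicted_log2` must be a numeric vector", call. = FALSE)
  bad <- !is.finite(predicted_log2)
  if (any(bad)) {
    who <- if (is.null(names(predicted_log2))) which(bad)
           else names(predicted_log2)[bad]
    stop("missing load prediction for sample(s): ",
         paste(who, collapse = ", "), call. = FALSE)
  }
  log2_scale <- matrix(predicted_log2, nrow = length(predicted_log2),
                       ncol = n_replicates)
  rownames(log2_scale) <- names(predicted_log2)
  .new_scale_sample(log2_scale, "predicted", gamma = 0, condition = NULL)
}

#' Configure a scale model by name
#'
#' Builds a reusable scale-model configuration for [run_da()],
#' [ground_truth()] and [run_benchmark()]. Names follow the engine's
#' conventions: `"tss"` (gamma defaults to 0), `"pim"` (the Bayesian scale
#' prior, gamma defaults to 1), `"external"` (needs `measured_log2`, gamma
#' defaults to 0.5) and `"predicted"` (needs `predicted_log2`).
#' `measured_log2`/`predicted_log2` may be left `NULL` when the model is
#' used through [run_benchmark()], which fills them from each dataset's
#' measured loads.
#'
#' @param name One of `"tss"`, `"pim"`, `"external"`, `"predicted"`.
#' @param gamma Scale sd in log2 units; `NULL` picks the per-model default.
#' @param measured_log2,predicted_log2 Per-sample load vectors for the
#'   external/predicted models.
#' @return An object of class `scale_model_config`.
#' @export
scale_model <- function(name = c("tss", "pim", "external", "predicted"),
                        gamma = NULL, measured_log2 = NULL,
                        predicted_log2 = NULL) {
  name <- match.arg(name)
  if (is.null(gamma))
    gamma <- switch(name, tss = 0, pim = 1, external = 0.5, predicted = 0)
  .assert_scalar_number(gamma, "gamma", min = 0)
  structure(list(name = name, gamma = gamma, measured_log2 = measured_log2,
                 predicted_log2 = predicted_log2),
            class = "scale_model_config")
}

#' @export
print.scale_model_config <- function(x, ...) {
  cat("scale_model: ", x$name, " (gamma = ", x$gamma, ")\n", sep = "")
  invisible(x)
}

# Draw a scale_sample from a configuration for a given design.
.draw_scale <- function(model, condition, n_replicates, seed) {
  stopifnot(inherits(model, "scale_model_config"))
  switch(model$name,
    tss = ,
    pim = tss_scale(condition, n_replicates, gamma = model$gamma,
                    seed = seed),
    external = {
      if (is.null(model$measured_log2))
        stop("external scale model requires `measured_log2`", call. = FALSE)
      external_scale(model$measured_log2, n_replicates,
                     gamma = model$gamma, seed = seed)
    },
    predicted = {
      if (is.null(model$predicted_log2))
        stop("predicted scale model requires `predicted_log2`",
             call. = FALSE)
      predicted_scale(model$predicted_log2, n_replicates)
    })
}
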