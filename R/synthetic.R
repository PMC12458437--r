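#' Simulation configuration for paired counts and microbial loads
#'
#' Collects all parameters of the synthetic generator. The generator draws
#' per-taxon baseline (natural-log) abundances, places log2 effects of
#' magnitude `effect_log2` on a random subset of taxa, multiplies
#' condition-1 totals by `2^scale_shift_log2`, and observes the community
#' through multinomial sequencing at a log-normal depth that is independent
#' of the total load. External load measurements are the true log2 totals
#' plus Gaussian error with sd `load_meas_sd_log2` (default 0.5, matching
#' the uncertainty attached to real flow-cytometry/qPCR measurements in the
#' load-anchored ground truth).
#'
#' @param n_taxa Number of taxa D (>= 2).
#' @param n_per_group Samples per condition N (>= 2).
#' @param frac_diff Fraction of taxa in `[0, 1]` given a nonzero absolute
#'   effect.
#' @param effect_log2 Magnitude of the per-taxon absolute log2 fold change;
#'   each affected taxon gets sign + or - with probability 1/2.
#' @param scale_shift_log2 Log2 shift added to condition-1 total loads (the
#'   true scale component of the fold change).
#' @param depth_mean Mean sequencing depth (log-normal median).
#' @param depth_dispersion Log-normal sd of sequencing depth (natural log).
#' @param baseline_sd_log Between-taxon sd of baseline log abundance
#'   (natural log).
#' @param sample_sd_log Per-sample, per-taxon biological noise sd (natural
#'   log).
#' @param load_meas_sd_log2 Sd of the measurement error added to true log2
#'   loads.
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the configuration.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 100, n_per_group = 25, frac_diff = 0.1,
                       effect_log2 = 1, scale_shift_log2 = 0,
                       depth_mean = 10000, depth_dispersion = 0.3,
                       baseline_sd_log = 1, sample_sd_log = 0.5,
                       load_meas_sd_log2 = 0.5, seed = 1) {
  n_taxa <- .assert_count(n_taxa, "n_taxa", min = 2L)
  n_per_group <- .assert_count(n_per_group, "n_per_group", min = 2L)
  .assert_scalar_number(frac_diff, "frac_diff", 0, 1)
  .assert_scalar_number(effect_log2, "effect_log2")
  .assert_scalar_number(scale_shift_log2, "scale_shift_log2")
  depth_mean <- .assert_count(depth_mean, "depth_mean", min = 1L)
  .assert_scalar_number(depth_dispersion, "depth_dispersion", min = 0)
  .assert_scalar_number(baseline_sd_log, "baseline_sd_log", min = 0)
  if (baseline_sd_log <= 0)
    stop("`baseline_sd_log` must be positive", call. = FALSE)
  .assert_scalar_number(sample_sd_log, "sample_sd_log", min = 0)
  .assert_scalar_number(load_meas_sd_log2, "load_meas_sd_log2", min = 0)
  seed <- .assert_count(seed, "seed", min = -.Machine$integer.max)
  structure(
    list(n_taxa = n_taxa, n_per_group = n_per_group, frac_diff = frac_diff,
         effect_log2 = effect_log2, scale_shift_log2 = scale_shift_log2,
         depth_mean = depth_mean, depth_dispersion = depth_dispersion,
         baseline_sd_log = baseline_sd_log, sample_sd_log = sample_sd_log,
         load_meas_sd_log2 = load_meas_sd_log2, seed = seed),
    class = "sim_config")
}

#' Generate a paired synthetic dataset of counts and microbial loads
#'
#' Produces a two-condition taxa-by-sample count table together with the
#' true per-sample total loads, noisy external measurements of those loads,
#' and the per-taxon truth (absolute log2 effects and up/down/null flags).
#' By construction the composition-times-scale factorization holds exactly
#' for the latent abundances, so the dataset carries unambiguous
#' load-anchored ground truth.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `synthetic_dataset` with elements:
#'   \describe{
#'     \item{counts}{[count_table()] of observed sequence counts.}
#'     \item{true_loads_log2, measured_loads_log2}{Per-sample log2 totals,
#'       true and externally measured.}
#'     \item{true_effects_log2}{Per-taxon absolute log2 effect (0 for null
#'       taxa; excludes the shared scale shift).}
#'     \item{truth_flags}{Per-taxon `"up"`, `"down"` or `"null"`.}
#'     \item{true_abundance}{Latent D x N absolute-abundance matrix (linear
#'       scale), kept so the factorization can be checked.}
#'     \item{config}{The generating configuration.}
#'   }
#' @examples
#' ds <- generate_paired_dataset(sim_config(n_taxa = 20, n_per_group = 5))
#' table(ds$truth_flags)
#' @export
generate_paired_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  D <- cfg$n_taxa
  N <- 2L * cfg$n_per_group
  condition <- rep(c(0L, 1L), each = cfg$n_per_group)

  withr::with_seed(cfg$seed, {
    mu <- rnorm(D, 0, cfg$baseline_sd_log)
    n_diff <- floor(cfg$frac_diff * D)
    effects_log2 <- numeric(D)
    if (n_diff > 0) {
      idx <- sample.int(D, n_diff)
      signs <- sample(c(-1, 1), n_diff, replace = TRUE)
      effects_log2[idx] <- signs * cfg$effect_log2
    }
    # latent absolute abundances on the natural-log scale
    log_abs <- mu +
      outer(effects_log2 * log(2), condition) +
      matrix(rnorm(D * N, 0, cfg$sample_sd_log), D, N)
    abundance <- exp(log_abs)
    # explicit scale shift: condition-1 totals multiplied by 2^shift,
    # leaving composition untouched
    shift_fac <- 2^(cfg$scale_shift_log2 * condition)
    abundance <- sweep(abundance, 2, shift_fac, `*`)
    totals <- colSums(abundance)
    depth <- pmax(1, round(rlnorm(N, log(cfg$depth_mean),
                                  cfg$depth_dispersion)))
    counts <- matrix(0L, D, N)
    for (n in seq_len(N))
      counts[, n] <- rmultinom(1, depth[n], abundance[, n] / totals[n])
    true_loads_log2 <- log2(totals)
    measured_loads_log2 <- true_loads_log2 +
      rnorm(N, 0, cfg$load_meas_sd_log2)
  })

  rownames(counts) <- sprintf("taxon_%04d", seq_len(D))
  colnames(counts) <- sprintf("sample_%04d", seq_len(N))
  dimnames(abundance) <- dimnames(counts)
  names(true_loads_log2) <- names(measured_loads_log2) <- colnames(counts)
  names(effects_log2) <- rownames(counts)
  flags <- ifelse(effects_log2 > 0, "up",
                  ifelse(effects_log2 < 0, "down", "null"))

  structure(
    list(counts = count_table(counts, condition),
         true_loads_log2 = true_loads_log2,
         measured_loads_log2 = measured_loads_log2,
         true_effects_log2 = effects_log2,
         truth_flags = flags,
         true_abundance = abundance,
         config = cfg),
    class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset: ", length(x$counts$taxa), " taxa x ",
      length(x$counts$samples), " samples; ",
      sum(x$truth_flags != "null"), " non-null taxa; scale shift ",
      x$config$scale_shift_log2, " log2\n", sep = "")
  invisible(x)
}

#' Generate a cross-study taxon-overlap scenario
#'
#' Emulates the limited taxonomic overlap observed between microbiome
#' studies: a "training" taxon set and a fresh test dataset whose taxa share
#' a requested fraction `rho` of identifiers with it. The remaining test
#' taxa carry novel identifiers never seen in training, the situation that
#' forces zero-filling when a fixed-input model is applied across studies.
#'
#' @param cfg A [sim_config()] describing both the training taxon set size
#'   and the test dataset.
#' @param rho Overlap fraction in `[0, 1]`; the test taxon set shares
#'   exactly `round(rho * n_taxa)` identifiers with the training set.
#' @return An object of class `overlap_scenario`: list with `train_taxa`
#'   (character), `test_dataset` ([generate_paired_dataset()] output whose
#'   taxa have been relabeled), and `rho`.
#' @export
generate_overlap_scenario <- function(cfg, rho) {
  stopifnot(inherits(cfg, "sim_config"))
  .assert_scalar_number(rho, "rho", 0, 1)
  D <- cfg$n_taxa
  train_taxa <- sprintf("taxon_%04d", seq_len(D))
  cfg_test <- cfg
  cfg_test$seed <- cfg$seed + 1L
  test <- generate_paired_dataset(cfg_test)
  n_shared <- round(rho * D)
  shared <- withr::with_seed(cfg$seed + 2L,
                             sample(train_taxa, n_shared))
  new_ids <- c(shared,
               sprintf("novel_%04d", seq_len(D - n_shared)))
  rownames(test$counts$counts) <- new_ids
  test$counts$taxa <- new_ids
  rownames(test$true_abundance) <- new_ids
  names(test$true_effects_log2) <- new_ids
  names(test$truth_flags) <- new_ids
  structure(list(train_taxa = train_taxa, test_dataset = test, rho = rho),
            class = "overlap_scenario")
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes `counts.tsv` (taxa x samples), `metadata.tsv` (sample_id,
#' condition), `loads.tsv` (sample_id, log2_true, log2_measured) and
#' `truth.tsv` (taxon, true_effect_log2, truth_flag) under `dir`.
#'
#' @param ds A `synthetic_dataset`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_synthetic_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             loads = file.path(dir, "loads.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_count_table(ds$counts, paths[["counts"]])
  write_metadata(ds$counts, paths[["metadata"]])
  loads <- data.frame(sample_id = ds$counts$samples,
                      log2_true = ds$true_loads_log2,
                      log2_measured = ds$measured_loads_log2)
  write.table(loads, paths[["loads"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- data.frame(taxon = ds$counts$taxa,
                      true_effect_log2 = ds$true_effects_log2,
                      truth_flag = ds$truth_flags)
  write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
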