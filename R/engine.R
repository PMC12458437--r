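#' Combine composition and scale replicates into log2 absolute abundances
#'
#' Applies the factorization "absolute abundance = composition x total load"
#' on the log2 scale: `log2 W[d, n, s] = log2 Wpar[d, n, s] +
#' log2 Wperp[n, s]`.
#'
#' @param comp A `composition_replicates` object (or D x N x S array of
#'   proportions).
#' @param scale A `scale_sample` object (or N x S matrix of log2 loads).
#' @return A D x N x S array of log2 absolute abundances.
#' @export
absolute_replicates <- function(comp, scale) {
  v <- .as_composition_array(comp)
  sc <- if (inherits(scale, "scale_sample")) scale$log2_scale else scale
  if (!is.matrix(sc)) stop("`scale` must be a scale_sample or a matrix",
                           call. = FALSE)
  d <- dim(v)
  if (nrow(sc) != d[2] || ncol(sc) != d[3])
    stop("shape mismatch: compositions are ", d[1], " x ", d[2], " x ",
         d[3], " but scale is ", nrow(sc), " x ", ncol(sc), call. = FALSE)
  log2(v) + aperm(array(sc, dim = c(d[2], d[3], d[1])), c(3, 1, 2))
}

#' Per-replicate log2 fold changes and their decomposition
#'
#' For every replicate s, computes the absolute log2 fold change of each
#' taxon between conditions, together with its compositional and scale
#' parts:
#' `theta[d, s] = theta_par[d, s] + theta_perp[s]`, where each term is a
#' difference of within-group means of (respectively) log2 absolute
#' abundance, log2 composition, and log2 scale. The identity holds exactly
#' by construction; see the worked cancellation example below.
#'
#' @inheritParams absolute_replicates
#' @param condition Binary 0/1 vector over samples (both groups non-empty).
#' @return List with `theta` (D x S), `theta_par` (D x S) and `theta_perp`
#'   (length S).
#' @examples
#' # a taxon whose relative abundance doubles while total load halves
#' comp <- array(c(2 / 3, 1 / 3, 1 / 3, 2 / 3), c(2, 2, 1))
#' scl <- matrix(c(-1, 0), 2, 1)            # condition 1 first here
#' est <- estimate_theta(comp, scl, condition = c(1, 0))
#' est$theta[1, 1]  # theta_par = 1, theta_perp = -1, net change 0
#' @export
estimate_theta <- function(comp, scale, condition) {
  v <- .as_composition_array(comp)
  sc <- if (inherits(scale, "scale_sample")) scale$log2_scale else scale
  D <- dim(v)[1]; N <- dim(v)[2]; S <- dim(v)[3]
  condition <- .assert_condition(condition, N)
  idx1 <- which(condition == 1L); idx0 <- which(condition == 0L)
  if (length(idx1) == 0L || length(idx0) == 0L)
    stop("both conditions must contain at least one sample", call. = FALSE)
  if (nrow(sc) != N || ncol(sc) != S)
    stop("shape mismatch between composition and scale replicates",
         call. = FALSE)
  lv <- log2(v)
  theta_par <- matrix(0, D, S)
  for (s in seq_len(S)) {
    m <- lv[, , s, drop = FALSE]
    dim(m) <- c(D, N)
    theta_par[, s] <- rowMeans(m[, idx1, drop = FALSE]) -
      rowMeans(m[, idx0, drop = FALSE])
  }
  theta_perp <- colMeans(sc[idx1, , drop = FALSE]) -
    colMeans(sc[idx0, , drop = FALSE])
  theta <- theta_par + rep(theta_perp, each = D)
  rownames(theta) <- rownames(theta_par) <- dimnames(v)[[1]]
  list(theta = theta, theta_par = theta_par, theta_perp = theta_perp)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Rank-sum test with mid-ranks for ties. In `"exact"` mode the null
#' distribution of the rank sum is enumerated over all assignments of the
#' observed (mid-)ranks to the first group; in `"normal"` mode the
#' tie-corrected normal approximation is used without continuity
#' correction. `"auto"` picks exact when the combined sample size is at
#' most 16. When every value in both groups is identical there is no
#' evidence of separation and p = 1.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return Two-sided p-value in (0, 1].
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4), mode = "exact")  # 1/3
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (length(x) < 1L || length(y) < 1L)
    stop("both groups must be non-empty", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  nx <- length(x); ny <- length(y); n <- nx + ny
  if (mode == "auto") mode <- if (n <= 16L) "exact" else "normal"
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  if (mode == "exact") {
    sums <- colSums(matrix(r[combn(n, nx)], nrow = nx))
    mean(abs(sums - mu) >= abs(W - mu) - 1e-9)
  } else {
    ties <- table(r)
    sigma2 <- nx * ny / 12 *
      ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    min(1, 2 * pnorm(-abs(W - mu) / sqrt(sigma2)))
  }
}

# Vectorized normal-mode rank-sum over the rows of a D x N matrix.
.wilcoxon_rows <- function(mat, idx1, idx0, mode = "auto") {
  n1 <- length(idx1); n0 <- length(idx0); n <- n1 + n0
  if (mode == "auto") mode <- if (n <= 16L) "exact" else "normal"
  if (mode == "exact") {
    return(apply(mat, 1, function(row)
      wilcoxon_rank_sum(row[idx1], row[idx0], mode = "exact")))
  }
  p <- numeric(nrow(mat))
  mu <- n1 * (n + 1) / 2
  base_s2 <- n1 * n0 / 12
  for (d in seq_len(nrow(mat))) {
    row <- mat[d, c(idx1, idx0)]
    r <- rank(row)
    W <- sum(r[seq_len(n1)])
    if (anyDuplicated(r)) {
      ties <- table(r)
      s2 <- base_s2 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    } else s2 <- base_s2 * (n + 1)
    p[d] <- if (s2 <= 0) 1 else min(1, 2 * pnorm(-abs(W - mu) / sqrt(s2)))
  }
  p
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper around `stats::p.adjust(method = "BH")`,
#' preserving the input order and erroring on p-values outside `[0, 1]`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
benjamini_hochberg <- function(p) {
  if (!is.numeric(p) || length(p) < 1L)
    stop("`p` must be a non-empty numeric vector", call. = FALSE)
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Scale-aware Monte Carlo differential abundance
#'
#' The core engine. For each of S Monte Carlo replicates it draws a
#' composition for every sample from the Dirichlet measurement model, a
#' log2 total load from the chosen scale model, forms log2 absolute
#' abundances, runs a per-taxon Wilcoxon rank-sum test between conditions
#' and adjusts within the replicate by Benjamini-Hochberg. Reported
#' quantities are averages over replicates, so both compositional and scale
#' uncertainty propagate into the final calls.
#'
#' @param counts A [count_table()] (or matrix with `condition` supplied).
#' @param condition Binary 0/1 vector; taken from `counts` when `NULL`.
#' @param scale_model A [scale_model()] configuration.
#' @param n_replicates Number of Monte Carlo replicates S.
#' @param alpha Significance level applied to the averaged adjusted
#'   p-values.
#' @param prior_mass Dirichlet prior mass per cell (see
#'   [draw_compositions()]).
#' @param seed Integer seed; composition and scale streams are derived from
#'   it deterministically.
#' @param p_average `"adjusted"` (default) averages within-replicate
#'   BH-adjusted p-values; `"raw"` averages raw p-values and adjusts once.
#' @param test_mode Passed to the rank-sum test (`"auto"` switches to exact
#'   enumeration when the combined group size is at most 16).
#' @param keep_replicates Keep per-replicate p-value and theta matrices in
#'   the result (for diagnostics).
#' @return A `da_result`: a `data.frame` with one row per taxon and columns
#'   `taxon`, `theta` (mean absolute log2 fold change), `theta_par`
#'   (compositional part), `theta_perp` (scale part, shared across taxa),
#'   `p_adj` (mean adjusted p), `significant` (`p_adj < alpha`), and
#'   `direction` (`"+"`, `"-"` or `"0"`). Run metadata is stored in
#'   attributes `n_replicates`, `scale_model`, `alpha`, `seed`.
#' @examples
#' ds <- generate_paired_dataset(sim_config(n_taxa = 10, n_per_group = 5))
#' fit <- run_da(ds$counts, scale_model = scale_model("pim"),
#'               n_replicates = 16, seed = 1)
#' head(fit)
#' @export
run_da <- function(counts, condition = NULL, scale_model,
                   n_replicates = 128, alpha = 0.05, prior_mass = 0.5,
                   seed = 1, p_average = c("adjusted", "raw"),
                   test_mode = "auto", keep_replicates = FALSE) {
  p_average <- match.arg(p_average)
  .assert_scalar_number(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1)
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  seed <- .assert_count(seed, "seed", min = -.Machine$integer.max)
  y <- .as_count_matrix(counts)
  if (nrow(y) < 2L)
    stop("at least two taxa are required (composition undefined)",
         call. = FALSE)
  condition <- .resolve_condition(counts, condition)
  idx1 <- which(condition == 1L); idx0 <- which(condition == 0L)
  if (length(idx1) == 0L || length(idx0) == 0L)
    stop("both conditions must contain at least one sample", call. = FALSE)

  comp <- draw_compositions(y, n_replicates, prior_mass, seed = seed)
  scl <- .draw_scale(scale_model, condition, n_replicates,
                     seed = seed + 1L)
  if (nrow(scl$log2_scale) != ncol(y))
    stop("scale model produced ", nrow(scl$log2_scale),
         " samples but counts have ", ncol(y), call. = FALSE)

  est <- estimate_theta(comp, scl, condition)
  log2_abs <- absolute_replicates(comp, scl)
  D <- nrow(y); S <- n_replicates
  p_raw <- matrix(1, D, S)
  for (s in seq_len(S))
    p_raw[, s] <- .wilcoxon_rows(log2_abs[, , s], idx1, idx0,
                                 mode = test_mode)
  if (p_average == "adjusted") {
    p_adj_mat <- apply(p_raw, 2, benjamini_hochberg)
    if (is.null(dim(p_adj_mat))) p_adj_mat <- matrix(p_adj_mat, nrow = D)
    p_adj <- rowMeans(p_adj_mat)
  } else {
    p_adj_mat <- NULL
    p_adj <- benjamini_hochberg(rowMeans(p_raw))
  }

  theta_par <- rowMeans(est$theta_par)
  theta_perp <- mean(est$theta_perp)
  theta <- theta_par + theta_perp
  res <- data.frame(
    taxon = rownames(y),
    theta = theta,
    theta_par = theta_par,
    theta_perp = rep(theta_perp, D),
    p_adj = p_adj,
    significant = p_adj < alpha,
    direction = ifelse(theta > 0, "+", ifelse(theta < 0, "-", "0")),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "n_replicates") <- S
  attr(res, "scale_model") <- scl$model_name
  attr(res, "gamma") <- scale_model$gamma
  attr(res, "alpha") <- alpha
  attr(res, "seed") <- seed
  attr(res, "p_average") <- p_average
  if (keep_replicates) {
    attr(res, "p_raw") <- p_raw
    attr(res, "p_adj_replicates") <- p_adj_mat
    attr(res, "theta_replicates") <- est
  }
  class(res) <- c("da_result", "data.frame")
  res
}
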