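#' Monte Carlo replicates of per-sample composition
#'
#' The measurement model of the engine: for each sample, composition
#' replicates are drawn from the Dirichlet posterior
#' `Dirichlet(y_n + prior_mass)` implied by a Dirichlet-multinomial model of
#' the observed counts `y_n`. Zeros in the counts yield strictly positive
#' but stochastically small proportions; no pseudo-count point replacement
#' is performed.
#'
#' @param counts A [count_table()] or a non-negative integer matrix
#'   (taxa x samples).
#' @param n_replicates Number of Monte Carlo replicates S (>= 1).
#' @param prior_mass Non-negative Dirichlet prior mass added to every cell;
#'   the default 0.5 is the uniform-prior convention of Dirichlet-multinomial
#'   resampling frameworks.
#' @param seed Integer seed; draws are deterministic given the seed.
#' @return An object of class `composition_replicates`: list with `values`
#'   (D x N x S array of proportions; every `(sample, replicate)` slice sums
#'   to 1), `prior_mass`, `n_replicates`, `seed`.
#' @examples
#' ct <- count_table(matrix(c(10L, 0L), 2, 1,
#'                   dimnames = list(c("a", "b"), "s1")), condition = 0)
#' cr <- draw_compositions(ct, n_replicates = 50, seed = 1)
#' colSums(cr$values[, 1, ])[1:3]  # each replicate sums to 1
#' @export
draw_compositions <- function(counts, n_replicates = 128, prior_mass = 0.5,
                              seed = 1) {
  y <- .as_count_matrix(counts)
  n_replicates <- .assert_count(n_replicates, "n_replicates")
  .assert_scalar_number(prior_mass, "prior_mass", min = 0)
  seed <- .assert_count(seed, "seed", min = -.Machine$integer.max)
  if (any(y < 0) || any(y != round(y)))
    stop("`counts` must be non-negative integers", call. = FALSE)
  D <- nrow(y); N <- ncol(y); S <- n_replicates
  zero_total <- colSums(y) == 0
  if (any(zero_total)) {
    if (prior_mass == 0)
      stop("sample(s) with zero total count and prior_mass = 0: ",
           paste(colnames(y)[zero_total], collapse = ", "),
           " (posterior undefined)", call. = FALSE)
    warning("sample(s) with zero total count draw from the uniform prior: ",
            paste(colnames(y)[zero_total], collapse = ", "), call. = FALSE)
  }
  alpha <- as.numeric(y) + prior_mass
  values <- withr::with_seed(seed, {
    g <- array(rgamma(D * N * S, shape = rep(alpha, times = S)),
               dim = c(D, N, S))
    tot <- colSums(g)                      # N x S totals per (sample, rep)
    g / array(rep(tot, each = D), dim = c(D, N, S))
  })
  dimnames(values) <- list(rownames(y), colnames(y), NULL)
  structure(list(values = values, prior_mass = prior_mass,
                 n_replicates = S, seed = seed),
            class = "composition_replicates")
}

#' @export
print.composition_replicates <- function(x, ...) {
  d <- dim(x$values)
  cat("composition_replicates: ", d[1], " taxa x ", d[2], " samples x ",
      d[3], " replicates (prior_mass = ", x$prior_mass, ")\n", sep = "")
  invisible(x)
}

.as_composition_array <- function(comp) {
  if (inherits(comp, "composition_replicates")) comp$values
  else if (is.array(comp) && length(dim(comp)) == 3L) comp
  else stop("expected composition_replicates or a D x N x S array",
            call. = FALSE)
}
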