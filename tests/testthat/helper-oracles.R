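# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the BH oracle applies the step-up formula
# directly, and the rank-sum oracle enumerates data splits using the
# Mann-Whitney pairwise-comparison statistic instead of rank sums.

bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  stepped <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(1, stepped)[order(o)]
}

# U statistic by explicit pairwise comparison (0.5 for ties)
u_stat <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) u <- u + (xi > yj) + 0.5 * (xi == yj)
  u
}

# exact two-sided rank-sum p by brute force over all assignments of the
# pooled observations to the first group
wilcox_exact_oracle <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  n <- length(pooled)
  mu <- nx * (n - nx) / 2
  u_obs <- u_stat(x, y)
  splits <- utils::combn(n, nx)
  stats <- apply(splits, 2, function(idx)
    u_stat(pooled[idx], pooled[-idx]))
  mean(abs(stats - mu) >= abs(u_obs - mu) - 1e-9)
}

tiny_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_taxa = 20, n_per_group = 5, depth_mean = 2000), list(...))
  do.call(sim_config, args)
}

# fabricate a da_result-like frame for scoring tests
fake_da <- function(taxa, sig_idx, dir) {
  data.frame(taxon = taxa,
             significant = seq_along(taxa) %in% sig_idx,
             direction = dir, stringsAsFactors = FALSE)
}
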