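test_that("absolute replicates are the elementwise log2 sum", {
  # scale identically zero: output is log2 of the compositions
  v <- array(runif(2 * 3 * 4, 0.1, 1), c(2, 3, 4))
  zero <- matrix(0, 3, 4)
  expect_equal(absolute_replicates(v, zero), log2(v))

  # uniform composition with constant log2 load c: every entry c - log2(D)
  u <- array(1 / 5, c(5, 2, 3))
  sc <- matrix(2.5, 2, 3)
  expect_equal(absolute_replicates(u, sc),
               array(2.5 - log2(5), c(5, 2, 3)))

  # random instance against an explicit triple loop
  set.seed(42)
  v <- array(runif(3 * 4 * 2, 0.01, 1), c(3, 4, 2))
  sc <- matrix(rnorm(4 * 2), 4, 2)
  got <- absolute_replicates(v, sc)
  want <- array(0, dim(v))
  for (d in 1:3) for (n in 1:4) for (s in 1:2)
    want[d, n, s] <- log2(v[d, n, s]) + sc[n, s]
  expect_equal(got, want)

  expect_error(absolute_replicates(v, matrix(0, 2, 2)), "shape mismatch")
})

test_that("theta decomposes into compositional and scale parts", {
  # doubling relative abundance while load halves cancels exactly
  comp <- array(c(2 / 3, 1 / 3, 1 / 3, 2 / 3), c(2, 2, 1))
  scl <- matrix(c(-1, 0), 2, 1)
  est <- estimate_theta(comp, scl, condition = c(1, 0))
  expect_equal(est$theta_par[1, 1], 1)
  expect_equal(est$theta_perp[1], -1)
  expect_lt(abs(est$theta[1, 1]), 1e-12)

  # identical group compositions and scales give theta = 0 everywhere
  same <- array(rep(c(0.2, 0.3, 0.5), 4), c(3, 4, 1))
  est0 <- estimate_theta(same, matrix(1, 4, 1), c(0, 0, 1, 1))
  expect_true(all(abs(est0$theta) < 1e-12))

  # two-samples-per-group toy against hand-computed means
  v <- array(c(0.5, 0.5, 0.25, 0.75, 0.1, 0.9, 0.6, 0.4), c(2, 4, 1))
  sc <- matrix(c(1, 2, 3, 5), 4, 1)
  est2 <- estimate_theta(v, sc, c(0, 0, 1, 1))
  tp_hand <- mean(c(log2(0.1), log2(0.6))) -
    mean(c(log2(0.5), log2(0.25)))
  expect_equal(est2$theta_par[1, 1], tp_hand, tolerance = 1e-12)
  expect_equal(est2$theta_perp[1], mean(c(3, 5)) - mean(c(1, 2)))
  expect_error(estimate_theta(v, sc, c(0, 0, 0, 0)), "both conditions")
})

test_that("the decomposition identity holds per replicate for every model", {
  ds <- generate_paired_dataset(tiny_cfg(frac_diff = 0.2, effect_log2 = 2,
                                         scale_shift_log2 = 1, seed = 21))
  cond <- ds$counts$condition
  cr <- draw_compositions(ds$counts, n_replicates = 16, seed = 2)
  models <- list(
    tss_scale(cond, 16, gamma = 0, seed = 3),
    tss_scale(cond, 16, gamma = 1, seed = 3),
    external_scale(ds$measured_loads_log2, 16, gamma = 0.5, seed = 3),
    predicted_scale(ds$true_loads_log2, 16))
  idx1 <- which(cond == 1); idx0 <- which(cond == 0)
  for (sc in models) {
    est <- estimate_theta(cr, sc, cond)
    expect_lt(max(abs(est$theta - (est$theta_par +
                                   rep(est$theta_perp, each = 20)))), 1e-10)
    # and theta recomputed from the absolute abundances agrees
    la <- absolute_replicates(cr, sc)
    theta_direct <- sapply(seq_len(16), function(s)
      rowMeans(la[, idx1, s]) - rowMeans(la[, idx0, s]))
    expect_lt(max(abs(est$theta - theta_direct)), 1e-10)
  }
})

test_that("exact rank-sum p-values match brute-force enumeration", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4), mode = "exact"), 1 / 3)
  expect_equal(wilcoxon_rank_sum(c(1, 5, 2), c(1, 5, 2)), 1)
  expect_equal(wilcoxon_rank_sum(c(3, 3, 3), c(3, 3), mode = "normal"), 1)

  set.seed(7)
  for (i in 1:5) {
    x <- sample(1:6, 5, replace = TRUE)  # ties guaranteed
    y <- sample(1:6, 5, replace = TRUE)
    expect_equal(wilcoxon_rank_sum(x, y, mode = "exact"),
                 wilcox_exact_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("normal-mode rank-sum matches the tie-corrected approximation", {
  set.seed(13)
  for (i in 1:10) {
    x <- round(rnorm(12), 1)  # rounding induces occasional ties
    y <- round(rnorm(15, 0.5), 1)
    want <- suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value)
    expect_equal(wilcoxon_rank_sum(x, y, mode = "normal"), want,
                 tolerance = 1e-12)
  }
})

test_that("benjamini_hochberg implements the step-up adjustment", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(c(0.005, 0.02, 0.1)),
               c(0.015, 0.03, 0.1))
  expect_equal(benjamini_hochberg(rep(0.2, 5)), rep(0.2, 5))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(99)
  for (i in 1:20) {
    p <- runif(sample(2:40, 1))
    expect_equal(benjamini_hochberg(p), bh_oracle(p), tolerance = 1e-12)
  }
  # permutation equivariance: adjusting permuted p permutes the adjustment
  p <- runif(15)
  perm <- sample(15)
  expect_equal(benjamini_hochberg(p[perm]), benjamini_hochberg(p)[perm])
})

test_that("the engine controls type-I error under the complete null", {
  ds <- generate_paired_dataset(
    sim_config(n_taxa = 50, n_per_group = 20, frac_diff = 0,
               scale_shift_log2 = 0, seed = 31))
  fit <- run_da(ds$counts, scale_model = scale_model("tss"),
                n_replicates = 128, alpha = 0.05, seed = 17)
  frac_sig <- mean(fit$significant)
  expect_lte(frac_sig, 0.05 + 3 * sqrt(0.05 * 0.95 / 50))
})

test_that("a strong spiked taxon is recovered with the right direction", {
  cfg <- sim_config(n_taxa = 20, n_per_group = 30, frac_diff = 0.05,
                    effect_log2 = 4, depth_mean = 5000, seed = 12)
  ds <- generate_paired_dataset(cfg)
  spike <- names(which(ds$truth_flags != "null"))
  expect_length(spike, 1)
  fit <- run_da(ds$counts,
                scale_model = scale_model("external", gamma = 0,
                                          measured_log2 = ds$true_loads_log2),
                n_replicates = 64, seed = 3)
  row <- fit[fit$taxon == spike, ]
  expect_true(row$significant)
  expect_identical(row$direction,
                   if (ds$true_effects_log2[spike] > 0) "+" else "-")
})

test_that("constant predicted loads reproduce the TSS gamma = 0 result", {
  ds <- generate_paired_dataset(tiny_cfg(frac_diff = 0.2, effect_log2 = 2,
                                         seed = 14))
  tss <- run_da(ds$counts, scale_model = scale_model("tss"),
                n_replicates = 32, seed = 5)
  const <- run_da(ds$counts,
                  scale_model = scale_model(
                    "predicted",
                    predicted_log2 = rep(11, length(ds$counts$samples))),
                  n_replicates = 32, seed = 5)
  expect_equal(as.data.frame(tss), as.data.frame(const),
               ignore_attr = TRUE)
})

test_that("averaged adjusted p lies within the per-replicate range", {
  ds <- generate_paired_dataset(tiny_cfg(frac_diff = 0.2, effect_log2 = 2,
                                         seed = 18))
  fit <- run_da(ds$counts, scale_model = scale_model("pim"),
                n_replicates = 24, seed = 2, keep_replicates = TRUE)
  reps <- attr(fit, "p_adj_replicates")
  expect_true(all(fit$p_adj >= apply(reps, 1, min) - 1e-12))
  expect_true(all(fit$p_adj <= apply(reps, 1, max) + 1e-12))
  expect_true(all(fit$p_adj >= 0 & fit$p_adj <= 1))
  expect_identical(fit$significant, fit$p_adj < attr(fit, "alpha"))
})

test_that("TSS results depend on counts only through their proportions", {
  # deep counts: tripling every count leaves proportions, hence theta,
  # essentially unchanged under the gamma = 0 scale model
  ds <- generate_paired_dataset(
    sim_config(n_taxa = 10, n_per_group = 6, depth_mean = 1e5,
               depth_dispersion = 0, frac_diff = 0.2, effect_log2 = 2,
               seed = 9))
  m <- ds$counts$counts
  f1 <- run_da(count_table(m, ds$counts$condition),
               scale_model = scale_model("tss"), n_replicates = 64,
               seed = 4)
  f2 <- run_da(count_table(m * 3L, ds$counts$condition),
               scale_model = scale_model("tss"), n_replicates = 64,
               seed = 4)
  expect_lt(max(abs(f1$theta - f2$theta)), 0.05)
  expect_identical(f1$significant, f2$significant)
})

test_that("engine input validation catches degenerate designs", {
  ds <- generate_paired_dataset(tiny_cfg(seed = 1))
  one_taxon <- matrix(ds$counts$counts[1, , drop = FALSE], 1)
  expect_error(run_da(one_taxon, condition = ds$counts$condition,
                      scale_model = scale_model("tss")), "two taxa")
  expect_error(run_da(ds$counts, scale_model = scale_model("tss"),
                      alpha = 1.5), "alpha")
  expect_error(run_da(ds$counts, condition = rep(0L, 10),
                      scale_model = scale_model("tss")), "both conditions")
})
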