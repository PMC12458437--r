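test_that("sample correlation behaves like Pearson on the log10 vectors", {
  y <- c(1, 2, 3, 4)
  expect_equal(sample_correlation(paired_loads(y, 2 * y + 5)), 1)
  expect_equal(sample_correlation(paired_loads(y, -y)), -1)

  yhat <- c(1, 2, 3, 5)
  # textbook sum formula as oracle
  r_hand <- sum((y - mean(y)) * (yhat - mean(yhat))) /
    sqrt(sum((y - mean(y))^2) * sum((yhat - mean(yhat))^2))
  expect_equal(sample_correlation(paired_loads(y, yhat)), r_hand,
               tolerance = 1e-12)

  expect_warning(r0 <- sample_correlation(paired_loads(y, rep(2, 4))),
                 "zero variance")
  expect_true(is.nan(r0))
})

test_that("mean-centered R2 scores constants at zero and offsets at one", {
  y <- c(1, 2, 3, 4)
  expect_identical(mean_centered_r2(paired_loads(y, rep(3.7, 4))), 0)
  expect_equal(mean_centered_r2(paired_loads(y, y + 100)), 1)
  expect_equal(mean_centered_r2(paired_loads(y, c(1, 2, 3, 5))), 0.85)
  # centering is applied to each vector's own mean
  expect_equal(mean_centered_r2(paired_loads(y, c(1, 2, 3, 5) - 50)), 0.85)
  expect_warning(r2 <- mean_centered_r2(paired_loads(rep(2, 3), 1:3)),
                 "zero variance")
  expect_true(is.nan(r2))
})

test_that("high correlation can coexist with poor explained variance", {
  # compressed predictions: perfect correlation, R2 well below 1
  y <- c(5, 6, 7, 8, 9)
  pair <- paired_loads(y, 0.1 * y)
  expect_equal(sample_correlation(pair), 1)
  expect_lt(mean_centered_r2(pair), 0.2)
  expect_lte(mean_centered_r2(pair), 1)
})

test_that("centered absolute residuals drop offsets and keep misfit", {
  y <- c(0, 2)
  expect_equal(centered_abs_residuals(paired_loads(y, y)), c(0, 0))
  expect_equal(centered_abs_residuals(paired_loads(y, y + 3)), c(0, 0))
  expect_equal(centered_abs_residuals(paired_loads(y, c(2, 0))), c(2, 2))
})

test_that("feature alignment zero-fills, drops, and reports correctly", {
  prof <- matrix(c(0.6, 0.4, 0.3, 0.7), 2, 2,
                 dimnames = list(c("B", "D"), c("s1", "s2")))
  res <- align_features(prof, c("A", "B", "C"))
  expect_identical(rownames(res$matrix), c("A", "B", "C"))
  expect_equal(res$report$shared_fraction, 1 / 3)
  expect_identical(res$report$zero_filled, c("A", "C"))
  expect_identical(res$report$dropped_features, "D")
  expect_true(all(res$matrix["A", ] == 0))
  expect_equal(res$report$n_shared + length(res$report$zero_filled),
               res$report$n_expected)

  # identity alignment reorders only
  res_id <- align_features(prof, c("D", "B"))
  expect_equal(res_id$report$shared_fraction, 1)
  expect_equal(res_id$matrix, prof[c("D", "B"), ])

  # disjoint: all zeros
  res0 <- align_features(prof, c("X", "Y"))
  expect_equal(res0$report$shared_fraction, 0)
  expect_true(all(res0$matrix == 0))

  # idempotence
  twice <- align_features(res$matrix, c("A", "B", "C"))
  expect_identical(twice$matrix, res$matrix)
  expect_equal(twice$report$shared_fraction, 1)

  expect_error(align_features(prof, c("A", "A")), "duplicate")
})

test_that("renormalization restores unit column sums when requested", {
  prof <- matrix(c(0.6, 0.4, 0.3, 0.7), 2, 2,
                 dimnames = list(c("B", "D"), c("s1", "s2")))
  plain <- align_features(prof, c("A", "B"))
  expect_lt(max(colSums(plain$matrix)), 1)  # documented: no renormalization
  renorm <- align_features(prof, c("A", "B"), renormalize = TRUE)
  expect_equal(colSums(renorm$matrix), c(s1 = 1, s2 = 1))
})

test_that("mode frequency flags prediction collapse", {
  expect_equal(mode_frequency(c(5.1, 5.1, 5.1, 6.0)), 0.75)
  expect_equal(mode_frequency(1:10), 1 / 10)
  expect_equal(mode_frequency(rep(3.14, 8)), 1)
  # values equal only after rounding collapse together
  expect_equal(mode_frequency(c(1.0000001, 1.0000002, 2), decimals = 6), 2 / 3)
})

test_that("lower taxon overlap drives prediction collapse", {
  # a fixed linear predictor over the training features, applied to
  # zero-filled aligned profiles at decreasing overlap
  cfg <- sim_config(n_taxa = 40, n_per_group = 15, depth_mean = 5000,
                    seed = 55)
  train_taxa <- sprintf("taxon_%04d", 1:40)
  weights <- withr::with_seed(1, rnorm(40, sd = 4))
  rhos <- c(0, 0.25, 0.5, 0.75, 1)
  stats <- t(sapply(rhos, function(rho) {
    sc <- generate_overlap_scenario(cfg, rho)
    m <- sc$test_dataset$counts$counts
    prop <- sweep(m, 2, colSums(m), `/`)
    al <- align_features(prop, train_taxa)
    preds <- as.numeric(weights %*% al$matrix)
    c(shared = al$report$shared_fraction,
      modefreq = mode_frequency(preds, decimals = 1))
  }))
  expect_equal(stats[, "shared"], rhos, tolerance = 0.05)
  expect_equal(unname(stats[1, "modefreq"]), 1)  # zero overlap: collapse
  expect_lt(cor(stats[, "shared"], stats[, "modefreq"],
                method = "spearman"), 0)
})

test_that("linear-scale loads are validated before log transform", {
  expect_error(paired_loads(c(10, 0), c(1, 2), scale = "linear"),
               "positive")
  p <- paired_loads(c(100, 1000), c(10, 100), scale = "linear")
  expect_equal(p$measured_log10, c(2, 3))
})
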