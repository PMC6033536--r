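test_that("translation efficiency follows its defining ratio", {
  expect_equal(translation_efficiency(100, 2, 50), 1)
  expect_equal(translation_efficiency(0, 2, 50), 0)
  expect_equal(translation_efficiency(c(100, 30), c(2, 1), c(50, 30)),
               c(1, 1))
  expect_error(translation_efficiency(10, 0, 50), "mean_rna_density")
  expect_error(translation_efficiency(10, 2, 0), "cds_length")
  expect_error(translation_efficiency(-1, 2, 10), "cds_footprints")
})

test_that("pause score divides the peak by the mean of the rest", {
  expect_equal(pause_score(c(1, 1, 1, 9)), 9)
  expect_equal(pause_score(c(3, 3, 3, 3)), 1)
  # first-argmax tie break: peak at position 1, rest mean (5+1)/2
  expect_equal(pause_score(c(5, 5, 1)), 5 / 3)
  expect_error(pause_score(c(0, 0, 5)), "zero")
  expect_error(pause_score(7), "at least 2")
})

test_that("pause score is invariant to rescaling the profile", {
  set.seed(14)
  for (i in 1:20) {
    d <- rgamma(sample(3:40, 1), shape = 2)
    expect_equal(pause_score(d * runif(1, 0.01, 100)), pause_score(d))
  }
})

test_that("binned Z-scores standardize within expression bins", {
  # two-point bin: sample-SD standardization gives +/- 1/sqrt(2)
  r <- data.frame(expression = c(2, 1), lfc = c(1, -1))
  z <- binned_zscores(r, bin_size = 2)
  expect_equal(z$zscore, c(-1, 1) / sqrt(2))

  set.seed(15)
  big <- data.frame(expression = runif(900), lfc = rnorm(900))
  z <- binned_zscores(big, bin_size = 300)
  for (b in unique(z$bin)) {
    expect_lt(abs(mean(z$zscore[z$bin == b])), 1e-9)
    expect_lt(abs(sd(z$zscore[z$bin == b]) - 1), 1e-9)
  }
})

test_that("a small remainder bin is merged into the previous one", {
  set.seed(16)
  r <- data.frame(expression = runif(650), lfc = rnorm(650))
  z <- binned_zscores(r, bin_size = 300)
  expect_equal(as.integer(table(z$bin)), c(300, 350))
  expect_match(attr(z, "bin_merge"), "merged")

  # a remainder of at least half a bin is kept separate
  r2 <- data.frame(expression = runif(750), lfc = rnorm(750))
  z2 <- binned_zscores(r2, bin_size = 300)
  expect_equal(as.integer(table(z2$bin)), c(300, 300, 150))
})

test_that("binned Z-scores ignore a constant shift of all fold changes", {
  set.seed(17)
  r <- data.frame(expression = runif(400), lfc = rnorm(400))
  z1 <- binned_zscores(r, bin_size = 100)$zscore
  r$lfc <- r$lfc + 5
  z2 <- binned_zscores(r, bin_size = 100)$zscore
  expect_equal(z1, z2)
})

test_that("degenerate z-score inputs are rejected with the bin named", {
  expect_error(binned_zscores(data.frame(expression = 1, lfc = 0)),
               "at least 2")
  expect_error(
    binned_zscores(data.frame(expression = 1:4, lfc = rep(1, 4)),
                   bin_size = 4),
    "bin 1")
})

test_that("correlation reports match known exact cases", {
  x <- 1:20
  out <- correlate_features(x, 2 * x)
  expect_equal(out$pearson_r, 1)
  expect_equal(out$spearman_rs, 1)
  expect_equal(out$slope, 2)

  anti <- correlate_features(x, -x^3) # anti-monotone, nonlinear
  expect_equal(anti$spearman_rs, -1)

  expect_error(correlate_features(rep(1, 5), 1:5), "constant")
  expect_error(correlate_features(1:3, 1:4), "equal length")
})

test_that("spearman statistic is invariant under monotone transforms", {
  set.seed(18)
  x <- rlnorm(100)
  y <- rnorm(100) + x
  base <- correlate_features(x, y)$spearman_rs
  expect_equal(correlate_features(log(x), y)$spearman_rs, base)
  expect_equal(correlate_features(x^2, y)$spearman_rs, base)
})

test_that("the synthetic cohort is reproducible and structurally sound", {
  a <- generate_synthetic_profiles(n = 60, seed = 7)
  b <- generate_synthetic_profiles(n = 60, seed = 7)
  expect_identical(a$records, b$records)
  expect_equal(nrow(a$records), 60)
  expect_true(all(a$records$uorf_length >= 2))
  expect_true(all(vapply(a$profiles, function(p)
    length(p$densities) == p$uorf_length, logical(1))))
  # TE columns are consistent with the footprint counts they summarize
  te <- translation_efficiency(a$records$footprints_control,
                               a$records$rna_density * 50,
                               a$records$cds_length)
  expect_equal(te, a$records$te_control, tolerance = 0.05)
  expect_error(generate_synthetic_profiles(n = 5), "at least 10")
})

test_that("a planted length effect is recovered by the analysis chain", {
  cohort <- generate_synthetic_profiles(n = 500, effect_size = 0.5,
                                        noise = 1, seed = 19)
  rec <- binned_zscores(cohort$records, bin_size = 300)
  rep <- correlate_features(log(rec$uorf_length), rec$zscore)
  expect_gt(rep$pearson_r, 0)
  expect_lt(rep$pearson_p, 0.05)
  expect_gt(rep$slope, 0)
})

test_that("a null cohort shows no length effect beyond sampling noise", {
  cohort <- generate_synthetic_profiles(n = 400, effect_size = 0,
                                        noise = 1, seed = 20)
  rec <- binned_zscores(cohort$records, bin_size = 200)
  rep <- correlate_features(log(rec$uorf_length), rec$zscore)
  expect_lt(abs(rep$pearson_r), 3 / sqrt(400))
})
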