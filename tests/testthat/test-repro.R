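test_that("CV uses the population (divisor-n) standard deviation", {
  # a printed site pair: pop-sd CV 2.35 against the reported 2.36
  expect_equal(cv_percent(c(0.748, 0.784)), 2.3499, tolerance = 1e-4)
  expect_equal(cv_percent(c(5, 5, 5)), 0)
  expect_equal(cv_percent(c(1, 3)), 50)           # pop sd 1, mean 2
  expect_equal(cv_percent(c(2, 6) * 1e3), 50)     # scale invariance
  expect_error(cv_percent(3), "two values")
  expect_error(cv_percent(c(-1, 1)), "zero mean")
  expect_equal(CV_THRESHOLD_PERCENT, 5)
})

test_that("Bland-Altman bias and limits follow their definitions", {
  x <- c(1.2, 3.4, 2.2, 5.0)
  ba0 <- bland_altman(x, x)
  expect_equal(c(ba0$bias, ba0$loa_low, ba0$loa_high), c(0, 0, 0))

  fx <- table_metrics_fixture()
  fad <- fx[fx$weighting == "FA" & fx$metric == "density", ]
  ba <- bland_altman(fad$site1, fad$site2)
  expect_equal(ba$bias, -0.02125)                     # printed -0.022
  expect_equal(ba$loa_low, -0.046, tolerance = 1e-2)  # printed -0.046
  expect_equal(ba$loa_high - ba$bias, ba$bias - ba$loa_low)  # symmetric LoA
  expect_lte(ba$loa_low, ba$bias)
  expect_lte(ba$bias, ba$loa_high)

  # a bias that is exact arithmetic on the printed values
  mde <- fx[fx$weighting == "MD" & fx$metric == "efficiency", ]
  expect_identical(round(bland_altman(mde$site1, mde$site2)$bias, 3), -0.092)

  # swapping the measurement order negates bias and mirrors the limits
  ba_sw <- bland_altman(fad$site2, fad$site1)
  expect_equal(ba_sw$bias, -ba$bias)
  expect_equal(ba_sw$loa_low, -ba$loa_high)
  expect_error(bland_altman(1:3, 1:4), "length")
  expect_error(bland_altman(1, 2), "two pairs")
})

test_that("ICC(2,1) reproduces the worked example and its invariances", {
  fx <- table_metrics_fixture()
  fad <- fx[fx$weighting == "FA" & fx$metric == "density", ]
  X <- cbind(fad$site1, fad$site2)
  ic <- icc_2_1(X)
  expect_equal(ic$icc, 0.865, tolerance = 1e-3)   # printed 0.86
  expect_equal(ic$interpretation, "good")

  # no rater or error variance: perfect reliability
  Xp <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(icc_2_1(Xp)$icc, 1)

  # affine invariance: shift and positive scaling leave the ICC unchanged
  expect_equal(icc_2_1(10 + X)$icc, ic$icc, tolerance = 1e-12)
  expect_equal(icc_2_1(3.7 * X)$icc, ic$icc, tolerance = 1e-12)

  expect_error(icc_2_1(X[1, , drop = FALSE]), "n >= 2")
  expect_error(icc_2_1(cbind(1:4)), "k >= 2")
  Xna <- X; Xna[2, 1] <- NA
  expect_error(icc_2_1(Xna), "missing")

  # cross-check the ANOVA mean squares against aov()
  df <- data.frame(y = as.vector(X),
                   subj = factor(rep(1:4, 2)),
                   rater = factor(rep(1:2, each = 4)))
  ms <- summary(stats::aov(y ~ subj + rater, df))[[1]][["Mean Sq"]]
  expect_equal(c(ic$ms_subjects, ic$ms_raters, ic$ms_error), ms,
               tolerance = 1e-12)
})

test_that("ICC estimates track known variance components in simulation", {
  # consistency at a sample size where small-sample bias is negligible
  reps <- 300
  vals <- vapply(seq_len(reps), function(r)
    icc_2_1(generate_two_site_dataset(30, 3, 0, 1, base_value = 5,
                                      seed = 5000 + r))$icc, 0)
  expect_equal(mean(vals), 0.9, tolerance = 0.02)
  # at n = 4 the estimator is biased low, never high, toward the same target
  vals4 <- vapply(seq_len(reps), function(r)
    icc_2_1(generate_two_site_dataset(4, 3, 0, 1, seed = 9000 + r))$icc, 0)
  expect_lt(mean(vals4), 0.9)
  expect_gt(mean(vals4), 0.7)
})

test_that("reliability_table reproduces the packaged statistics rows", {
  rel <- reliability_table(table_metrics_fixture(long = TRUE))
  expect_equal(nrow(rel$stats), 20)    # 4 weightings x 5 metrics
  expect_equal(nrow(rel$cvs), 80)

  printed <- table_printed_stats()
  mg <- merge(rel$stats, printed, by = c("weighting", "metric"),
              suffixes = c("", ".printed"))
  expect_equal(nrow(mg), 20)
  expect_true(all(abs(mg$icc - mg$icc.printed) <= 0.02))
  expect_true(all(abs(mg$ba_bias - mg$ba_bias.printed) <= 0.001))
  expect_true(all(abs(mg$loa_low - mg$loa_low.printed) <= 0.005))
  expect_true(all(abs(mg$loa_high - mg$loa_high.printed) <= 0.005))

  # headline values: FA-weighted modularity is the most reliable metric
  fam <- rel$stats[rel$stats$weighting == "FA" &
                     rel$stats$metric == "modularity", ]
  expect_equal(fam$icc, 0.93, tolerance = 0.01)
  ecs <- rel$stats[rel$stats$weighting == "ECVF" &
                     rel$stats$metric == "strength", ]
  expect_identical(round(ecs$ba_bias, 3), -18.949)

  expect_error(reliability_table(table_metrics_fixture(long = TRUE)[-1, ]),
               "unpaired")
})

test_that("swapping the sites flips bias but not CV or ICC", {
  long <- table_metrics_fixture(long = TRUE)
  swapped <- long
  swapped$site <- ifelse(long$site == "site1", "site2", "site1")
  a <- reliability_table(long)
  b <- reliability_table(swapped)
  expect_equal(b$cvs$cv_percent, a$cvs$cv_percent, tolerance = 1e-12)
  expect_equal(b$stats$icc, a$stats$icc, tolerance = 1e-12)
  expect_equal(b$stats$ba_bias, -a$stats$ba_bias, tolerance = 1e-12)
  expect_equal(b$stats$loa_low, -a$stats$loa_high, tolerance = 1e-12)
})
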