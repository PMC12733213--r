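test_that("fixed-effect pooling follows the inverse-variance formulas", {
  p <- fixed_effect(c(1, 3), c(1, 1))
  expect_equal(p$pooled, 2)
  expect_equal(p$Q, 2)
  expect_equal(p$df, 1)
  # identical estimates: pooled is that estimate, Q = 0
  p0 <- fixed_effect(c(0.4, 0.4, 0.4), c(0.1, 0.2, 0.3))
  expect_equal(p0$pooled, 0.4)
  expect_equal(p0$Q, 0)
  expect_equal(p0$i2, 0)
  # uniform rescaling of all weights leaves the weighted mean unchanged
  set.seed(5)
  yi <- rnorm(6); sei <- runif(6, 0.1, 0.5)
  expect_equal(fixed_effect(yi, sei * sqrt(2))$pooled,
               fixed_effect(yi, sei)$pooled)
  expect_error(fixed_effect(1, 1), "insufficient-studies")
  expect_error(fixed_effect(c(1, 2), c(1, -1)), "input error")
})

test_that("DerSimonian-Laird agrees with a brute-force oracle", {
  set.seed(11)
  for (r in 1:25) {
    k <- sample(2:6, 1)
    yi <- rnorm(k, 0.3, 0.4)
    sei <- runif(k, 0.05, 0.6)
    ours <- random_effects_dl(yi, sei)
    oracle <- dl_oracle(yi, sei)
    expect_equal(ours$pooled, oracle$pooled, tolerance = 1e-10)
    expect_equal(ours$tau2, oracle$tau2, tolerance = 1e-10)
    expect_equal(ours$se_pooled, oracle$se, tolerance = 1e-10)
    expect_equal(ours$Q, oracle$Q, tolerance = 1e-10)
  }
})

test_that("DerSimonian-Laird agrees with metafor on random instances", {
  library(metafor)
  set.seed(13)
  for (r in 1:10) {
    k <- sample(3:8, 1)
    yi <- rnorm(k, 0.3, 0.4)
    sei <- runif(k, 0.05, 0.6)
    ours <- random_effects_dl(yi, sei)
    ref <- rma(yi = yi, sei = sei, method = "DL")
    expect_equal(ours$pooled, as.numeric(ref$beta), tolerance = 1e-10)
    expect_equal(ours$tau2, ref$tau2, tolerance = 1e-10)
    expect_equal(ours$i2, ref$I2, tolerance = 1e-6)
  }
})

test_that("random effects degenerate to fixed effect when tau2 = 0", {
  yi <- rep(0.25, 4); sei <- c(0.1, 0.2, 0.15, 0.3)
  re <- random_effects_dl(yi, sei)
  fe <- fixed_effect(yi, sei)
  expect_equal(re$tau2, 0)
  expect_equal(re$pooled, fe$pooled)
  expect_equal(re$se_pooled, fe$se_pooled)
})

test_that("I2 truncates at zero and the RE interval is never narrower", {
  set.seed(17)
  for (r in 1:20) {
    k <- sample(3:10, 1)
    yi <- rnorm(k, 0, 0.3)
    sei <- runif(k, 0.1, 0.5)
    re <- random_effects_dl(yi, sei)
    fe <- fixed_effect(yi, sei)
    if (re$Q <= re$df) expect_equal(re$i2, 0)
    expect_gte(re$i2, 0)
    expect_lt(re$i2, 100)
    expect_gte(re$tau2, 0)
    expect_gte((re$ci95_high - re$ci95_low),
               (fe$ci95_high - fe$ci95_low) - 1e-12)
  }
})

test_that("between-study variance is recovered on a large synthetic table", {
  g <- generate_studies(synthetic_config(k_studies = 200,
                                         mu_qaly_gain = 1,
                                         tau_qaly = 0.22, seed = 29))
  p <- random_effects_dl(g$table$qaly_gain, g$table$se_qaly_gain)
  # MC sd of the DL tau2-hat at this k (from replicated runs) is ~0.007
  expect_lt(abs(p$tau2 - 0.22^2), 0.022)
  expect_lt(abs(p$pooled - 1), 3 * sqrt(0.22^2 / 200))
})

test_that("log-scale ICER pooling back-transforms to a geometric-type mean", {
  # constant input: back-transformed pooled equals that constant
  p <- pool_log_icer(rep(50000, 5), rep(0.3, 5))
  expect_equal(p$back_transformed$pooled, 50000)
  # bounds stay ordered under the monotone transform
  s <- fixture()
  pf <- pool_log_icer(s$icer_per_qaly, rep(0.2, 17))
  bt <- pf$back_transformed
  expect_true(bt$ci95_low < bt$pooled && bt$pooled < bt$ci95_high)
  # equal log-scale SEs make the DL weights equal, so the pooled
  # back-transform is exactly the geometric mean: 211,596 on the fixture
  expect_equal(bt$pooled, exp(mean(log(s$icer_per_qaly))))
  expect_equal(bt$pooled, 211596.3, tolerance = 1e-6)
  # nonpositive ICERs are excluded with a warning
  expect_warning(px <- pool_log_icer(c(100, -5, 200), rep(0.1, 3)),
                 "nonpositive")
  expect_equal(px$k, 2)
  # lognormal sample with zero heterogeneity recovers the geometric mean
  set.seed(31)
  x <- rlnorm(400, meanlog = 11, sdlog = 0.25)
  pl <- pool_log_icer(x, rep(0.25, 400))
  expect_equal(pl$back_transformed$pooled, exp(11),
               tolerance = 3 * 0.25 / sqrt(400))
})

test_that("SE imputation conventions are deterministic and labeled", {
  s <- fixture()
  fx <- impute_se(s, "qaly_gain", "fixed_se", 1)
  expect_true(all(fx$se == 1))
  cv <- impute_se(s, "qaly_gain", "constant_cv", 0.2)
  expect_equal(cv$se, pmax(0.2 * abs(s$qaly_gain),
                           1e-6 * mean(abs(s$qaly_gain))))
  expect_match(attr(cv, "convention"), "constant_cv:0.2")
  # constant_cv on 0.5 gives 0.1
  tt <- tiny_table(3)
  tt$qaly_gain <- c(0.5, 0.5, 0.5)
  expect_equal(impute_se(tt, "qaly_gain", "constant_cv", 0.2)$se,
               rep(0.1, 3))
  # under a common SE the FE pooled estimate is the unweighted mean
  ef <- impute_se(s, "incremental_cost", "fixed_se", 1)
  expect_equal(fixed_effect(ef$estimate, ef$se)$pooled,
               mean(s$incremental_cost))
  # user_column requires the column
  expect_error(impute_se(s, "qaly_gain", "user_column"), "se_qaly_gain")
  g <- generate_studies(synthetic_config(seed = 3))
  eu <- impute_se(g$table, "qaly_gain", "user_column")
  expect_equal(eu$se, g$table$se_qaly_gain)
})
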