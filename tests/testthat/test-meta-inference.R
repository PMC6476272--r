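test_that("fixed-effect pooling matches the weighted-mean closed form", {
  # single row passes through
  r1 <- fixed_effect_meta(0.2, 0.1)
  expect_equal(r1$pooled_effect, 0.2)
  expect_equal(r1$se, 0.1)
  expect_equal(r1$q_df, 0)

  # two equal-precision rows: pooled mean, se / sqrt(2), Q = 2
  r2 <- fixed_effect_meta(c(0.1, 0.3), c(0.1, 0.1))
  expect_equal(r2$pooled_effect, 0.2)
  expect_equal(r2$se, 0.1 / sqrt(2))
  expect_equal(r2$q_statistic, 2)
  expect_equal(r2$q_df, 1)
  expect_equal(r2$p_heterogeneity, pchisq(2, 1, lower.tail = FALSE))

  # identical rows: no heterogeneity
  r3 <- fixed_effect_meta(c(0.2, 0.2, 0.2), c(0.1, 0.1, 0.1))
  expect_equal(r3$q_statistic, 0)
  expect_equal(r3$p_heterogeneity, 1)
  expect_equal(r3$i2_pct, 0)

  # general closed form on random rows
  set.seed(10)
  b <- rnorm(8); s <- runif(8, 0.05, 0.3)
  r <- fixed_effect_meta(b, s)
  w <- 1 / s^2
  expect_equal(r$pooled_effect, sum(w * b) / sum(w), tolerance = 1e-12)
  expect_equal(r$se, 1 / sqrt(sum(w)), tolerance = 1e-12)
})

test_that("two-estimate heterogeneity test behaves as a z test", {
  expect_equal(compare_two_estimates(0.5, 0.1, 0.5, 0.2), 1)
  # offset of 1.96 combined SEs gives p = 0.05
  se_a <- 0.1; se_b <- 0.15
  off <- qnorm(0.975) * sqrt(se_a^2 + se_b^2)
  expect_equal(compare_two_estimates(0, se_a, off, se_b), 0.05,
               tolerance = 1e-10)
  # symmetric in argument order
  expect_equal(compare_two_estimates(0.1, 0.1, 0.4, 0.2),
               compare_two_estimates(0.4, 0.2, 0.1, 0.1))
})

test_that("REML tau^2 matches the brute-force profile-likelihood grid", {
  set.seed(404)
  for (i in 1:3) {
    k <- 20
    x <- rnorm(k)
    sev <- rep(0.1, k)
    y <- 0 - 0.5 * x + rnorm(k, 0, sqrt(0.04)) + rnorm(k, 0, sev)
    X <- cbind(1, x)
    fit <- random_effects_metareg(y, sev, data.frame(x = x))
    oracle <- oracle_reml_grid(y, sev, X)
    expect_lt(abs(fit$tau2 - oracle$tau2), 1e-3)
    expect_lt(max(abs(fit$gamma - oracle$gamma)), 1e-4)
  }
})

test_that("REML fit agrees with an independent meta-regression implementation", {
  skip_if_not_installed("metafor")
  set.seed(505)
  k <- 49
  x <- rnorm(k)
  sev <- runif(k, 0.05, 0.15)
  y <- 0.1 - 0.55 * x + rnorm(k, 0, sqrt(0.04125)) + rnorm(k, 0, sev)
  fit <- random_effects_metareg(y, sev, data.frame(x = x))
  m <- metafor::rma(yi = y, sei = sev, mods = ~x, method = "REML")
  expect_equal(fit$tau2, m$tau2, tolerance = 1e-5)
  expect_equal(unname(fit$gamma), as.numeric(coef(m)), tolerance = 1e-6)
  expect_equal(unname(fit$se_gamma), as.numeric(m$se), tolerance = 1e-5)
  f0 <- random_effects_metareg(y, sev)
  m0 <- metafor::rma(yi = y, sei = sev, method = "REML")
  expect_equal(f0$tau2, m0$tau2, tolerance = 1e-5)
  # multivariable moderators
  x2 <- rnorm(k)
  fit2 <- random_effects_metareg(y, sev, data.frame(x = x, x2 = x2))
  m2 <- metafor::rma(yi = y, sei = sev, mods = ~x + x2, method = "REML")
  expect_equal(fit2$tau2, m2$tau2, tolerance = 1e-5)
  expect_equal(unname(fit2$gamma), as.numeric(coef(m2)), tolerance = 1e-6)
})

test_that("zero-residual rows give exact recovery and R^2 = 100", {
  x <- seq(-2, 2, length.out = 10)
  y <- 0.2 - 0.5 * x
  fit <- random_effects_metareg(y, rep(0.1, 10), data.frame(x = x))
  expect_equal(unname(fit$gamma), c(0.2, -0.5), tolerance = 1e-8)
  expect_equal(fit$tau2, 0, tolerance = 1e-8)
  expect_equal(fit$r2_pct, 100)
})

test_that("a permuted moderator is rarely significant", {
  set.seed(321)
  hits <- 0L
  n_rep <- 100
  for (i in seq_len(n_rep)) {
    k <- 30
    x <- rnorm(k)
    sev <- runif(k, 0.05, 0.15)
    y <- rnorm(k, 0, sqrt(0.04)) + rnorm(k, 0, sev)
    fit <- random_effects_metareg(y, sev, data.frame(x = sample(x)))
    if (fit$p_gamma[2] < 0.05) hits <- hits + 1L
  }
  expect_lte(hits / n_rep, 0.12)
})

test_that("fixed-effect pooling is the tau^2 = 0 special case", {
  set.seed(11)
  b <- rnorm(10, 0, 0.05)
  s <- runif(10, 0.2, 0.4)  # heterogeneity well below sampling noise
  fe <- fixed_effect_meta(b, s)
  re <- random_effects_metareg(b, s)
  expect_equal(re$tau2, 0, tolerance = 1e-8)
  expect_equal(unname(re$gamma[1]), fe$pooled_effect, tolerance = 1e-8)
  expect_equal(unname(re$se_gamma[1]), fe$se, tolerance = 1e-8)
})

test_that("R^2 is invariant to affine rescaling of the moderator", {
  set.seed(606)
  k <- 30
  x <- rnorm(k)
  sev <- runif(k, 0.05, 0.15)
  y <- -0.5 * x + rnorm(k, 0, 0.2) + rnorm(k, 0, sev)
  f1 <- random_effects_metareg(y, sev, data.frame(x = x))
  f2 <- random_effects_metareg(y, sev, data.frame(x = 3.2 * x - 7))
  expect_equal(f1$r2_pct, f2$r2_pct, tolerance = 1e-6)
  expect_equal(f1$tau2, f2$tau2, tolerance = 1e-8)
})

test_that("moderators derive from profiles with truncating substitution", {
  expect_equal(moderator_from_profile(100), 0)
  expect_equal(moderator_from_profile(50), log(0.5))
  expect_equal(moderator_from_profile(NA, is_truncating = TRUE), log(0.01))
  expect_equal(round(moderator_from_profile(NA, is_truncating = TRUE), 4),
               -4.6052)
  expect_equal(moderator_from_profile(NA, is_truncating = TRUE,
                                      truncating_substitution = 0.05),
               log(0.05))
  expect_equal(moderator_from_profile(c(100, NA, 50),
                                      is_truncating = c(FALSE, TRUE, FALSE)),
               c(0, log(0.01), log(0.5)))
  expect_error(moderator_from_profile(-5), "non-positive")
  expect_equal(moderator_from_profile(NA, pathway_class = "GoF",
                                      categorical = TRUE), "GoF")
})

test_that("leave-one-out refits exclude each variant in turn", {
  set.seed(13)
  k <- 10
  x <- c(rnorm(9, 0, 0.3), 4)   # one extreme-moderator row
  sev <- rep(0.1, k)
  y <- -0.5 * x + rnorm(k, 0, 0.1)
  loo <- leave_one_out_metareg(y, sev, data.frame(x = x),
                               labels = paste0("v", 1:k))
  expect_equal(nrow(loo), k)
  expect_setequal(loo$excluded, paste0("v", 1:k))

  # excluding the extreme-leverage row moves gamma1 more than excluding the
  # row closest to the mean moderator
  full <- random_effects_metareg(y, sev, data.frame(x = x))
  g_full <- unname(full$gamma[2])
  shift <- abs(loo$gamma1 - g_full)
  central <- which.min(abs(x - mean(x)))
  expect_gt(shift[k], shift[central])

  # constant outcomes give identical refits (gamma1 = 0 in every iteration)
  y_c <- rep(0.2, 6); x_c <- rep(c(0, 1), 3)
  loo_c <- leave_one_out_metareg(y_c, rep(0.1, 6), data.frame(x = x_c))
  expect_equal(length(unique(round(loo_c$gamma1, 10))), 1)
  expect_equal(unique(round(loo_c$gamma1, 10)), 0)
})

test_that("row filters implement the sensitivity-analysis rules", {
  rows <- data.frame(variant_id = paste0("v", 1:6),
                     allele_freq = c(9e-6, 2e-5, 1e-4, 1e-3, 6e-3, 0.02),
                     quality_score = c(4, 3, 2, 1, 4, 4),
                     category = c("LoF", "LoF", "GoF", "WT-like", "GoF", "LoF"),
                     is_truncating = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  # ultra-rare exclusion: frequency < 0.001% (1e-5) removed
  f1 <- suppressMessages(filter_rows(rows, min_freq = 1e-5))
  expect_setequal(f1$variant_id, paste0("v", 2:6))
  # quality threshold 4 keeps only maximum-score rows
  f2 <- suppressMessages(filter_rows(rows, min_quality = 4))
  expect_setequal(f2$variant_id, c("v1", "v5", "v6"))
  # rare-only: frequency < 0.5%
  f3 <- suppressMessages(filter_rows(rows, rare_only = TRUE))
  expect_setequal(f3$variant_id, paste0("v", 1:4))
  # category subset and truncating exclusion
  f4 <- suppressMessages(filter_rows(rows, categories = c("LoF", "GoF"),
                                     include_truncating = FALSE))
  expect_setequal(f4$variant_id, c("v2", "v3", "v5", "v6"))
  # no rules: identity
  expect_identical(suppressMessages(filter_rows(rows)), rows)
  expect_error(suppressMessages(filter_rows(rows, min_freq = 1)), "all rows")
})
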