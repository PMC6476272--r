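test_that("variant panel honors the generating BMI-effect model", {
  # zero residual variance: every effect lies exactly on the moderator line
  cfg <- simulation_config(seed = 3, n_variants = 50, tau2 = 0,
                           gamma0 = 0.1, gamma1 = -0.5)
  panel <- simulate_variant_panel(cfg)
  expect_equal(panel$true_beta_bmi,
               0.1 - 0.5 * log(panel$true_emax_barr), tolerance = 1e-12)
  expect_true(all(panel$true_u == 0))

  # fully null model: all effects are zero
  cfg0 <- simulation_config(seed = 3, n_variants = 50, tau2 = 0,
                            gamma0 = 0, gamma1 = 0)
  panel0 <- simulate_variant_panel(cfg0)
  expect_true(all(panel0$true_beta_bmi == 0))

  # truncating variants: always LoF with both efficacies at 1% of WT
  tr <- panel[panel$is_truncating, ]
  expect_true(all(tr$true_category == "LoF"))
  expect_true(all(tr$true_emax_camp <= 0.01 & tr$true_emax_barr <= 0.01))
})

test_that("allele frequencies are log-uniform over the configured range", {
  cfg <- simulation_config(seed = 5, n_variants = 10000,
                           freq_range = c(1e-5, 0.02))
  panel <- simulate_variant_panel(cfg)
  expect_gte(min(panel$allele_freq), 1e-5)
  expect_lte(max(panel$allele_freq), 0.02)
  ks <- ks.test(log(panel$allele_freq), "punif", log(1e-5), log(0.02))
  expect_gt(ks$p.value, 0.01)
})

test_that("config validation rejects malformed inputs", {
  expect_error(simulation_config(category_mix = c(LoF = 0.5, `WT-like` = 0.2,
                                                  GoF = 0.2)),
               "sum to 1")
  expect_error(simulation_config(freq_range = c(0.01, 0.5)), "freq_range")
  expect_error(simulation_config(tau2 = -1), "tau2")
  expect_error(simulation_config(assay = list(n_replicate_experiments = 1)),
               "replicate")
})

test_that("genotypes are Hardy-Weinberg binomial draws", {
  panel <- data.frame(variant_id = c("A", "B", "C"),
                      allele_freq = c(0, 0.5, 0.01))
  g <- simulate_genotypes(panel, 100000, seed = 9)
  expect_true(all(g %in% 0:2))

  # f = 0: monomorphic
  expect_true(all(g[, "A"] == 0))

  # f = 0.5: mean allele count within 3 binomial SEs of 1
  se_mean <- sqrt(2 * 0.5 * 0.5 / 100000)
  expect_lt(abs(mean(g[, "B"]) - 1), 3 * se_mean)

  # f = 0.01: genotype class counts consistent with HWE (chi-square oracle)
  f <- 0.01
  obs <- tabulate(g[, "C"] + 1, nbins = 3)
  chi <- chisq.test(obs, p = c((1 - f)^2, 2 * f * (1 - f), f^2))
  expect_gt(chi$p.value, 0.01)
})

test_that("phenotypes follow the additive BMI model and recover a known effect", {
  # a single common variant with beta = -0.39 is recovered within 2 SE at
  # biobank-like scale
  effects <- data.frame(variant_id = "V1", allele_freq = 0.02,
                        true_emax_camp = 1.2, true_emax_barr = 1.2,
                        true_beta_bmi = -0.39, true_u = 0,
                        true_category = "GoF", is_truncating = FALSE)
  cfg <- simulation_config(seed = 21, n_individuals = 200000, n_variants = 1,
                           covariate_effects = c(age = 0, sex = 0, array = 0))
  g <- simulate_genotypes(effects, cfg$n_individuals, cfg$seed)
  ph <- simulate_phenotypes(g, effects, cfg)$phenotypes
  fit <- fit_linear_assoc(ph$bmi, g[, 1])
  expect_lt(abs(fit$effect - (-0.39)), 2 * fit$se)

  # outcome prevalence independent of BMI when the logistic slope is 0
  cfg0 <- simulation_config(seed = 22, n_individuals = 50000, n_variants = 1,
                            disease_logodds_per_bmi = 0)
  ph0 <- simulate_phenotypes(g[1:50000, , drop = FALSE], effects, cfg0)$phenotypes
  hi <- ph0$t2d[ph0$bmi >= median(ph0$bmi)]
  lo <- ph0$t2d[ph0$bmi < median(ph0$bmi)]
  expect_gt(prop.test(c(sum(hi), sum(lo)), c(length(hi), length(lo)))$p.value,
            0.01)
})

test_that("null genotype-BMI association has nominal confidence coverage", {
  effects <- data.frame(variant_id = "V1", allele_freq = 0.1,
                        true_emax_camp = 1, true_emax_barr = 1,
                        true_beta_bmi = 0, true_u = 0,
                        true_category = "WT-like", is_truncating = FALSE)
  covered <- 0L
  n_rep <- 200
  for (r in seq_len(n_rep)) {
    cfg <- simulation_config(seed = 1000 + r, n_individuals = 400,
                             n_variants = 1,
                             covariate_effects = c(age = 0, sex = 0, array = 0))
    g <- simulate_genotypes(effects, cfg$n_individuals, cfg$seed)
    ph <- simulate_phenotypes(g, effects, cfg)$phenotypes
    fit <- fit_linear_assoc(ph$bmi, g[, 1])
    ci <- fit$effect + c(-1, 1) * qt(0.975, fit$n - 2) * fit$se
    if (ci[1] <= 0 && ci[2] >= 0) covered <- covered + 1L
  }
  expect_gte(covered / n_rep, 0.90)
})

test_that("generated moderator/effect pairs satisfy the variance identity", {
  # Var(beta) = gamma1^2 Var(ln Emax) + tau2, within 5% relative error
  cfg <- simulation_config(seed = 17, n_variants = 10000)
  panel <- simulate_variant_panel(cfg)
  x <- log(panel$true_emax_barr)
  expected <- cfg$gamma1^2 * var(x) + cfg$tau2
  expect_lt(abs(var(panel$true_beta_bmi) - expected) / expected, 0.05)
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- simulation_config(seed = 8, n_individuals = 500, n_variants = 10,
                           freq_range = c(0.001, 0.02))
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$effects, d2$effects)
  expect_identical(d1$genotypes, d2$genotypes)
  expect_identical(d1$phenotypes, d2$phenotypes)
  expect_identical(d1$traces, d2$traces)
})

test_that("noiseless plates quantify back to the generating E_max exactly", {
  cfg <- simulation_config(seed = 12, n_variants = 8, prop_truncating = 0,
                           assay = list(noise_sd = 0))
  panel <- simulate_variant_panel(cfg)
  traces <- simulate_assay_plate(panel, cfg)

  # mock wells stay at baseline at all times
  mock <- traces[traces$condition == "mock", ]
  expect_equal(unique(mock$signal), cfg$assay$baseline)

  # zero noise makes every sample zero-variance, which test_vs_wt flags
  prof <- suppressWarnings(
    quantify_traces(traces, baseline_end = cfg$assay$baseline_duration_s))
  prof <- prof[match(panel$variant_id, prof$variant_id), ]
  expect_equal(prof$emax_camp_pct, 100 * panel$true_emax_camp,
               tolerance = 1e-9)
  expect_equal(prof$emax_barr_pct, 100 * panel$true_emax_barr,
               tolerance = 1e-9)
})

test_that("dataset files round-trip through the documented schemas", {
  cfg <- simulation_config(seed = 30, n_individuals = 200, n_variants = 5,
                           freq_range = c(0.01, 0.02))
  ds <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir)
  gt <- read.delim(paths[["genotypes"]])
  expect_equal(nrow(gt), 200)
  expect_equal(as.matrix(gt[, -1]), ds$genotypes, ignore_attr = TRUE)
  tr <- read.csv(paths[["traces"]])
  expect_named(tr, c("variant_id", "pathway", "condition", "replicate",
                     "time_s", "signal"))
  ph <- read.delim(paths[["phenotypes"]])
  expect_equal(ph$bmi, ds$phenotypes$bmi, tolerance = 1e-9)
})
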