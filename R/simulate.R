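#' Simulate a panel of MC4R-like variants with known functional effects
#'
#' Draws allele frequencies log-uniformly over the configured range, assigns
#' each variant a functional category (LoF, WT-like or GoF), draws true
#' relative maximal efficacies (fraction of wild type, 1.0 = WT) for the cAMP
#' and beta-arrestin pathways, and generates the true per-allele BMI effect
#' from the moderator model
#' \eqn{\beta_v = \gamma_0 + \gamma_1 \ln(E_{max,\beta arr,v}) + u_v},
#' \eqn{u_v \sim N(0, \tau^2)}. Truncating (nonsense/frameshift) variants are
#' not assayed in vitro; they carry efficacies of 1% of wild type in both
#' pathways and are always LoF.
#'
#' @param config a [simulation_config()] object.
#' @return data frame with one row per variant: `variant_id`, `allele_freq`,
#'   `true_emax_camp`, `true_emax_barr`, `true_beta_bmi`, `true_u` (the
#'   recorded between-variant residual), `true_category`, `is_truncating`.
#' @export
simulate_variant_panel <- function(config) {
  config <- validate_config(config)
  set.seed(derive_seed(config$seed, "panel"))
  k <- config$n_variants

  lf <- stats::runif(k, log(config$freq_range[1]), log(config$freq_range[2]))
  freq <- exp(lf)

  n_trunc <- round(config$prop_truncating * k)
  is_trunc <- seq_len(k) <= n_trunc   # ids are shuffled by random freq order anyway
  cats <- character(k)
  cats[is_trunc] <- "LoF"
  n_rest <- k - n_trunc
  cats[!is_trunc] <- sample(names(config$category_mix), n_rest, replace = TRUE,
                            prob = config$category_mix)

  emax_camp <- numeric(k)
  emax_barr <- numeric(k)
  for (i in seq_len(k)) {
    if (is_trunc[i]) {
      emax_camp[i] <- 0.01
      emax_barr[i] <- 0.01
    } else if (cats[i] == "LoF") {
      emax_camp[i] <- stats::runif(1, config$emax_lof_range[1],
                                   config$emax_lof_range[2])
      emax_barr[i] <- stats::runif(1, config$emax_lof_range[1],
                                   config$emax_lof_range[2])
    } else if (cats[i] == "GoF") {
      emax_camp[i] <- stats::runif(1, config$emax_gof_range[1],
                                   config$emax_gof_range[2])
      emax_barr[i] <- stats::runif(1, config$emax_gof_range[1],
                                   config$emax_gof_range[2])
    } else {
      emax_camp[i] <- abs(stats::rnorm(1, 1, config$emax_wt_sd))
      emax_barr[i] <- abs(stats::rnorm(1, 1, config$emax_wt_sd))
    }
  }

  u <- if (config$tau2 > 0) stats::rnorm(k, 0, sqrt(config$tau2)) else rep(0, k)
  beta <- config$gamma0 + config$gamma1 * log(emax_barr) + u

  data.frame(variant_id = sprintf("V%03d", seq_len(k)),
             allele_freq = freq,
             true_emax_camp = emax_camp,
             true_emax_barr = emax_barr,
             true_beta_bmi = beta,
             true_u = u,
             true_category = cats,
             is_truncating = is_trunc,
             stringsAsFactors = FALSE)
}

#' Simulate Hardy-Weinberg genotypes
#'
#' Allele counts are drawn independently per variant as Binomial(2, f): the
#' panel variants are in negligible linkage disequilibrium (pairwise R^2 <
#' 0.01), so no LD is simulated.
#'
#' @param effects variant panel from [simulate_variant_panel()].
#' @param n number of individuals.
#' @param seed integer seed.
#' @return integer matrix of allele counts (0/1/2), rows = samples, columns
#'   named by `variant_id`.
#' @export
simulate_genotypes <- function(effects, n, seed) {
  stopifnot(n >= 1)
  set.seed(derive_seed(seed, "genotypes"))
  k <- nrow(effects)
  g <- matrix(0L, nrow = n, ncol = k,
              dimnames = list(NULL, effects$variant_id))
  for (j in seq_len(k)) {
    g[, j] <- stats::rbinom(n, 2L, effects$allele_freq[j])
  }
  g
}

#' Simulate phenotypes and covariates for a genotyped cohort
#'
#' BMI is additive in allele counts:
#' `BMI = bmi_mean + covariate terms + sum_v beta_v g_v + N(0, bmi_sd^2)`.
#' Binary outcomes (type 2 diabetes and coronary artery disease stand-ins)
#' depend on genotype only through BMI:
#' `logit P = disease_base_logodds + disease_logodds_per_bmi * (BMI - bmi_mean)`.
#'
#' @param genotypes allele-count matrix from [simulate_genotypes()].
#' @param effects the matching variant panel.
#' @param config the [simulation_config()] used for the run.
#' @return list with `phenotypes` (data frame: `sample_id`, `age`, `sex`,
#'   `array`, `bmi`, `t2d`, `cad`) and the `genotypes` matrix passed through.
#' @export
simulate_phenotypes <- function(genotypes, effects, config) {
  config <- validate_config(config)
  stopifnot(ncol(genotypes) == nrow(effects))
  set.seed(derive_seed(config$seed, "phenotypes"))
  n <- nrow(genotypes)

  age <- stats::runif(n, 40, 69)          # cohort recruitment window
  sex <- stats::rbinom(n, 1L, 0.5)
  array <- stats::rbinom(n, 1L, 0.1)      # minority genotyped on second array

  ce <- config$covariate_effects
  genetic <- as.numeric(genotypes %*% effects$true_beta_bmi)
  bmi <- config$bmi_mean +
    ce[["age"]] * (age - mean(c(40, 69))) + ce[["sex"]] * sex +
    ce[["array"]] * array + genetic + stats::rnorm(n, 0, config$bmi_sd)

  lp <- config$disease_base_logodds +
    config$disease_logodds_per_bmi * (bmi - config$bmi_mean)
  pr <- stats::plogis(lp)
  t2d <- stats::rbinom(n, 1L, pr)
  cad <- stats::rbinom(n, 1L, pr)

  list(phenotypes = data.frame(sample_id = sprintf("S%06d", seq_len(n)),
                               age = age, sex = sex, array = array, bmi = bmi,
                               t2d = t2d, cad = cad,
                               stringsAsFactors = FALSE),
       genotypes = genotypes)
}

# Closed-form trace of the noiseless saturating-exponential model:
# baseline + A * E * (1 - exp(-k * t_post)) after stimulation, flat baseline
# before. Exposed for tests that need the analytic AUC.
trace_signal <- function(time_s, emax_frac, assay) {
  t_post <- pmax(0, time_s - assay$baseline_duration_s)
  assay$baseline +
    assay$plateau_scale * emax_frac * (1 - exp(-assay$rise_rate * t_post))
}

#' Simulate a plate of time-resolved luminescence traces
#'
#' For each variant, pathway and replicate experiment a trace is generated as
#' a flat noisy baseline followed, post-stimulation, by a saturating
#' exponential rise `baseline + plateau_scale * E * (1 - exp(-rise_rate * t))`
#' whose plateau is proportional to the variant's true relative E_max for that
#' pathway. Every replicate plate carries its own mock well (E = 0) and
#' wild-type well (E = 1), the anchors of the two-point normalization.
#' Truncating variants are not assayed and get no wells.
#'
#' @param effects variant panel from [simulate_variant_panel()].
#' @param config the [simulation_config()] for the run.
#' @return long-format data frame: `variant_id`, `pathway` (`"cAMP"` or
#'   `"barr"`), `condition` (`"mock"`, `"WT"`, `"variant"`), `replicate`,
#'   `time_s`, `signal`.
#' @export
simulate_assay_plate <- function(effects, config) {
  config <- validate_config(config)
  set.seed(derive_seed(config$seed, "plates"))
  a <- config$assay
  time_s <- seq(0, by = a$sampling_interval_s, length.out = a$n_timepoints)

  assayed <- effects[!effects$is_truncating, , drop = FALSE]
  wells <- rbind(
    data.frame(variant_id = "mock", condition = "mock", emax_camp = 0,
               emax_barr = 0, stringsAsFactors = FALSE),
    data.frame(variant_id = "WT", condition = "WT", emax_camp = 1,
               emax_barr = 1, stringsAsFactors = FALSE),
    data.frame(variant_id = assayed$variant_id, condition = "variant",
               emax_camp = assayed$true_emax_camp,
               emax_barr = assayed$true_emax_barr, stringsAsFactors = FALSE)
  )

  out <- vector("list", 2 * a$n_replicate_experiments * nrow(wells))
  i <- 1L
  for (pathway in c("cAMP", "barr")) {
    for (rep_i in seq_len(a$n_replicate_experiments)) {
      for (w in seq_len(nrow(wells))) {
        e <- if (pathway == "cAMP") wells$emax_camp[w] else wells$emax_barr[w]
        mu <- trace_signal(time_s, e, a)
        sig <- mu + if (a$noise_sd > 0) stats::rnorm(length(time_s), 0, a$noise_sd) else 0
        out[[i]] <- data.frame(variant_id = wells$variant_id[w],
                               pathway = pathway,
                               condition = wells$condition[w],
                               replicate = rep_i,
                               time_s = time_s, signal = sig,
                               stringsAsFactors = FALSE)
        i <- i + 1L
      }
    }
  }
  do.call(rbind, out)
}

#' Generate a complete synthetic dataset
#'
#' Runs the variant panel, genotype, phenotype and assay-plate generators in
#' sequence under a single run seed with deterministic per-stage sub-seeds.
#'
#' @param config a [simulation_config()].
#' @return list: `config`, `effects`, `genotypes`, `phenotypes`, `traces`.
#' @export
simulate_dataset <- function(config) {
  config <- validate_config(config)
  effects <- simulate_variant_panel(config)
  genotypes <- simulate_genotypes(effects, config$n_individuals, config$seed)
  pheno <- simulate_phenotypes(genotypes, effects, config)
  traces <- simulate_assay_plate(effects, config)
  list(config = config, effects = effects, genotypes = genotypes,
       phenotypes = pheno$phenotypes, traces = traces)
}

#' Write a synthetic dataset to disk
#'
#' Genotypes, phenotypes/covariates and the variant truth table are written as
#' TSV; assay traces as long-format CSV, matching the schemas the
#' quantification and association stages read.
#'
#' @param dataset output of [simulate_dataset()].
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of file paths written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genotypes = file.path(dir, "genotypes.tsv"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             variants = file.path(dir, "variant_truth.tsv"),
             traces = file.path(dir, "assay_traces.csv"))
  gt <- as.data.frame(dataset$genotypes)
  gt <- cbind(sample_id = dataset$phenotypes$sample_id, gt)
  utils::write.table(gt, paths["genotypes"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dataset$phenotypes, paths["phenotypes"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$effects, paths["variants"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(dataset$traces, paths["traces"], row.names = FALSE,
                   quote = FALSE)
  invisible(paths)
}
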