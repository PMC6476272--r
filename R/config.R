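#' Simulation configuration
#'
#' Constructs the configuration object that drives the synthetic-data
#' generator. The defaults describe a desk-scale cohort with the statistical
#' structure the downstream analysis assumes: rare variants with allele
#' frequencies spanning 2% down to 0.0001% drawn log-uniformly, per-variant
#' BMI effects generated from the moderator model
#' \deqn{\beta_v = \gamma_0 + \gamma_1 \ln(E_{max,\beta arr,v}) + u_v,
#'   \quad u_v \sim N(0, \tau^2),}
#' binary disease outcomes depending on genotype only through BMI, and
#' saturating noisy luminescence traces whose plateau scales with each
#' variant's true maximal efficacy.
#'
#' @param seed integer seed for the run's random number stream.
#' @param n_individuals cohort size.
#' @param n_variants number of nonsynonymous variants in the panel.
#' @param freq_range length-2 numeric, allele-frequency bounds as fractions;
#'   must lie within (0, 0.02].
#' @param category_mix named numeric proportions for `LoF`, `WT-like`, `GoF`
#'   variants; must sum to 1.
#' @param prop_truncating fraction of variants that are nonsense/frameshift
#'   (always LoF, both pathway efficacies at 1% of wild type).
#' @param gamma0 intercept of the BMI-effect model (kg/m^2 per allele).
#' @param gamma1 slope on ln relative beta-arrestin E_max (kg/m^2 per allele
#'   per ln-unit).
#' @param tau2 between-variant residual variance of true BMI effects
#'   ((kg/m^2 per allele)^2).
#' @param bmi_mean,bmi_sd population BMI distribution (kg/m^2).
#' @param covariate_effects named numeric: `age` (kg/m^2 per year), `sex` and
#'   `array` (kg/m^2 shift).
#' @param disease_base_logodds baseline log-odds of each binary outcome at
#'   population-mean BMI.
#' @param disease_logodds_per_bmi log-odds per kg/m^2 of BMI above the mean.
#' @param emax_lof_range,emax_wt_sd,emax_gof_range distribution of true
#'   relative E_max (fraction of wild type) per category: LoF uniform on
#'   `emax_lof_range`, WT-like normal around 1 with SD `emax_wt_sd`
#'   (truncated positive), GoF uniform on `emax_gof_range`.
#' @param assay named list of plate-reader parameters: `baseline` (signal
#'   units), `plateau_scale` (signal units at wild-type efficacy), `rise_rate`
#'   (per second), `noise_sd` (signal units), `n_replicate_experiments`,
#'   `n_timepoints`, `sampling_interval_s`, `baseline_duration_s` (length of
#'   the pre-stimulation window).
#' @return an object of class `sim_config` (a validated named list).
#' @export
simulation_config <- function(seed = 1L,
                              n_individuals = 50000L,
                              n_variants = 60L,
                              freq_range = c(1e-6, 0.02),
                              category_mix = c(LoF = 0.77, `WT-like` = 0.08,
                                               GoF = 0.15),
                              prop_truncating = 12 / 61,
                              gamma0 = 0,
                              gamma1 = -0.55,
                              tau2 = 0.04125,
                              bmi_mean = 27,
                              bmi_sd = 4.7,
                              covariate_effects = c(age = 0.02, sex = -0.6,
                                                    array = 0),
                              disease_base_logodds = -3,
                              disease_logodds_per_bmi = 0.1,
                              emax_lof_range = c(0, 0.8),
                              emax_wt_sd = 0.03,
                              emax_gof_range = c(1.1, 1.5),
                              assay = list()) {
  assay_defaults <- list(baseline = 1000, plateau_scale = 5000,
                         rise_rate = 0.002, noise_sd = 40,
                         n_replicate_experiments = 4L,
                         n_timepoints = 110L, sampling_interval_s = 30,
                         baseline_duration_s = 600)
  assay <- utils::modifyList(assay_defaults, assay)

  cfg <- list(seed = as.integer(seed), n_individuals = as.integer(n_individuals),
              n_variants = as.integer(n_variants), freq_range = freq_range,
              category_mix = category_mix, prop_truncating = prop_truncating,
              gamma0 = gamma0, gamma1 = gamma1, tau2 = tau2,
              bmi_mean = bmi_mean, bmi_sd = bmi_sd,
              covariate_effects = covariate_effects,
              disease_base_logodds = disease_base_logodds,
              disease_logodds_per_bmi = disease_logodds_per_bmi,
              emax_lof_range = emax_lof_range, emax_wt_sd = emax_wt_sd,
              emax_gof_range = emax_gof_range, assay = assay)
  class(cfg) <- "sim_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(cfg$freq_range) != 2 || any(cfg$freq_range <= 0) ||
      any(cfg$freq_range > 0.02) || cfg$freq_range[1] > cfg$freq_range[2]) {
    stop("freq_range must be an increasing pair within (0, 0.02]")
  }
  if (abs(sum(cfg$category_mix) - 1) > 1e-9) {
    stop("category_mix must sum to 1")
  }
  if (!all(c("LoF", "WT-like", "GoF") %in% names(cfg$category_mix))) {
    stop("category_mix must name LoF, WT-like and GoF proportions")
  }
  if (cfg$tau2 < 0) stop("tau2 must be non-negative")
  if (cfg$assay$n_replicate_experiments < 2) {
    stop("at least 2 replicate experiments are required for any test result")
  }
  if (cfg$n_individuals < 1 || cfg$n_variants < 1) {
    stop("cohort and panel sizes must be positive")
  }
  cfg
}

#' Read a simulation configuration from a YAML file
#'
#' Flat keys mirror the arguments of [simulation_config()]; an `assay` section
#' holds the plate-reader parameters. Missing keys take the defaults.
#'
#' @param path path to a YAML file.
#' @return a `sim_config` object.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  # YAML maps come back as lists; the constructor expects named vectors for
  # these two fields
  for (fld in c("category_mix", "covariate_effects")) {
    if (!is.null(raw[[fld]])) raw[[fld]] <- unlist(raw[[fld]])
  }
  if (!is.null(raw$freq_range)) raw$freq_range <- unlist(raw$freq_range)
  do.call(simulation_config, raw)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  %d individuals, %d variants, allele frequency %g-%g\n",
              x$n_individuals, x$n_variants, x$freq_range[1], x$freq_range[2]))
  cat(sprintf("  BMI-effect model: gamma0 = %g, gamma1 = %g, tau2 = %g\n",
              x$gamma0, x$gamma1, x$tau2))
  cat(sprintf("  assay: %d replicates, %d timepoints every %gs, noise SD %g\n",
              x$assay$n_replicate_experiments, x$assay$n_timepoints,
              x$assay$sampling_interval_s, x$assay$noise_sd))
  invisible(x)
}
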