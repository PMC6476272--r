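#' Summarize functional categories
#'
#' Counts per overall category with percentages of the total (rounded half
#' away from zero, matching printed-summary conventions) and the percentage of
#' variants with any functional consequence (LoF + GoF + opposing).
#'
#' @param categories character vector of overall categories (truncating
#'   variants included, as LoF).
#' @return list: `counts` (named), `percent` (named, integer-rounded),
#'   `pct_any_consequence`, `total`.
#' @export
summarize_categories <- function(categories) {
  if (length(categories) == 0) stop("no classified variants")
  lv <- c("LoF", "GoF", "opposing", "WT-like")
  counts <- vapply(lv, function(l) sum(categories == l), numeric(1))
  total <- length(categories)
  pct <- round_half_away(100 * counts / total)
  any_cons <- round_half_away(100 * (counts[["LoF"]] + counts[["GoF"]] +
                                       counts[["opposing"]]) / total)
  list(counts = counts, percent = pct, pct_any_consequence = any_cons,
       total = total)
}

#' Summarize carriers of a variant set
#'
#' Counts individuals carrying exactly one and two-or-more alleles across the
#' set, their percentages of the cohort (one decimal), and the "1 in N"
#' phrasing.
#'
#' @param genotypes allele-count matrix.
#' @param variant_set variant IDs (column names) defining the set.
#' @return list: `n_1copy`, `n_2copy`, `n_total`, `pct_1copy`, `pct_2copy`,
#'   `one_in_n_1copy` (NA when there are no carriers), `cohort_n`.
#' @export
summarize_carriers <- function(genotypes, variant_set) {
  if (nrow(genotypes) == 0) stop("empty cohort")
  total <- rowSums(genotypes[, variant_set, drop = FALSE])
  n <- nrow(genotypes)
  n1 <- sum(total == 1)
  n2 <- sum(total >= 2)
  list(n_1copy = n1, n_2copy = n2, n_total = n1 + n2,
       pct_1copy = round_half_away(100 * n1 / n, 1),
       pct_2copy = round_half_away(100 * n2 / n, 1),
       one_in_n_1copy = if (n1 > 0) round(n / n1) else NA_real_,
       cohort_n = n)
}

#' BMI difference expressed as body-weight difference
#'
#' A BMI difference of `delta_bmi` kg/m^2 for a person of height `height_m`
#' meters corresponds to `delta_bmi * height_m^2` kg of body weight.
#'
#' @param delta_bmi BMI difference (kg/m^2).
#' @param height_m height (m), positive.
#' @return weight difference in kg.
#' @export
bmi_to_weight_delta <- function(delta_bmi, height_m) {
  if (any(height_m <= 0)) stop("height must be positive")
  delta_bmi * height_m^2
}

#' Run the full synthetic-data analysis pipeline
#'
#' Orchestrates simulate -> quantify -> bias -> associate -> meta-regress on a
#' fully seeded synthetic dataset and returns a machine-readable report. All
#' stage tables can optionally be written under `out_dir` together with a
#' `report.json`.
#'
#' @param config a [simulation_config()]; its `seed` drives every stage.
#' @param out_dir optional output directory for stage TSV/CSV artifacts and
#'   the JSON report.
#' @param min_carriers carrier floor below which a per-variant association is
#'   reported as unavailable.
#' @return list of class `pipeline_report`: `config` echo, `profiles`,
#'   `bias`, `associations`, `pooled` (GoF/LoF fixed-effect results),
#'   `metareg` (the moderated fit), `category_summary`, `carrier_summary`,
#'   `phewas_threshold`, `seed`, `version`.
#' @export
run_full_pipeline <- function(config = simulation_config(), out_dir = NULL,
                              min_carriers = 2) {
  config <- validate_config(config)
  dataset <- simulate_dataset(config)
  a <- config$assay

  trunc_ids <- dataset$effects$variant_id[dataset$effects$is_truncating]
  profiles <- quantify_traces(dataset$traces,
                              baseline_end = a$baseline_duration_s,
                              truncating_ids = trunc_ids)
  norm <- normalized_activities(dataset$traces,
                                baseline_end = a$baseline_duration_s)

  bias_ids <- select_bias_analysis_set(profiles)
  bias <- if (length(bias_ids) > 0) bias_table(norm, bias_ids) else NULL

  assoc <- per_variant_bmi_assoc(dataset$genotypes, dataset$phenotypes,
                                 min_carriers = min_carriers)

  # category-level pooling over estimable variants
  merged <- merge(assoc, profiles[, c("variant_id", "overall_category",
                                      "is_truncating")],
                  by.x = "unit_id", by.y = "variant_id")
  pooled <- list()
  for (cat in c("GoF", "LoF")) {
    d <- merged[merged$overall_category == cat & merged$estimable, ]
    pooled[[cat]] <- if (nrow(d) > 0) {
      fixed_effect_meta(d$effect, d$se)
    } else NULL
  }

  # meta-regression on assayed missense variants with estimable associations
  mr_rows <- merge(assoc[assoc$estimable, ],
                   profiles[!profiles$is_truncating, ],
                   by.x = "unit_id", by.y = "variant_id")
  # a measured E_max at or below 0% has no defined log-moderator; such a
  # variant (possible for near-null responders under assay noise) is dropped
  mr_rows <- mr_rows[mr_rows$emax_barr_pct > 0, , drop = FALSE]
  metareg <- if (nrow(mr_rows) >= 3) {
    x <- moderator_from_profile(mr_rows$emax_barr_pct)
    random_effects_metareg(mr_rows$effect, mr_rows$se,
                           data.frame(ln_emax_barr = x))
  } else NULL

  cat_summary <- summarize_categories(profiles$overall_category)
  barr_gof <- if (!is.null(bias)) {
    bias$variant_id[bias$bias_class == "barr-biased"]
  } else character()
  carrier_summary <- if (length(barr_gof) > 0) {
    summarize_carriers(dataset$genotypes, barr_gof)
  } else NULL

  # named atomic vectors serialize to JSON as bare arrays; convert the named
  # summaries to lists so the report keeps their names
  cat_json <- cat_summary
  cat_json$counts <- as.list(cat_summary$counts)
  cat_json$percent <- as.list(cat_summary$percent)
  report <- list(seed = config$seed,
                 version = "1.0.0",
                 config = unclass(config),
                 category_summary = cat_json,
                 carrier_summary = carrier_summary,
                 pooled = pooled,
                 metareg = if (!is.null(metareg)) {
                   list(gamma = as.list(metareg$gamma),
                        se_gamma = as.list(metareg$se_gamma),
                        p_gamma = as.list(metareg$p_gamma),
                        tau2 = metareg$tau2, tau2_null = metareg$tau2_null,
                        r2_pct = metareg$r2_pct, k = metareg$k)
                 } else NULL,
                 phewas_threshold = 0.05 / 353)

  out <- list(config = config, dataset = dataset, profiles = profiles,
              bias = bias, associations = assoc, pooled = pooled,
              metareg = metareg, category_summary = cat_summary,
              carrier_summary = carrier_summary, report = report)
  class(out) <- "pipeline_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_dataset(dataset, out_dir)
    utils::write.table(profiles, file.path(out_dir, "variant_profiles.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(bias)) {
      utils::write.table(bias, file.path(out_dir, "bias_table.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(assoc, file.path(out_dir, "associations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cs <- x$category_summary
  cat(sprintf("Pipeline run (seed %d): %d variants, %d individuals\n",
              x$config$seed, x$config$n_variants, x$config$n_individuals))
  cat(sprintf("  categories: LoF %d (%d%%), GoF %d (%d%%), opposing %d (%d%%), WT-like %d (%d%%)\n",
              cs$counts[["LoF"]], cs$percent[["LoF"]],
              cs$counts[["GoF"]], cs$percent[["GoF"]],
              cs$counts[["opposing"]], cs$percent[["opposing"]],
              cs$counts[["WT-like"]], cs$percent[["WT-like"]]))
  cat(sprintf("  any functional consequence: %d%%\n", cs$pct_any_consequence))
  if (!is.null(x$metareg)) {
    cat(sprintf("  meta-regression: gamma1 = %.3f (p = %.2g), tau2 = %.4f, R2 = %.1f%%\n",
                x$metareg$gamma[2], x$metareg$p_gamma[2], x$metareg$tau2,
                x$metareg$r2_pct))
  }
  if (!is.null(x$carrier_summary)) {
    cc <- x$carrier_summary
    cat(sprintf("  barr-biased GoF carriers: %d one-copy (%.1f%%), %d two-copy (%.1f%%)\n",
                cc$n_1copy, cc$pct_1copy, cc$n_2copy, cc$pct_2copy))
  }
  invisible(x)
}
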