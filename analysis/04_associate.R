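#!/usr/bin/env Rscript
# Stage 4: genetic association analyses.
#
# Per-variant linear association of BMI with allele count (adjusted for age,
# sex, genotyping array), fixed-effect inverse-variance pooling within GoF
# and LoF categories, carrier-group contrasts for the beta-arrestin-biased
# GoF allele set, BMI-threshold obesity case-control analyses, and a small
# phenome-style scan with Bonferroni control over the outcomes tested.

library(mc4rbias)

data_dir <- "scratch/synthetic"
res_dir <- "results"

geno_df <- read.delim(file.path(data_dir, "genotypes.tsv"))
genotypes <- as.matrix(geno_df[, -1])
pheno <- read.delim(file.path(data_dir, "phenotypes.tsv"))
profiles <- read.delim(file.path(res_dir, "variant_profiles.tsv"))
bias <- read.delim(file.path(res_dir, "bias_table.tsv"))
covs <- pheno[, c("age", "sex", "array")]

## per-variant BMI associations
assoc <- per_variant_bmi_assoc(genotypes, pheno)
write.table(assoc, file.path(res_dir, "associations.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("%d of %d variants estimable (>= 2 carriers at this cohort size)\n",
            sum(assoc$estimable), nrow(assoc)))

## category-level pooling
merged <- merge(assoc[assoc$estimable, ],
                profiles[, c("variant_id", "overall_category")],
                by.x = "unit_id", by.y = "variant_id")
for (cat_lab in c("GoF", "LoF")) {
  d <- merged[merged$overall_category == cat_lab, ]
  if (nrow(d) == 0) next
  fe <- fixed_effect_meta(d$effect, d$se)
  cat(sprintf("%s pooled BMI effect: %.3f kg/m2 per allele (SE %.3f, p = %.2g, k = %d, P_het = %.2g)\n",
              cat_lab, fe$pooled_effect, fe$se, fe$p, fe$k,
              fe$p_heterogeneity))
}

## carrier groups for the beta-arrestin-biased GoF set
set_ids <- bias$variant_id[bias$bias_class == "barr-biased"]
if (length(set_ids) > 0) {
  cs <- summarize_carriers(genotypes, set_ids)
  cat(sprintf("barr-biased GoF carriers: %d one-copy (%.1f%%, 1 in %d), %d two-copy (%.1f%%)\n",
              cs$n_1copy, cs$pct_1copy, cs$one_in_n_1copy,
              cs$n_2copy, cs$pct_2copy))
  cg <- carrier_group_assoc(genotypes, set_ids, pheno$bmi, covs,
                            model = "linear", outcome = "bmi")
  print(cg, digits = 3)
  write.table(cg, file.path(res_dir, "carrier_associations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  one_copy <- cg[cg$unit_id == "carriers_1copy", ]
  if (!is.na(one_copy$effect)) {
    cat(sprintf("one-copy BMI difference of %.2f kg/m2 ~ %.1f kg body weight at 1.7 m\n",
                one_copy$effect, bmi_to_weight_delta(abs(one_copy$effect), 1.7)))
  }

  ## obesity case-control with BMI-threshold phenotypes
  flags <- derive_obesity_phenotypes(pheno$bmi)
  keep <- flags$obesity != "excluded"
  dose <- rowSums(genotypes[keep, set_ids, drop = FALSE])
  ob <- fit_logistic_assoc(as.integer(flags$obesity[keep] == "case"),
                           dose, covs[keep, ], unit_id = "carrier_dose",
                           outcome = "obesity")
  cat(sprintf("obesity OR per biased-GoF allele: %.3f (p = %.2g; %d cases)\n",
              exp(ob$effect), ob$p, ob$n_cases))
  if (one_copy$effect != 0) {
    sc <- scale_or_per_unit(ob$effect, one_copy$effect, ob$se)
    cat(sprintf("rescaled: OR %.3f per kg/m2 genetically lower BMI\n",
                sc$or_per_kgm2))
  }
}

## phenome-style scan over the binary outcomes
outcomes <- pheno[, c("t2d", "cad")]
scan <- phewas_scan(outcomes, rowSums(genotypes[, set_ids, drop = FALSE]),
                    covs, min_cases = 500, alpha = 0.05)
cat(sprintf("phenome scan: %d outcomes tested, threshold p < %.2g\n",
            scan$n_tested, scan$threshold))
write.table(scan$table, file.path(res_dir, "phewas.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
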