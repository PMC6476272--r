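#!/usr/bin/env Rscript
# Stage 5: random-effects meta-regression of per-variant BMI effects on the
# in-vitro functional moderators, with the sensitivity analyses.
#
# The primary model regresses each estimable missense variant's BMI
# association on ln(relative beta-arrestin E_max), with between-variant
# variance tau^2 estimated by REML; the headline quantity is the percent
# reduction in tau^2 when the moderator enters the model. Sensitivity
# analyses: cAMP moderator, multivariable (both moderators), leave-one-out,
# rare-only, and inclusion of truncating variants at a 1%-of-wild-type
# substitution.

library(mc4rbias)

res_dir <- "results"

profiles <- read.delim(file.path(res_dir, "variant_profiles.tsv"))
assoc <- read.delim(file.path(res_dir, "associations.tsv"))
truth <- read.delim(file.path(res_dir, "variant_truth.tsv"))

rows <- merge(assoc[assoc$estimable, c("unit_id", "effect", "se")],
              profiles, by.x = "unit_id", by.y = "variant_id")
rows <- merge(rows, truth[, c("variant_id", "allele_freq")],
              by.x = "unit_id", by.y = "variant_id")
missense <- rows[!rows$is_truncating & rows$emax_barr_pct > 0 &
                   rows$emax_camp_pct > 0, ]
cat(sprintf("meta-regression input: %d missense variants\n", nrow(missense)))

x_barr <- moderator_from_profile(missense$emax_barr_pct)
x_camp <- moderator_from_profile(missense$emax_camp_pct)

fit_barr <- random_effects_metareg(missense$effect, missense$se,
                                   data.frame(ln_emax_barr = x_barr))
cat("\n-- beta-arrestin moderator --\n")
print(fit_barr)

fit_camp <- random_effects_metareg(missense$effect, missense$se,
                                   data.frame(ln_emax_camp = x_camp))
cat("\n-- cAMP moderator --\n")
print(fit_camp)

fit_both <- random_effects_metareg(missense$effect, missense$se,
                                   data.frame(ln_emax_barr = x_barr,
                                              ln_emax_camp = x_camp))
cat("\n-- multivariable (both moderators) --\n")
print(fit_both)

## leave-one-out
loo <- leave_one_out_metareg(missense$effect, missense$se,
                             data.frame(ln_emax_barr = x_barr),
                             labels = missense$unit_id)
write.table(loo, file.path(res_dir, "metareg_leave_one_out.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("\nleave-one-out gamma1 range: %.3f to %.3f\n",
            min(loo$gamma1), max(loo$gamma1)))

## rare variants only (allele frequency < 0.5%)
rare <- filter_rows(missense[, c("unit_id", "effect", "se", "allele_freq")],
                    rare_only = TRUE)
fit_rare <- random_effects_metareg(rare$effect, rare$se,
                                   data.frame(x = x_barr[missense$unit_id %in%
                                                           rare$unit_id]))
cat(sprintf("rare-only (k = %d): gamma1 = %.3f, R2 = %.1f%%\n",
            fit_rare$k, fit_rare$gamma[2], fit_rare$r2_pct))

## all nonsynonymous variants, truncating substituted at 1% of wild type
all_rows <- rows[(rows$is_truncating | (rows$emax_barr_pct > 0)), ]
x_all <- moderator_from_profile(all_rows$emax_barr_pct,
                                is_truncating = all_rows$is_truncating,
                                truncating_substitution = 0.01)
fit_all <- random_effects_metareg(all_rows$effect, all_rows$se,
                                  data.frame(ln_emax_barr = x_all))
cat(sprintf("incl. truncating at 1%% WT (k = %d): gamma1 = %.3f, R2 = %.1f%%\n",
            fit_all$k, fit_all$gamma[2], fit_all$r2_pct))

out <- list(
  primary = list(moderator = "ln_emax_barr",
                 gamma = as.list(fit_barr$gamma),
                 se = as.list(fit_barr$se_gamma),
                 p = as.list(fit_barr$p_gamma),
                 tau2 = fit_barr$tau2, tau2_null = fit_barr$tau2_null,
                 r2_pct = fit_barr$r2_pct, k = fit_barr$k),
  camp = list(gamma1 = unname(fit_camp$gamma[2]),
              p = unname(fit_camp$p_gamma[2]), r2_pct = fit_camp$r2_pct),
  multivariable = list(gamma = as.list(fit_both$gamma),
                       p = as.list(fit_both$p_gamma)),
  rare_only = list(k = fit_rare$k, gamma1 = unname(fit_rare$gamma[2]),
                   r2_pct = fit_rare$r2_pct),
  with_truncating = list(k = fit_all$k, gamma1 = unname(fit_all$gamma[2]),
                         r2_pct = fit_all$r2_pct)
)
jsonlite::write_json(out, file.path(res_dir, "metareg.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("wrote results/metareg.json\n")
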