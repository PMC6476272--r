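#!/usr/bin/env Rscript
# Stage 2: quantify the assay plates.
#
# Each well's trace is reduced to a baseline-corrected AUC, normalized within
# its own replicate plate (mock = 0%, wild type = 100%), tested against the
# wild-type level with a single-sample t test per pathway, and the two
# pathway calls are combined into LoF / WT-like / GoF / opposing categories.
# Truncating (nonsense/frameshift) variants are LoF by rule.

library(mc4rbias)

data_dir <- "scratch/synthetic"
res_dir <- "results"

traces <- read.csv(file.path(data_dir, "assay_traces.csv"))
truth <- read.delim(file.path(res_dir, "variant_truth.tsv"))

profiles <- quantify_traces(traces, baseline_end = 600, alpha = 0.05,
                            truncating_ids = truth$variant_id[truth$is_truncating])
write.table(profiles, file.path(res_dir, "variant_profiles.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

norm <- normalized_activities(traces, baseline_end = 600)
write.table(norm, file.path(data_dir, "normalized_activities.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

s <- summarize_categories(profiles$overall_category)
cat(sprintf("of %d variants: %d LoF (%d%%), %d GoF (%d%%), %d opposing (%d%%), %d WT-like (%d%%)\n",
            s$total,
            s$counts[["LoF"]], s$percent[["LoF"]],
            s$counts[["GoF"]], s$percent[["GoF"]],
            s$counts[["opposing"]], s$percent[["opposing"]],
            s$counts[["WT-like"]], s$percent[["WT-like"]]))
cat(sprintf("variants with any functional consequence: %d%%\n",
            s$pct_any_consequence))
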