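#!/usr/bin/env Rscript
# Stage 3: signaling bias for gain-of-function variants.
#
# For every variant that is GoF in at least one pathway, the bias statistic
# is the ratio of geometric means of the per-experiment beta-arrestin and
# cAMP maximal activities, with an unpaired two-sample t test on the log
# scale against ratio = 1.

library(mc4rbias)

data_dir <- "scratch/synthetic"
res_dir <- "results"

profiles <- read.delim(file.path(res_dir, "variant_profiles.tsv"))
norm <- read.delim(file.path(data_dir, "normalized_activities.tsv"))

ids <- select_bias_analysis_set(profiles)
cat(sprintf("%d variants enter the bias analysis (GoF in >= 1 pathway)\n",
            length(ids)))

bias <- bias_table(norm, ids, alpha = 0.05)
write.table(bias, file.path(res_dir, "bias_table.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

for (cls in c("barr-biased", "cAMP-biased", "unbiased")) {
  v <- bias$variant_id[bias$bias_class == cls]
  cat(sprintf("%s: %s\n", cls, if (length(v)) paste(v, collapse = ", ") else "none"))
}
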