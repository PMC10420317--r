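#!/usr/bin/env Rscript
# Step 2: per-subject scoring — ceramide ratios, CERT1 subscores/total/
# category, HOMA-IR, metabolic-syndrome flags, Framingham risk and
# vascular age — against the cohort's own quartile reference.

suppressPackageStartupMessages(library(certscore))
cohort <- read_cohort_csv("results/cohort.csv")

frame <- build_analysis_frame(cohort)
mets <- classify_mets(cohort)
scores <- cbind(frame[, c("id", "group", paste0("s_", cert1_variables()),
                          "cert1", "category", "homa_ir", "frs", "va")],
                mets_count = mets$count, mets_positive = mets$positive)
write.csv(scores, "results/scores.csv", row.names = FALSE)

ref <- fit_quartile_reference(cohort)
write_quartile_reference(ref, "results/quartile_reference.csv")

cat("CERT1 by group (median [IQR]):\n")
for (g in unique(scores$group)) {
  s <- scores$cert1[scores$group == g]
  cat(sprintf("  %-12s %4.1f [%.1f; %.1f]\n", g, median(s),
              quantile(s, 0.25), quantile(s, 0.75)))
}
cat("\nRisk-category distribution:\n")
print(table(scores$group, scores$category))
cat("\nMetS-positive by design group (classifier vs label):\n")
print(table(scores$group, scores$mets_positive))
cat("\nWrote results/scores.csv and results/quartile_reference.csv\n")
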