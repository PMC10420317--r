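#!/usr/bin/env Rscript
# Step 3: Kruskal-Wallis + Dunn group comparisons for every cohort
# variable and for CERT1.

suppressPackageStartupMessages(library(certscore))
cohort <- read_cohort_csv("results/cohort.csv")
frame <- build_analysis_frame(cohort)

vars <- c("age", "bmi", "wc", "sbp", "dbp", "glucose", "insulin",
          "homa_ir", "tc", "hdl", "ldl", "tg", "crp",
          "cer16", "cer18", "cer241", "cer240",
          "r16_240", "r18_240", "r241_240", "frs", "va", "cert1")
tests <- lapply(vars, function(v) kruskal_dunn(frame, v))

omnibus <- do.call(rbind, lapply(tests, function(t)
  data.frame(variable = t$variable, H = t$statistic, df = t$df,
             p = t$p_value)))
pairwise <- do.call(rbind, lapply(tests, function(t)
  cbind(variable = t$variable, t$pairwise)))
write.csv(omnibus, "results/group_tests.csv", row.names = FALSE)
write.csv(pairwise, "results/group_tests_pairwise.csv", row.names = FALSE)

cat("Variables differing across groups (omnibus p < 0.05):\n")
print(omnibus$variable[omnibus$p < 0.05])
cat("\nCERT1 pairwise comparisons (Bonferroni-adjusted):\n")
print(tests[[which(vars == "cert1")]]$pairwise)
cat("\nWrote results/group_tests.csv and results/group_tests_pairwise.csv\n")
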