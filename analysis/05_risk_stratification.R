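#!/usr/bin/env Rscript
# Step 5: CERT1 against the Framingham outcomes (Spearman + linear fit)
# and the group-by-risk-category contingency analysis.

suppressPackageStartupMessages(library(certscore))
cohort <- read_cohort_csv("results/cohort.csv")
frame <- build_analysis_frame(cohort)

assoc <- list(frs = spearman_with_linfit(frame, "cert1", "frs"),
              va = spearman_with_linfit(frame, "cert1", "va"))
assoc_df <- do.call(rbind, lapply(assoc, function(a)
  data.frame(y = a$y, rho = a$rho, p = a$p_value,
             slope = a$slope, intercept = a$intercept, n = a$n)))
write.csv(assoc_df, "results/associations.csv", row.names = FALSE)

for (a in assoc) {
  cat(sprintf("CERT1 vs %-3s rho = %.4f (p = %.4f); %s = %.4f x CERT1 + %.2f\n",
              a$y, a$rho, a$p_value, toupper(a$y), a$slope, a$intercept))
}

ct <- risk_category_contingency(cohort, cert1_score(cohort))
tab <- as.data.frame.matrix(ct$table)
write.csv(cbind(group = rownames(tab), tab), "results/contingency.csv",
          row.names = FALSE)
cat(sprintf("\nGroup x risk-category: chi-square = %.3f, df = %d, p = %.2g\n",
            ct$statistic, ct$df, ct$p_value))
if (!is.na(ct$fisher_p)) {
  cat(sprintf("  (sparse table: Fisher exact p = %.2g)\n", ct$fisher_p))
}
print(ct$table)
cat("\nWrote results/associations.csv and results/contingency.csv\n")
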