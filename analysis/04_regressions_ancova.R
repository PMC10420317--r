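#!/usr/bin/env Rscript
# Step 4: multiple linear regressions of each ceramide endpoint (and
# CERT1) on the seven clinical surrogates, then the CERT1 rank-ANCOVA
# battery over the four covariate sets.

suppressPackageStartupMessages(library(certscore))
cohort <- read_cohort_csv("results/cohort.csv")
frame <- build_analysis_frame(cohort, risk_scores = FALSE)

outcomes <- c("cer16", "cer18", "cer241", "cer240",
              "r16_240", "r18_240", "r241_240", "cert1")
preds <- c("wc", "sbp", "dbp", "homa_ir", "hdl", "tg", "crp")

regs <- lapply(outcomes, function(o)
  ols_multiple_regression(frame, o, preds))
coefs <- do.call(rbind, lapply(regs, function(r)
  cbind(outcome = r$outcome, r$coefficients)))
write.csv(coefs, "results/regressions.csv", row.names = FALSE)

cat("Significant predictors (p < 0.05) per outcome:\n")
for (r in regs) {
  sig <- r$coefficients$term[r$coefficients$p < 0.05 &
                               r$coefficients$term != "(Intercept)"]
  cat(sprintf("  %-9s %s\n", r$outcome,
              if (length(sig)) paste(sig, collapse = ", ") else "(none)"))
}

sets <- list("wc", c("homa_ir", "crp"), c("wc", "homa_ir"), c("wc", "crp"))
anc <- lapply(sets, function(cv) rank_ancova(frame, "cert1", cv))
contr <- do.call(rbind, lapply(anc, function(a)
  cbind(covariates = paste(a$covariates, collapse = "+"), a$contrasts)))
write.csv(contr, "results/ancova.csv", row.names = FALSE)

cat("\nCERT1 group contrasts vs NW after covariate adjustment:\n")
print(contr[, c("covariates", "group", "p")])
cat("\nWrote results/regressions.csv and results/ancova.csv\n")
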