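#!/usr/bin/env Rscript
# Step 5: backward-AIC logistic selection for overall benefit.
#
# Confounders are eliminated one at a time while removal does not increase
# the AIC; TMB (pseudocounted, log scale) and min-PHBR are then added
# sequentially, recording the AIC at each addition and the AUROC of every
# model, to ask whether PHBR adds explanatory power once TMB is in the
# model.

suppressPackageStartupMessages(library(phbrtmb))

records <- utils::read.delim("results/patient_records.tsv",
                             stringsAsFactors = FALSE)
records <- records[records$benefit != "not_evaluable", ]
records$y <- as.integer(records$benefit == "benefit")
records$log_tmb <- log(add_pseudocount(records$tmb))
records$tumor_group <- factor(records$tumor_type)
records <- records[!is.na(records$log_tmb), ]

sel <- backward_aic_logistic(
  records, outcome = "y",
  candidates = c("sex", "ethnicity", "age_at_treatment", "tumor_group",
                 "therapy", "msi_status"),
  forced = c("log_tmb", "min_phbr"))

write_tsv(sel$trace, "results/analysis/model_selection_trace.tsv")
write_tsv(sel$coefficients, "results/analysis/model_selection_coefficients.tsv")
write_tsv(data.frame(model = names(sel$auroc), auroc = unname(sel$auroc)),
          "results/analysis/model_selection_auroc.tsv")

message(sprintf("confounders retained: %s",
                if (length(sel$retained)) paste(sel$retained, collapse = ", ")
                else "(none)"))
aic_add <- sel$trace[sel$trace$action == "add_forced", ]
for (i in seq_len(nrow(aic_add))) {
  message(sprintf("AIC after adding %s: %.1f", aic_add$term[i], aic_add$aic[i]))
}
message(sprintf("AUROC: %s",
                paste(sprintf("%s=%.2f", names(sel$auroc), sel$auroc),
                      collapse = ", ")))
if (sel$separation) message("note: separation detected in at least one fit")
message("model-selection tables written under results/analysis/")
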