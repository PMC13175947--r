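#!/usr/bin/env Rscript
# Stage 5: subgroup fairness audit of the simulated classifier for the
# any-injecting label: per-group metrics, parity ratios, 80%-rule flags,
# and the discordant-case export for manual error review.

suppressPackageStartupMessages(library(pwideval))

seed <- 20181231L
B <- 1000L
cohort <- read_cohort("results/cohort")

fa <- fairness_audit(cohort, n_iterations = B, seed = seed)
metrics <- do.call(rbind, lapply(names(fa), function(a) {
  cbind(attribute = a, fa[[a]]$metrics)
}))
parity <- do.call(rbind, lapply(names(fa), function(a) {
  cbind(attribute = a, as.data.frame(fa[[a]]$parity))
}))
write.csv(metrics, "results/fairness_metrics.csv", row.names = FALSE)
write.csv(parity, "results/fairness_parity.csv", row.names = FALSE)

message(sprintf("Age dichotomised at the cohort median (%.0f years).",
                attr(fa, "age_cut")))
flagged <- parity[parity$flag, ]
if (nrow(flagged) == 0L) {
  message("No metric fell below the 0.80 parity threshold.")
} else {
  for (i in seq_len(nrow(flagged))) {
    message(sprintf("80%% rule flag: %s / %s ratio %.3f (min %s, max %s)",
                    flagged$attribute[i], flagged$metric[i], flagged$ratio[i],
                    flagged$min_group[i], flagged$max_group[i]))
  }
}

gold <- cohort_labels(cohort, "gold")
pred <- cohort_labels(cohort, "pred")
errors <- export_error_cases(gold, pred, cohort[, c("admission_id", "note_text")])
write.csv(errors, "results/error_cases.csv", row.names = FALSE)
message(sprintf("Exported %d discordant (admission, label) cases for review (%d FP, %d FN).",
                nrow(errors), sum(errors$error_type == "false_positive"),
                sum(errors$error_type == "false_negative")))
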