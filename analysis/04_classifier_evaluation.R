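#!/usr/bin/env Rscript
# Stage 4: per-label diagnostic metrics for the simulated text classifier,
# plus model comparison (simulated model vs keyword baseline) by
# prevalence-weighted average F1.

suppressPackageStartupMessages(library(pwideval))

seed <- 20181231L
B <- 1000L
cohort <- read_cohort("results/cohort")
gold <- cohort_labels(cohort, "gold")
pred_sim <- cohort_labels(cohort, "pred")
pred_kw <- classify_cohort(cohort)

em <- evaluate_labels(gold, pred_sim, n_iterations = B, seed = seed)
em$cell <- format_est_ci(em$estimate, em$ci_low, em$ci_high)
wide <- reshape(em[, c("label", "metric", "cell")], idvar = "label",
                timevar = "metric", direction = "wide")
names(wide) <- sub("^cell\\.", "", names(wide))
write.csv(wide, "results/label_metrics.csv", row.names = FALSE)

comparison <- compare_models(gold,
                             list(simulated = pred_sim, keyword = pred_kw),
                             n_iterations = B, seed = seed)
write.csv(comparison, "results/model_comparison.csv", row.names = FALSE)

idu <- em[em$label == "idu_any" & em$metric %in% c("sensitivity", "specificity", "f1"), ]
for (i in seq_len(nrow(idu))) {
  message(sprintf("Any injecting drug use %s: %s", idu$metric[i], idu$cell[i]))
}
message(sprintf("Prevalence-weighted average F1: %s %.3f (%.3f, %.3f) vs %s %.3f.",
                comparison$model[1], comparison$weighted_f1[1],
                comparison$ci_low[1], comparison$ci_high[1],
                comparison$model[2], comparison$weighted_f1[2]))
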