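#!/usr/bin/env Rscript
# Stage 1: generate the default synthetic admission cohort (n = 859,
# configured PWID prevalence 17.1%) and write it, plus the baseline
# characteristics table, under results/.

suppressPackageStartupMessages(library(pwideval))

seed <- 20181231L
out_dir <- "results"
cohort_dir <- file.path(out_dir, "cohort")
dir.create(out_dir, showWarnings = FALSE)

cfg <- cohort_config(seed = seed)
cohort <- generate_cohort(cfg)
write_cohort(cohort, cohort_dir)

n_pwid <- sum(cohort$gold_idu_any)
wc <- lengths(strsplit(cohort$note_text, "[ ]+"))
message(sprintf("Generated %d admissions; %d (%.1f%%) PWID by gold standard.",
                nrow(cohort), n_pwid, 100 * n_pwid / nrow(cohort)))
message(sprintf("Note length: mean %.0f words (SD %.0f); PWID %.0f vs non-PWID %.0f.",
                mean(wc), sd(wc), mean(wc[cohort$gold_idu_any]),
                mean(wc[!cohort$gold_idu_any])))

summary_tab <- summarize_cohort(cohort)
write.csv(summary_tab, file.path(out_dir, "cohort_summary.csv"),
          row.names = FALSE)
message("Wrote ", cohort_dir, "/ and ", out_dir, "/cohort_summary.csv")
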