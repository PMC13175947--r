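# Shared fixtures: confusion tables reconstructed from the published group
# sizes, sensitivities and predictive values of the emulated study, plus
# cached synthetic cohorts (built once per test run).

# ICD proxy rules (cohort n = 859, 149 gold-positive)
recon_icd <- list(
  hepc_and_sud = confusion_counts(tp = 47, fp = 22, fn = 102, tn = 688),
  hiv_and_sud  = confusion_counts(tp = 0, fp = 0, fn = 149, tn = 710),
  any3_of_5    = confusion_counts(tp = 16, fp = 8, fn = 133, tn = 702),
  any4_of_5    = confusion_counts(tp = 1, fp = 0, fn = 148, tn = 710)
)

# best text model, any injecting drug use
recon_llm_idu <- confusion_counts(tp = 122, fp = 1, fn = 27, tn = 709)

# fairness subgroups for the same model/label
recon_groups <- list(
  age_lt52   = confusion_counts(tp = 107, fp = 1, fn = 14, tn = 321),
  age_ge52   = confusion_counts(tp = 15, fp = 0, fn = 13, tn = 388),
  female     = confusion_counts(tp = 41, fp = 0, fn = 7, tn = 225),
  male       = confusion_counts(tp = 81, fp = 1, fn = 20, tn = 484),
  aboriginal = confusion_counts(tp = 31, fp = 1, fn = 4, tn = 40),
  non_indig  = confusion_counts(tp = 91, fp = 0, fn = 23, tn = 665)
)

# expand a confusion table back into aligned gold/pred vectors
ct_vectors <- function(ct) {
  list(
    gold = rep(c(TRUE, TRUE, FALSE, FALSE), c(ct$tp, ct$fn, ct$fp, ct$tn)),
    pred = rep(c(TRUE, FALSE, TRUE, FALSE), c(ct$tp, ct$fn, ct$fp, ct$tn))
  )
}

zero_distractors <- c(negated_idu = 0, third_party = 0, prescribed_opioid = 0,
                      prescribed_benzo = 0, hepc_mention = 0)

# cohorts are expensive to build; cache them across test files
.fixture_env <- new.env(parent = emptyenv())
cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# default study-scale cohort, metadata/labels/codes only
study_cohort_nonotes <- function() {
  cached("study_nonotes", function() {
    generate_cohort(cohort_config(seed = 20181231L, render_notes = FALSE))
  })
}

# large cohort for binomial-convergence checks
big_cohort <- function() {
  cached("big", function() {
    generate_cohort(cohort_config(n_admissions = 5000L, seed = 314L,
                                  render_notes = FALSE))
  })
}

# small cohort with notes, default distractors
noted_cohort <- function() {
  cached("noted", function() {
    generate_cohort(cohort_config(n_admissions = 150L, seed = 77L))
  })
}

# small cohort with notes and distractors disabled (exact round-trip regime)
clean_note_cohort <- function() {
  cached("clean_notes", function() {
    generate_cohort(cohort_config(n_admissions = 150L, seed = 88L,
                                  distractor_rates = zero_distractors))
  })
}
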