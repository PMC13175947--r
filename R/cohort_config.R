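#' Default conditional label prevalences
#'
#' Per-label Bernoulli probabilities conditional on PWID status, matching the
#' gold-standard frequencies of the emulated cohort (149 PWID / 710 non-PWID):
#' heroin 36/149 among PWID and absent among non-PWID, methamphetamine 47/149
#' vs 14/710, methadone 60/149 vs 28/710, and so on. `idu_any` is fixed at
#' 1 (PWID) / 0 (non-PWID): the PWID flag *is* the any-injecting gold label.
#' Injection recency within PWID (current 98/149, historical 28/149) is
#' backed out of the recency confusion tables of the emulated study.
#'
#' @return List with elements `pwid` and `non_pwid`, each a named numeric
#'   vector over [pwid_labels()].
#' @export
default_label_prevalences <- function() {
  list(
    pwid = c(
      idu_any = 1, idu_current = 98 / 149, idu_historical = 28 / 149,
      heroin = 36 / 149, prescription_opioids = 13 / 149, fentanyl = 3 / 149,
      methamphetamine = 47 / 149, cocaine = 3 / 149, cannabis = 14 / 149,
      benzodiazepine = 0.10, methadone = 60 / 149, buprenorphine = 13 / 149
    ),
    non_pwid = c(
      idu_any = 0, idu_current = 0, idu_historical = 0,
      heroin = 0, prescription_opioids = 1 / 710, fentanyl = 0,
      methamphetamine = 14 / 710, cocaine = 0, cannabis = 4 / 710,
      benzodiazepine = 0.0085, methadone = 28 / 710, buprenorphine = 2 / 710
    )
  )
}

#' Default demographic model
#'
#' Age is log-normal by PWID status tuned to medians 45 (PWID) and 54
#' (non-PWID) with spread matched to the reported interquartile ranges.
#' Length of stay is 1 + negative binomial, tuned to median (IQR) 6 (3, 13)
#' days for PWID and 4 (2, 8) for non-PWID. Sex, Indigenous status and
#' discharge status are categorical draws at the emulated cohort frequencies
#' (e.g. patient-directed discharge 22% among PWID vs 4.6%).
#'
#' @return Nested list of distribution parameters keyed by PWID status.
#' @export
default_demographics <- function() {
  list(
    male_prop = c(pwid = 101 / 149, non_pwid = 485 / 710),
    indigenous_probs = list(
      pwid = c("Aboriginal and/or Torres Strait Islander" = 35 / 149,
               "Non-Indigenous" = 114 / 149,
               "Unknown" = 0),
      non_pwid = c("Aboriginal and/or Torres Strait Islander" = 41 / 710,
                   "Non-Indigenous" = 665 / 710,
                   "Unknown" = 4 / 710)
    ),
    age = list(pwid = c(meanlog = log(45), sdlog = 0.244),
               non_pwid = c(meanlog = log(54), sdlog = 0.412)),
    length_of_stay = list(pwid = c(size = 0.8, mu = 8.5),
                          non_pwid = c(size = 0.9, mu = 5.0)),
    discharge_probs = list(
      pwid = c(home = 103 / 149, transfer = 13 / 149,
               "patient-directed" = 33 / 149, death = 0),
      non_pwid = c(home = 607 / 710, transfer = 68 / 710,
                   "patient-directed" = 33 / 710, death = 3 / 710)
    )
  )
}

#' Default note-length model
#'
#' Word counts are log-normal by PWID status with means 350 (PWID) and 290
#' (non-PWID) words; the common log-scale SD 0.56 reproduces the overall
#' mean 300 / SD 182 of the emulated corpus. Counts are truncated below at
#' 20 words.
#'
#' @return List with `pwid` and `non_pwid` log-normal parameters and
#'   `min_words`.
#' @export
default_note_length <- function() {
  sdlog <- 0.56
  list(pwid = c(meanlog = log(350) - sdlog^2 / 2, sdlog = sdlog),
       non_pwid = c(meanlog = log(290) - sdlog^2 / 2, sdlog = sdlog),
       min_words = 20)
}

#' Default ICD coding model
#'
#' Per-code-group emission probabilities: `sensitivity` is the probability a
#' code from the group is recorded when the group's triggering gold condition
#' holds; `fp_rate` is the probability of a spurious code otherwise. Defaults
#' emulate administrative coding that is highly specific but insensitive for
#' injecting drug use: the implied hepatitis-C-and-SUD composite has joint
#' sensitivity 0.60 x 0.525 = 0.315 and joint false-positive rate
#' 0.25 x 0.124 = 0.031.
#'
#' @return List with named numeric vectors `sensitivity` and `fp_rate` over
#'   the five code groups.
#' @export
default_icd_model <- function() {
  list(
    sensitivity = c(hiv = 0.007, hepatitis_c = 0.60, substance_related = 0.30,
                    sud = 0.525, homelessness = 0.25),
    fp_rate = c(hiv = 0.0014, hepatitis_c = 0.25, substance_related = 0.010,
                sud = 0.124, homelessness = 0.030)
  )
}

#' Default simulated-classifier error model
#'
#' Per-label sensitivity and specificity of the simulated text classifier,
#' set to the operating characteristics of the best-performing model in the
#' emulated study (e.g. any injecting: sensitivity 0.819, specificity 0.999).
#' Cocaine and fentanyl rates are not reported there (too few cases); the
#' package uses sensitivity 0.667 and specificity 0.999 for them.
#'
#' @return List with named numeric vectors `sensitivity` and `specificity`
#'   over [pwid_labels()].
#' @export
default_prediction_error <- function() {
  list(
    sensitivity = c(
      idu_any = 0.819, idu_current = 0.939, idu_historical = 0.929,
      heroin = 0.973, prescription_opioids = 0.786, fentanyl = 0.667,
      methamphetamine = 0.984, cocaine = 0.667, cannabis = 1.000,
      benzodiazepine = 0.952, methadone = 1.000, buprenorphine = 1.000
    ),
    specificity = c(
      idu_any = 0.999, idu_current = 0.905, idu_historical = 0.941,
      heroin = 0.999, prescription_opioids = 0.964, fentanyl = 0.999,
      methamphetamine = 1.000, cocaine = 0.999, cannabis = 0.999,
      benzodiazepine = 0.970, methadone = 0.991, buprenorphine = 0.993
    )
  )
}

#' Default distractor rates for note rendering
#'
#' Rates at which confusable documentation phenomena are injected into notes
#' where they do not assert a gold label: explicit negation of injecting,
#' third-party substance use, prescribed-context opioid/benzodiazepine
#' mentions, and hepatitis-C serology lines. Set all to 0 for notes whose
#' text is exactly recoverable by the keyword reference classifier.
#'
#' @return Named numeric vector of per-note injection probabilities.
#' @export
default_distractor_rates <- function() {
  c(negated_idu = 0.20, third_party = 0.10,
    prescribed_opioid = 0.15, prescribed_benzo = 0.12, hepc_mention = 0.15)
}

#' Build a cohort configuration
#'
#' Assembles and validates the full parameter set of the synthetic-cohort
#' generator. All defaults emulate the study conditions of the reference
#' cohort: 859 admissions, 17.1% PWID prevalence, the conditional label
#' prevalences of [default_label_prevalences()], and the coding/classifier
#' error models above.
#'
#' @param n_admissions Positive integer, number of admissions to generate.
#' @param pwid_prevalence Proportion in \[0, 1\].
#' @param label_prevalences See [default_label_prevalences()].
#' @param demographics See [default_demographics()].
#' @param note_length See [default_note_length()].
#' @param icd_model See [default_icd_model()].
#' @param prediction_error See [default_prediction_error()].
#' @param distractor_rates See [default_distractor_rates()].
#' @param phi Logical; embed synthetic PHI (names, dates, MRN, IHI, phone,
#'   address) in notes and record their spans.
#' @param render_notes Logical; set `FALSE` to skip note text generation
#'   (metadata/labels/codes only), useful for large statistical checks.
#' @param seed Integer seed; all randomness in [generate_cohort()] derives
#'   from it via per-record substreams.
#' @return Object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_admissions = 859L,
                          pwid_prevalence = 0.171,
                          label_prevalences = default_label_prevalences(),
                          demographics = default_demographics(),
                          note_length = default_note_length(),
                          icd_model = default_icd_model(),
                          prediction_error = default_prediction_error(),
                          distractor_rates = default_distractor_rates(),
                          phi = TRUE,
                          render_notes = TRUE,
                          seed = 1L) {
  n_admissions <- as.integer(n_admissions)
  if (is.na(n_admissions) || n_admissions < 1L) {
    stop("n_admissions must be a positive integer")
  }
  check_prop <- function(x, what) {
    if (any(is.na(x)) || any(x < 0) || any(x > 1)) {
      stop(what, " must be proportions in [0, 1]")
    }
  }
  check_prop(pwid_prevalence, "pwid_prevalence")
  for (arm in c("pwid", "non_pwid")) {
    p <- label_prevalences[[arm]]
    missing <- setdiff(pwid_labels(), names(p))
    if (length(missing) > 0L) {
      stop("label_prevalences$", arm, " missing labels: ",
           paste(missing, collapse = ", "))
    }
    check_prop(p, paste0("label_prevalences$", arm))
  }
  check_prop(icd_model$sensitivity, "icd_model$sensitivity")
  check_prop(icd_model$fp_rate, "icd_model$fp_rate")
  for (field in c("sensitivity", "specificity")) {
    p <- prediction_error[[field]]
    missing <- setdiff(pwid_labels(), names(p))
    if (length(missing) > 0L) {
      stop("prediction_error$", field, " missing labels: ",
           paste(missing, collapse = ", "))
    }
    check_prop(p, paste0("prediction_error$", field))
  }
  check_prop(distractor_rates, "distractor_rates")
  structure(
    list(n_admissions = n_admissions,
         pwid_prevalence = pwid_prevalence,
         label_prevalences = label_prevalences,
         demographics = demographics,
         note_length = note_length,
         icd_model = icd_model,
         prediction_error = prediction_error,
         distractor_rates = distractor_rates,
         phi = isTRUE(phi),
         render_notes = isTRUE(render_notes),
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}
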