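#' Sample gold labels conditional on PWID status
#'
#' Draws the twelve binary labels from the configured conditional prevalence
#' map. Substance and OAT labels are drawn independently given PWID status
#' (the joint distribution of substances within PWID is not identified by the
#' emulated study's marginal counts). `idu_any` is forced true whenever a
#' recency label is drawn true, preserving the schema invariant.
#'
#' @param is_pwid Logical scalar.
#' @param label_prevalences List with `pwid` and `non_pwid` prevalence maps.
#' @return Named logical vector over [pwid_labels()].
#' @export
sample_gold_labels <- function(is_pwid,
                               label_prevalences = default_label_prevalences()) {
  p <- if (isTRUE(is_pwid)) label_prevalences$pwid else label_prevalences$non_pwid
  missing <- setdiff(pwid_labels(), names(p))
  if (length(missing) > 0L) {
    stop("prevalence map missing labels: ", paste(missing, collapse = ", "))
  }
  p <- p[pwid_labels()]
  gold <- stats::runif(length(p)) < p
  names(gold) <- pwid_labels()
  if (gold[["idu_current"]] || gold[["idu_historical"]]) {
    gold[["idu_any"]] <- TRUE
  }
  gold
}

# Valid example codes per group; a draw from a group emits one of these.
# Child codes (with fourth characters) are included deliberately so that
# downstream prefix matching is exercised.
icd_group_codes <- function() {
  list(
    hiv = c("B21", "B22", "B23.8", "B24", "Z21"),
    hepatitis_c = c("B17.1", "B18.2", "Z22.52"),
    substance_related = c("Z72.2", "Z86.41", "T40.1", "T40.2", "T40.3",
                          "T40.4", "T40.5", "T43.6"),
    sud = c("F11.2", "F14.1", "F15.2", "F19.2"),
    homelessness = c("Z59.0")
  )
}

# Pick a code for an emitting group, preferring codes consistent with the
# gold substances (heroin/prescription opioids -> F11/T40.1-4, etc.).
pick_group_code <- function(group, gold) {
  codes <- icd_group_codes()[[group]]
  if (group == "sud") {
    cands <- character(0)
    if (gold[["heroin"]] || gold[["prescription_opioids"]]) cands <- c(cands, "F11.2")
    if (gold[["cocaine"]]) cands <- c(cands, "F14.1")
    if (gold[["methamphetamine"]]) cands <- c(cands, "F15.2")
    if (length(cands) == 0L) cands <- "F19.2"
    return(if (length(cands) > 1L) sample(cands, 1L) else cands)
  }
  if (group == "substance_related") {
    cands <- character(0)
    if (gold[["heroin"]]) cands <- c(cands, "T40.1")
    if (gold[["prescription_opioids"]]) cands <- c(cands, sample(c("T40.2", "T40.3", "T40.4"), 1L))
    if (gold[["cocaine"]]) cands <- c(cands, "T40.5")
    if (gold[["methamphetamine"]]) cands <- c(cands, "T43.6")
    if (length(cands) == 0L) cands <- sample(c("Z72.2", "Z86.41"), 1L)
    return(if (length(cands) > 1L) sample(cands, 1L) else cands)
  }
  if (length(codes) > 1L) sample(codes, 1L) else codes
}

#' Simulate administrative ICD coding for one admission
#'
#' For each code group whose triggering gold condition holds, a code from the
#' group is emitted with probability equal to the group's coding sensitivity;
#' otherwise a spurious code is emitted at the group's false-positive rate.
#' Triggers: hepatitis C, HIV and homelessness codes are triggered by PWID
#' status (`idu_any`); substance-use-disorder and substance-related codes by
#' any relevant substance label or `idu_any`. Emitted codes are syntactically
#' valid members of their group.
#'
#' @param gold Named logical vector over [pwid_labels()].
#' @param icd_model List with `sensitivity` and `fp_rate` per group, see
#'   [default_icd_model()].
#' @return Character vector of ICD-10-AM codes (possibly empty).
#' @export
assign_icd_codes <- function(gold, icd_model = default_icd_model()) {
  groups <- names(icd_group_codes())
  unknown <- setdiff(names(icd_model$sensitivity), groups)
  if (length(unknown) > 0L) {
    stop("unknown code group(s) in icd_model: ", paste(unknown, collapse = ", "))
  }
  substance_any <- gold[["heroin"]] || gold[["prescription_opioids"]] ||
    gold[["methamphetamine"]] || gold[["cocaine"]]
  triggers <- c(
    hiv = gold[["idu_any"]],
    hepatitis_c = gold[["idu_any"]],
    substance_related = substance_any || gold[["idu_any"]],
    sud = substance_any || gold[["idu_any"]],
    homelessness = gold[["idu_any"]]
  )
  codes <- character(0)
  for (g in groups) {
    p <- if (triggers[[g]]) icd_model$sensitivity[[g]] else icd_model$fp_rate[[g]]
    if (stats::runif(1) < p) codes <- c(codes, pick_group_code(g, gold))
  }
  codes
}

#' Simulate classifier predictions for one admission
#'
#' Each predicted label is drawn independently: true with probability equal
#' to the configured per-label sensitivity when the gold label is true, and
#' with probability 1 - specificity when it is false.
#'
#' @param gold Named logical vector over [pwid_labels()].
#' @param error_model List with `sensitivity` and `specificity` per label.
#' @return Named logical vector of predicted labels.
#' @export
simulate_predictions <- function(gold, error_model = default_prediction_error()) {
  labs <- pwid_labels()
  sens <- error_model$sensitivity[labs]
  spec <- error_model$specificity[labs]
  if (anyNA(sens) || anyNA(spec)) stop("error model incomplete")
  p_true <- ifelse(gold[labs], sens, 1 - spec)
  pred <- stats::runif(length(labs)) < p_true
  names(pred) <- labs
  pred
}

# Deterministic per-record substream seed: a function of (seed, index) only,
# so record i is identical regardless of cohort size.
record_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 7919) %% 2147483629)
}

#' Generate a synthetic admission cohort
#'
#' Draws `n_admissions` records with the full structure of the emulated
#' study: PWID status, gold labels, demographics, note text with recorded
#' PHI spans, administrative ICD codes, and simulated classifier
#' predictions. Bit-reproducible for a fixed config seed; each record uses a
#' substream derived from (seed, record index), so individual records are
#' stable when `n_admissions` changes.
#'
#' @param config A [cohort_config()] object.
#' @return Data frame with one row per admission: `admission_id`, `is_pwid`,
#'   demographics, `note_text`, list-columns `phi_spans` and `icd_codes`,
#'   gold columns `gold_<label>` and prediction columns `pred_<label>`.
#'   The config is attached as attribute `"config"`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_admissions
  labs <- pwid_labels()
  bank <- note_template_bank()
  roster <- default_name_roster()
  demo <- config$demographics
  nl <- config$note_length

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(record_seed(config$seed, i))
    is_pwid <- stats::runif(1) < config$pwid_prevalence
    arm <- if (is_pwid) "pwid" else "non_pwid"
    gold <- sample_gold_labels(is_pwid, config$label_prevalences)

    age <- stats::rlnorm(1, demo$age[[arm]][["meanlog"]], demo$age[[arm]][["sdlog"]])
    sex <- if (stats::runif(1) < demo$male_prop[[arm]]) "male" else "female"
    ind <- sample(names(demo$indigenous_probs[[arm]]), 1L,
                  prob = demo$indigenous_probs[[arm]])
    los <- 1L + stats::rnbinom(1, size = demo$length_of_stay[[arm]][["size"]],
                               mu = demo$length_of_stay[[arm]][["mu"]])
    disch <- sample(names(demo$discharge_probs[[arm]]), 1L,
                    prob = demo$discharge_probs[[arm]])

    if (config$render_notes) {
      words <- max(round(stats::rlnorm(1, nl[[arm]][["meanlog"]],
                                       nl[[arm]][["sdlog"]])), nl$min_words)
      note <- render_note(gold, words, bank,
                          distractor_rates = config$distractor_rates,
                          phi = config$phi, name_roster = roster)
    } else {
      note <- list(note_text = "note rendering disabled",
                   phi_spans = data.frame(start = integer(0), end = integer(0),
                                          category = character(0)))
    }
    codes <- assign_icd_codes(gold, config$icd_model)
    pred <- simulate_predictions(gold, config$prediction_error)

    row <- data.frame(
      admission_id = sprintf("adm%05d", i),
      is_pwid = is_pwid,
      age = round(age, 1),
      sex = sex,
      indigenous_status = ind,
      length_of_stay = los,
      discharge_status = disch,
      note_text = note$note_text,
      stringsAsFactors = FALSE
    )
    row$phi_spans <- list(note$phi_spans)
    row$icd_codes <- list(codes)
    for (lab in labs) row[[paste0("gold_", lab)]] <- unname(gold[[lab]])
    for (lab in labs) row[[paste0("pred_", lab)]] <- unname(pred[[lab]])
    rows[[i]] <- row
  }
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  attr(cohort, "config") <- config
  cohort
}

#' Extract gold or prediction label matrix from a cohort
#'
#' @param cohort Data frame from [generate_cohort()].
#' @param which Either `"gold"` or `"pred"`.
#' @param labels Labels to extract (default all twelve).
#' @return Data frame with `admission_id` plus one logical column per label.
#' @export
cohort_labels <- function(cohort, which = c("gold", "pred"),
                          labels = pwid_labels()) {
  which <- match.arg(which)
  cols <- paste0(which, "_", labels)
  missing <- setdiff(cols, names(cohort))
  if (length(missing) > 0L) stop("cohort lacks columns: ", paste(missing, collapse = ", "))
  out <- cohort[, c("admission_id", cols)]
  names(out) <- c("admission_id", labels)
  out
}
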