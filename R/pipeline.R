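#' Build a run configuration
#'
#' Configuration for the end-to-end evaluation: either `synthetic` mode
#' (generate a cohort from `cohort_config`) or `external` mode (read a
#' previously serialised cohort directory).
#'
#' @param mode `"synthetic"` or `"external"`.
#' @param cohort_config A [cohort_config()] (synthetic mode).
#' @param input_dir Cohort directory (external mode).
#' @param out_dir Output directory for report artefacts.
#' @param labels Labels included in metric reports.
#' @param n_iterations Bootstrap replicates for all CIs.
#' @param seed Integer seed for evaluation-stage randomness (bootstrap).
#' @return Object of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "external"),
                       cohort_config = pwideval::cohort_config(),
                       input_dir = NULL,
                       out_dir = tempfile("pwideval-run-"),
                       labels = default_report_labels(),
                       n_iterations = 1000L,
                       seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "external" && is.null(input_dir)) {
    stop("external mode requires input_dir")
  }
  if (mode == "synthetic" && !inherits(cohort_config, "cohort_config")) {
    stop("synthetic mode requires a cohort_config")
  }
  structure(list(mode = mode, cohort_config = cohort_config,
                 input_dir = input_dir, out_dir = out_dir, labels = labels,
                 n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed)),
            class = "run_config")
}

# small stable FNV-1a hash of the deparsed config, for the report manifest;
# output paths are excluded so the hash reflects only scientific parameters
config_hash <- function(config) {
  keep <- unclass(config)[c("mode", "cohort_config", "labels",
                            "n_iterations", "seed")]
  bytes <- utf8ToInt(paste(deparse(keep), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

write_report_csv <- function(df, path, hash) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Summarise a cohort by PWID status
#'
#' Descriptive summary shaped like a baseline-characteristics table: counts
#' and percentages for categorical fields, median (IQR) for age and length
#' of stay, stratified by the gold PWID flag. Descriptive only; no
#' hypothesis tests.
#'
#' @param cohort Data frame from [generate_cohort()].
#' @return Data frame with columns `variable`, `level`, `non_pwid`, `pwid`.
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(nrow(cohort) >= 1L)
  pw <- cohort$gold_idu_any
  fmt_n_pct <- function(x, total) {
    sprintf("%d (%.1f%%)", x, if (total > 0) 100 * x / total else 0)
  }
  fmt_med_iqr <- function(v) {
    if (length(v) == 0L) return("NA")
    q <- stats::quantile(v, c(0.25, 0.5, 0.75))
    sprintf("%.0f (%.0f, %.0f)", q[2], q[1], q[3])
  }
  rows <- list()
  add <- function(variable, level, non_pwid, pwid) {
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, level = level, non_pwid = non_pwid, pwid = pwid,
      stringsAsFactors = FALSE)
  }
  add("n", "", as.character(sum(!pw)), as.character(sum(pw)))
  add("age", "median (IQR)", fmt_med_iqr(cohort$age[!pw]),
      fmt_med_iqr(cohort$age[pw]))
  add("length_of_stay", "median (IQR)",
      fmt_med_iqr(cohort$length_of_stay[!pw]),
      fmt_med_iqr(cohort$length_of_stay[pw]))
  for (var in c("sex", "indigenous_status", "discharge_status")) {
    for (lev in sort(unique(cohort[[var]]))) {
      add(var, lev,
          fmt_n_pct(sum(cohort[[var]][!pw] == lev), sum(!pw)),
          fmt_n_pct(sum(cohort[[var]][pw] == lev), sum(pw)))
    }
  }
  for (lab in c("heroin", "prescription_opioids", "fentanyl",
                "methamphetamine", "cocaine", "cannabis", "benzodiazepine",
                "methadone", "buprenorphine")) {
    col <- cohort[[paste0("gold_", lab)]]
    add("substance_or_oat", lab,
        fmt_n_pct(sum(col[!pw]), sum(!pw)), fmt_n_pct(sum(col[pw]), sum(pw)))
  }
  do.call(rbind, rows)
}

#' Export discordant cases for manual error review
#'
#' One row per (admission, label) where prediction and gold disagree, with
#' the error direction and a note excerpt. The `category` column is left as
#' `"uncategorised"` for manual tagging with one of: missed_documentation,
#' temporal_misclassification, contextual_misinterpretation,
#' annotation_error.
#'
#' @param gold,pred Data frames with `admission_id` and label columns.
#' @param notes Data frame with `admission_id` and `note_text`.
#' @param labels Labels to scan.
#' @param excerpt_chars Number of leading characters of the note to include.
#' @return Data frame: `admission_id`, `label`, `error_type`, `excerpt`,
#'   `category`.
#' @export
export_error_cases <- function(gold, pred, notes, labels = default_report_labels(),
                               excerpt_chars = 160L) {
  al <- align_predictions(gold, pred)
  out <- list()
  for (lab in labels) {
    g <- al$gold[[lab]]; p <- al$pred[[lab]]
    disc <- which(g != p)
    if (length(disc) == 0L) next
    ids <- al$gold$admission_id[disc]
    txt <- notes$note_text[match(ids, notes$admission_id)]
    out[[length(out) + 1L]] <- data.frame(
      admission_id = ids, label = lab,
      error_type = ifelse(p[disc], "false_positive", "false_negative"),
      excerpt = substr(txt, 1L, excerpt_chars),
      category = "uncategorised",
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L) {
    return(data.frame(admission_id = character(0), label = character(0),
                      error_type = character(0), excerpt = character(0),
                      category = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the end-to-end evaluation
#'
#' Orchestrates the full pipeline: obtain a cohort (generate or load),
#' de-identify and audit the notes, evaluate ICD proxy rules and substance
#' code flags against gold, evaluate the simulated classifier and keyword
#' baseline per label, compare models by prevalence-weighted F1, audit
#' fairness of the simulated classifier, and export discordant cases. All
#' artefacts are written as CSV (with a config-hash header comment) plus a
#' JSON manifest; identical config and seed give identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list of the report data frames; artefacts under
#'   `config$out_dir`.
#' @export
run_evaluation <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cohort <- switch(config$mode,
                   synthetic = generate_cohort(config$cohort_config),
                   external = read_cohort(config$input_dir))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  B <- config$n_iterations
  labels <- config$labels

  # 1. cohort summary
  summary_tab <- summarize_cohort(cohort)

  # 2. de-identification audit
  audit <- deid_audit(cohort)

  gold <- cohort_labels(cohort, "gold")
  pred_sim <- cohort_labels(cohort, "pred")
  notes <- cohort[, c("admission_id", "note_text")]

  # 3. ICD proxy rules and substance code flags vs gold
  rule_mat <- icd_rule_matrix(cohort)
  icd_targets <- c(stats::setNames(rep("idu_any", length(default_proxy_rules())),
                                   names(default_proxy_rules())),
                   stats::setNames(names(default_substance_code_map()),
                                   names(default_substance_code_map())))
  icd_rows <- list()
  idx <- bootstrap_indices(nrow(cohort), B, config$seed)
  for (rule in names(icd_targets)) {
    g <- gold[[icd_targets[[rule]]]]
    p <- rule_mat[[rule]]
    dm <- diagnostic_metrics(confusion_table(g, p))
    mets <- c("f1", "accuracy", "sensitivity", "specificity", "ppv", "npv")
    boots <- matrix(NA_real_, nrow = B, ncol = length(mets),
                    dimnames = list(NULL, mets))
    for (b in seq_len(B)) {
      bm <- diagnostic_metrics(confusion_table(g[idx[b, ]], p[idx[b, ]]))
      boots[b, ] <- unlist(bm[mets])
    }
    row <- data.frame(rule = rule, target = icd_targets[[rule]],
                      predicted = dm$n_predicted_positive,
                      n_gold = dm$n_positive_gold, stringsAsFactors = FALSE)
    for (m in mets) {
      def <- boots[, m][!is.na(boots[, m])]
      ci <- if (length(def)) unname(stats::quantile(def, c(0.025, 0.975))) else c(NA, NA)
      row[[m]] <- format_est_ci(dm[[m]], ci[1], ci[2])
    }
    icd_rows[[rule]] <- row
  }
  icd_tab <- do.call(rbind, icd_rows)
  rownames(icd_tab) <- NULL

  # 4. per-label classifier metrics (simulated model)
  label_long <- evaluate_labels(gold, pred_sim, labels = labels,
                                n_iterations = B, seed = config$seed)
  label_tab <- stats::reshape(
    transform(label_long, cell = format_est_ci(label_long$estimate,
                                               label_long$ci_low,
                                               label_long$ci_high))[
      , c("label", "metric", "cell")],
    idvar = "label", timevar = "metric", direction = "wide")
  names(label_tab) <- sub("^cell\\.", "", names(label_tab))
  rownames(label_tab) <- NULL

  # 5. model comparison: simulated model vs keyword baseline
  pred_kw <- classify_cohort(cohort)
  comparison <- compare_models(gold,
                               list(simulated = pred_sim, keyword = pred_kw),
                               labels = labels, n_iterations = B,
                               seed = config$seed)

  # 6. fairness audit of the simulated classifier on any injecting
  fair <- fairness_audit(cohort, n_iterations = B, seed = config$seed)
  fair_metrics <- do.call(rbind, lapply(names(fair), function(a) {
    cbind(attribute = a, fair[[a]]$metrics)
  }))
  fair_parity <- do.call(rbind, lapply(names(fair), function(a) {
    cbind(attribute = a, as.data.frame(fair[[a]]$parity))
  }))

  # 7. discordant-case export
  errors <- export_error_cases(gold, pred_sim, notes, labels = labels)

  write_report_csv(summary_tab, file.path(config$out_dir, "cohort_summary.csv"), hash)
  write_report_csv(audit, file.path(config$out_dir, "deid_audit.csv"), hash)
  write_report_csv(icd_tab, file.path(config$out_dir, "icd_rule_metrics.csv"), hash)
  write_report_csv(label_tab, file.path(config$out_dir, "label_metrics.csv"), hash)
  write_report_csv(comparison, file.path(config$out_dir, "model_comparison.csv"), hash)
  write_report_csv(fair_metrics, file.path(config$out_dir, "fairness_metrics.csv"), hash)
  write_report_csv(fair_parity, file.path(config$out_dir, "fairness_parity.csv"), hash)
  write_report_csv(errors, file.path(config$out_dir, "error_cases.csv"), hash)
  manifest <- list(config_hash = hash, seed = config$seed, mode = config$mode,
                   n_iterations = B, labels = labels,
                   package_version = as.character(utils::packageVersion("pwideval")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(cohort_summary = summary_tab, deid_audit = audit,
                 icd_rule_metrics = icd_tab, label_metrics = label_tab,
                 model_comparison = comparison, fairness_metrics = fair_metrics,
                 fairness_parity = fair_parity, error_cases = errors))
}
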