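#' Write a cohort to plain-text files
#'
#' Serialises a cohort into the package's external interchange formats:
#' `notes.jsonl` (admission_id, text), `gold.csv` (one boolean column per
#' label), `metadata.csv`, `icd_long.csv` (admission_id, code; one row per
#' code), `phi_spans.csv` and `predictions.csv` (simulated model).
#'
#' @param cohort Data frame from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param model_name Model name recorded in `predictions.csv`.
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir, model_name = "simulated") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  notes <- vapply(seq_len(nrow(cohort)), function(i) {
    jsonlite::toJSON(list(admission_id = cohort$admission_id[i],
                          text = cohort$note_text[i]),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(notes, file.path(dir, "notes.jsonl"))

  gold <- cohort_labels(cohort, "gold")
  for (lab in pwid_labels()) gold[[lab]] <- ifelse(gold[[lab]], "true", "false")
  utils::write.csv(gold, file.path(dir, "gold.csv"), row.names = FALSE)

  meta <- cohort[, c("admission_id", "is_pwid", "age", "sex",
                     "indigenous_status", "length_of_stay",
                     "discharge_status")]
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)

  icd <- do.call(rbind, lapply(seq_len(nrow(cohort)), function(i) {
    codes <- cohort$icd_codes[[i]]
    if (length(codes) == 0L) return(NULL)
    data.frame(admission_id = cohort$admission_id[i], code = codes,
               stringsAsFactors = FALSE)
  }))
  if (is.null(icd)) {
    icd <- data.frame(admission_id = character(0), code = character(0))
  }
  utils::write.csv(icd, file.path(dir, "icd_long.csv"), row.names = FALSE)

  phi <- do.call(rbind, lapply(seq_len(nrow(cohort)), function(i) {
    sp <- cohort$phi_spans[[i]]
    if (nrow(sp) == 0L) return(NULL)
    cbind(data.frame(admission_id = cohort$admission_id[i],
                     stringsAsFactors = FALSE), sp)
  }))
  if (is.null(phi)) {
    phi <- data.frame(admission_id = character(0), start = integer(0),
                      end = integer(0), category = character(0))
  }
  utils::write.csv(phi, file.path(dir, "phi_spans.csv"), row.names = FALSE)

  pred <- cohort_labels(cohort, "pred")
  pred <- cbind(pred[, "admission_id", drop = FALSE],
                model_name = model_name,
                pred[, pwid_labels(), drop = FALSE])
  write_predictions(pred, file.path(dir, "predictions.csv"))
  invisible(dir)
}

#' Read a cohort from plain-text files
#'
#' Inverse of [write_cohort()]: reconstitutes the cohort data frame
#' (metadata, notes, gold labels, ICD codes, PHI spans and predictions)
#' from a directory of interchange files.
#'
#' @param dir Directory written by [write_cohort()] (or user-supplied files
#'   of the same shapes).
#' @return Cohort data frame in the layout of [generate_cohort()].
#' @export
read_cohort <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "metadata.csv"),
                          stringsAsFactors = FALSE)
  lines <- readLines(file.path(dir, "notes.jsonl"), warn = FALSE)
  notes <- do.call(rbind, lapply(lines[nzchar(lines)], function(l) {
    obj <- jsonlite::fromJSON(l)
    data.frame(admission_id = obj$admission_id, note_text = obj$text,
               stringsAsFactors = FALSE)
  }))
  gold <- utils::read.csv(file.path(dir, "gold.csv"), stringsAsFactors = FALSE,
                          colClasses = "character")
  icd <- utils::read.csv(file.path(dir, "icd_long.csv"),
                         stringsAsFactors = FALSE)
  phi <- utils::read.csv(file.path(dir, "phi_spans.csv"),
                         stringsAsFactors = FALSE)
  pred <- load_predictions(file.path(dir, "predictions.csv"))

  cohort <- merge(meta, notes, by = "admission_id", sort = FALSE)
  cohort <- cohort[order(cohort$admission_id), ]
  cohort$phi_spans <- lapply(cohort$admission_id, function(id) {
    sp <- phi[phi$admission_id == id, c("start", "end", "category")]
    rownames(sp) <- NULL
    sp
  })
  cohort$icd_codes <- lapply(cohort$admission_id, function(id) {
    icd$code[icd$admission_id == id]
  })
  for (lab in pwid_labels()) {
    g <- gold[[lab]][match(cohort$admission_id, gold$admission_id)]
    cohort[[paste0("gold_", lab)]] <- parse_strict_bool(g, lab, "gold.csv")
    p <- pred[[lab]][match(cohort$admission_id, pred$admission_id)]
    cohort[[paste0("pred_", lab)]] <- p
  }
  rownames(cohort) <- NULL
  cohort
}
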