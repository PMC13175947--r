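#' Default keyword classifier lexicons
#'
#' Editable lexicons for the deterministic keyword/negation reference
#' classifier: injection terms, per-substance terms, negation cues, temporal
#' (historical) cues, unclear-recency cues and prescribed-context cues.
#' Multi-word terms are collapsed to single tokens internally ("track marks"
#' -> "trackmarks").
#'
#' @return Named list of character vectors.
#' @export
default_lexicons <- function() {
  list(
    injection = c("inject", "injects", "injected", "injecting", "ivdu",
                  "pwid", "trackmarks", "hitsup"),
    heroin = "heroin",
    prescription_opioids = c("oxycodone", "morphine", "endone"),
    fentanyl = "fentanyl",
    methamphetamine = c("methamphetamine", "amphetamine"),
    cocaine = "cocaine",
    cannabis = c("cannabis", "marijuana", "thc"),
    benzodiazepine = c("benzodiazepine", "benzodiazepines", "diazepam",
                       "alprazolam"),
    methadone = "methadone",
    buprenorphine = c("buprenorphine", "suboxone"),
    negation = c("denies", "denied", "no", "not", "without", "nil", "never"),
    temporal_historical = c("former", "previous", "previously", "history",
                            "historical", "past", "remote", "ex"),
    recency_unclear = c("unclear", "unknown", "unspecified"),
    prescribed_context = c("prescribed", "charted", "chart", "pain",
                           "regular", "management", "protocol")
  )
}

# phrase -> token collapsing applied before tokenisation
collapse_phrases <- function(text) {
  text <- gsub("track marks", "trackmarks", text, fixed = TRUE)
  gsub("hits up", "hitsup", text, fixed = TRUE)
}

#' Deterministic keyword/negation reference classifier
#'
#' A transparent rule-based classifier standing in for external text models
#' behind the same prediction interface. A lexicon hit is suppressed when a
#' negation cue occurs within `negation_window` tokens before it. Injection
#' hits carry recency context: a historical cue within the window marks
#' `idu_historical`; a hit with neither a historical nor an unclear-recency
#' cue marks `idu_current`. Prescription-opioid and benzodiazepine hits are
#' suppressed when a prescribed-context cue occurs within the window, so
#' charted analgesia does not count as misuse. Pure: same text, same labels.
#'
#' @param note_text Character scalar (de-identified text).
#' @param lexicons See [default_lexicons()].
#' @param negation_window Integer token window (default 5).
#' @return Named logical vector over [pwid_labels()].
#' @export
keyword_rule_classifier <- function(note_text,
                                    lexicons = default_lexicons(),
                                    negation_window = 5L) {
  stopifnot(is.character(note_text), length(note_text) == 1L)
  tokens <- strsplit(gsub("[^a-z0-9]+", " ", collapse_phrases(tolower(note_text))),
                     " ", fixed = TRUE)[[1]]
  tokens <- tokens[nzchar(tokens)]
  n <- length(tokens)
  w <- as.integer(negation_window)

  hit_info <- function(terms) {
    idx <- which(tokens %in% terms)
    if (length(idx) == 0L) {
      return(data.frame(negated = logical(0), historical = logical(0),
                        unclear = logical(0), prescribed = logical(0)))
    }
    do.call(rbind, lapply(idx, function(i) {
      before <- tokens[seq(max(1L, i - w), max(0L, i - 1L))]
      around <- tokens[seq(max(1L, i - w), min(n, i + w))]
      data.frame(
        negated = any(before %in% lexicons$negation),
        historical = any(around %in% lexicons$temporal_historical),
        unclear = any(around %in% lexicons$recency_unclear),
        prescribed = any(around %in% lexicons$prescribed_context)
      )
    }))
  }

  out <- stats::setNames(rep(FALSE, length(pwid_labels())), pwid_labels())

  inj <- hit_info(lexicons$injection)
  live <- inj[!inj$negated, , drop = FALSE]
  if (nrow(live) > 0L) {
    out[["idu_any"]] <- TRUE
    out[["idu_historical"]] <- any(live$historical)
    out[["idu_current"]] <- any(!live$historical & !live$unclear)
  }

  plain <- c("heroin", "fentanyl", "methamphetamine", "cocaine", "cannabis",
             "methadone", "buprenorphine")
  for (lab in plain) {
    h <- hit_info(lexicons[[lab]])
    out[[lab]] <- any(!h$negated)
  }
  for (lab in c("prescription_opioids", "benzodiazepine")) {
    h <- hit_info(lexicons[[lab]])
    out[[lab]] <- any(!h$negated & !h$prescribed)
  }
  out
}

#' Classify every note in a cohort with the keyword model
#'
#' @param cohort Data frame with `admission_id` and `note_text`.
#' @param ... Passed to [keyword_rule_classifier()].
#' @return Data frame: `admission_id` plus one logical column per label.
#' @export
classify_cohort <- function(cohort, ...) {
  mat <- t(vapply(cohort$note_text,
                  function(tx) keyword_rule_classifier(tx, ...),
                  logical(length(pwid_labels()))))
  out <- data.frame(admission_id = cohort$admission_id, mat,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

parse_strict_bool <- function(x, column, path) {
  v <- rep(NA, length(x))
  chr <- tolower(trimws(as.character(x)))
  v[chr %in% c("true", "1")] <- TRUE
  v[chr %in% c("false", "0")] <- FALSE
  bad <- which(is.na(v))
  if (length(bad) > 0L) {
    stop(sprintf("unparsable boolean in column '%s' of %s at data row %d: '%s'",
                 column, path, bad[1], as.character(x)[bad[1]]))
  }
  as.logical(v)
}

#' Load external model predictions
#'
#' Reads a predictions file (CSV, or JSONL with one object per line) with
#' columns `admission_id`, `model_name` and one strictly boolean column per
#' canonical label ({true, false, 1, 0}). Column order is irrelevant; rows
#' are returned in file order.
#'
#' @param path File path; format inferred from the `.jsonl`/`.json` vs
#'   `.csv` extension.
#' @param labels Expected label set (default the canonical twelve).
#' @return Data frame: `admission_id`, `model_name`, one logical column per
#'   label in canonical order.
#' @export
load_predictions <- function(path, labels = pwid_labels()) {
  if (grepl("\\.jsonl?$", path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    raw <- do.call(rbind, lapply(lines, function(l) {
      as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)
    }))
  } else {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "#")
  }
  needed <- c("admission_id", "model_name", labels)
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0L) {
    stop("predictions file ", path, " missing column(s): ",
         paste(missing, collapse = ", "))
  }
  out <- data.frame(admission_id = as.character(raw$admission_id),
                    model_name = as.character(raw$model_name),
                    stringsAsFactors = FALSE)
  for (lab in labels) out[[lab]] <- parse_strict_bool(raw[[lab]], lab, path)
  out
}

#' Write predictions to CSV
#'
#' Inverse of [load_predictions()]: write-then-load is an identity
#' round-trip.
#'
#' @param predictions Data frame with `admission_id`, `model_name` and label
#'   columns.
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_predictions <- function(predictions, path) {
  df <- predictions
  for (nm in names(df)) {
    if (is.logical(df[[nm]])) df[[nm]] <- ifelse(df[[nm]], "true", "false")
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Join predictions to gold labels by admission
#'
#' @param gold Data frame with `admission_id` and label columns.
#' @param predictions Data frame with `admission_id` and label columns.
#' @return List of aligned data frames (`gold`, `pred`), rows in gold order.
#' @export
align_predictions <- function(gold, predictions) {
  unknown <- setdiff(predictions$admission_id, gold$admission_id)
  if (length(unknown) > 0L) {
    stop("predictions reference unknown admission_id(s): ",
         paste(utils::head(unknown, 5L), collapse = ", "),
         if (length(unknown) > 5L) " ..." else "")
  }
  absent <- setdiff(gold$admission_id, predictions$admission_id)
  if (length(absent) > 0L) {
    stop("predictions missing admission_id(s): ",
         paste(utils::head(absent, 5L), collapse = ", "),
         if (length(absent) > 5L) " ..." else "")
  }
  pred <- predictions[match(gold$admission_id, predictions$admission_id), ,
                      drop = FALSE]
  rownames(pred) <- NULL
  list(gold = gold, pred = pred)
}
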