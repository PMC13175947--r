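#' Rule-based de-identification patterns
#'
#' The ordered pattern families used by [deidentify_text()]. Order matters:
#' longer numeric identifiers are matched first (IHI before MRN before
#' phone) so that a long identifier is never partially consumed by a shorter
#' pattern. Dialects covered: dates as dd/mm/yyyy, yyyy-mm-dd or
#' "d Month yyyy"; Australian phone numbers (02/03/04/07/08-prefixed, 8-10
#' digits with optional spaces); MRNs as standalone 7-digit integers; IHIs
#' as 16-digit numbers beginning 800360; street addresses as number + street
#' name + suffix. Names are matched from a caller-supplied lexicon, not by
#' NER.
#'
#' @return Data frame with columns `category`, `token`, `pattern`.
#' @export
deid_patterns <- function() {
  months <- paste(month.name, collapse = "|")
  data.frame(
    category = c("ihi", "mrn", "phone", "date", "address"),
    token = c("[IHI]", "[MRN]", "[PHONE]", "[DATE]", "[ADDRESS]"),
    pattern = c(
      "\\b800360[0-9]{10}\\b",
      "\\b[1-9][0-9]{6}\\b",
      "\\b0[234578][0-9]{0,2}( ?[0-9]{3,4}){2}\\b",
      paste0("\\b([0-9]{1,2}/[0-9]{1,2}/[0-9]{4}|",
             "[0-9]{4}-[0-9]{2}-[0-9]{2}|",
             "[0-9]{1,2} (", months, ") [0-9]{4})\\b"),
      "\\b[0-9]{1,4} [A-Z][a-z]+ (Street|St|Road|Rd|Avenue|Ave|Lane|Drive|Crescent|Place)\\b"
    ),
    stringsAsFactors = FALSE
  )
}

#' De-identify free text with placeholder tokens
#'
#' Replaces direct and quasi-identifiers with standardised bracketed tokens:
#' names (from `name_lexicon`) with `[NAME]`, dates with `[DATE]`, medical
#' record numbers with `[MRN]`, individual healthcare identifiers with
#' `[IHI]`, telephone numbers with `[PHONE]` and postal addresses with
#' `[ADDRESS]`. Runs of whitespace are then collapsed to single spaces. No
#' other preprocessing is applied: case, numbers and spelling pass through
#' unchanged.
#'
#' @param raw Character scalar, the raw note text.
#' @param name_lexicon Character vector of names to replace (may be empty).
#' @param phi_spans Optional data frame of known PHI spans (`start`, `end`,
#'   `category` in raw coordinates, half-open). When supplied, the result's
#'   `residual_phi` lists any span whose raw value still occurs verbatim in
#'   the cleaned text.
#' @return Object of class `deid_result`: list with `clean_text`,
#'   `replacements` (named count per category) and `residual_phi` (data
#'   frame, empty when no known PHI survives).
#' @export
deidentify_text <- function(raw, name_lexicon = character(0),
                            phi_spans = NULL) {
  stopifnot(is.character(raw), length(raw) == 1L, !is.na(raw))
  pats <- deid_patterns()
  counts <- c(name = 0L, date = 0L, mrn = 0L, ihi = 0L, phone = 0L,
              address = 0L)
  text <- raw
  for (k in seq_len(nrow(pats))) {
    m <- gregexpr(pats$pattern[k], text)[[1]]
    n_hit <- if (m[1] == -1L) 0L else length(m)
    counts[[pats$category[k]]] <- counts[[pats$category[k]]] + n_hit
    if (n_hit > 0L) {
      text <- gsub(pats$pattern[k], fixed_token(pats$token[k]), text)
    }
  }
  if (length(name_lexicon) > 0L) {
    # longest names first so partial (single-word) collisions cannot occur
    lex <- name_lexicon[order(-nchar(name_lexicon))]
    for (nm in lex) {
      pat <- paste0("\\b", escape_regex(nm), "\\b")
      m <- gregexpr(pat, text)[[1]]
      if (m[1] != -1L) {
        counts[["name"]] <- counts[["name"]] + length(m)
        text <- gsub(pat, "[NAME]", text)
      }
    }
  }
  text <- trimws(gsub("[[:space:]]+", " ", text))

  residual <- data.frame(start = integer(0), end = integer(0),
                         category = character(0), value = character(0),
                         stringsAsFactors = FALSE)
  if (!is.null(phi_spans) && nrow(phi_spans) > 0L) {
    vals <- substr(rep(raw, nrow(phi_spans)), phi_spans$start,
                   phi_spans$end - 1L)
    left <- vapply(vals, function(v) grepl(v, text, fixed = TRUE), logical(1))
    if (any(left)) {
      residual <- data.frame(start = phi_spans$start[left],
                             end = phi_spans$end[left],
                             category = phi_spans$category[left],
                             value = unname(vals[left]),
                             stringsAsFactors = FALSE)
    }
  }
  structure(list(clean_text = text, replacements = counts,
                 residual_phi = residual),
            class = "deid_result")
}

# gsub replacement strings treat backslashes specially; tokens are literal
fixed_token <- function(tok) gsub("\\\\", "\\\\\\\\", tok)

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.-])", "\\\\\\1", x)

#' Audit de-identification across a cohort
#'
#' Runs [deidentify_text()] on every note and tallies residual PHI against
#' the generator's recorded spans.
#'
#' @param cohort Data frame from [generate_cohort()].
#' @param name_lexicon Name roster used during generation.
#' @return Data frame with one row per admission and category with a
#'   positive residual count; zero rows means full removal.
#' @export
deid_audit <- function(cohort, name_lexicon = default_name_roster()) {
  out <- list()
  for (i in seq_len(nrow(cohort))) {
    res <- deidentify_text(cohort$note_text[i], name_lexicon,
                           phi_spans = cohort$phi_spans[[i]])
    if (nrow(res$residual_phi) > 0L) {
      tab <- table(res$residual_phi$category)
      out[[length(out) + 1L]] <- data.frame(
        admission_id = cohort$admission_id[i],
        category = names(tab),
        residual = as.integer(tab),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(admission_id = character(0), category = character(0),
                      residual = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
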