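#' Canonical annotation label set
#'
#' The twelve binary attributes annotated on each discharge summary: any
#' injecting drug use, injection recency (current = within the last 30 days,
#' historical = remote use; not mutually exclusive), six substances, and the
#' two opioid agonist therapy (OAT) agents. Every gold-label table, prediction
#' table and error model in the package is keyed by these names.
#'
#' @return Character vector of the twelve label names, in canonical order.
#' @export
pwid_labels <- function() {
  c("idu_any", "idu_current", "idu_historical",
    "heroin", "prescription_opioids", "fentanyl",
    "methamphetamine", "cocaine", "cannabis", "benzodiazepine",
    "methadone", "buprenorphine")
}

#' Default labels included in metric reports
#'
#' Cocaine and fentanyl are generated and evaluated internally but excluded
#' from default reports because their gold prevalence in the emulated cohort
#' is too low (three cases each) for stable estimates. Pass a different
#' vector to the reporting functions to override.
#'
#' @return Character vector of the ten default report labels.
#' @export
default_report_labels <- function() {
  setdiff(pwid_labels(), c("cocaine", "fentanyl"))
}

#' Validate a gold-label assignment
#'
#' Checks the structural invariant of the label schema: current or historical
#' injecting implies any injecting. Current and historical are deliberately
#' not mutually exclusive.
#'
#' @param labels Named logical vector over [pwid_labels()].
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_gold_labels <- function(labels) {
  stopifnot(is.logical(labels), !anyNA(labels))
  missing <- setdiff(pwid_labels(), names(labels))
  if (length(missing) > 0L) {
    stop("missing labels: ", paste(missing, collapse = ", "))
  }
  if ((labels[["idu_current"]] || labels[["idu_historical"]]) &&
      !labels[["idu_any"]]) {
    stop("idu_current or idu_historical set without idu_any")
  }
  invisible(TRUE)
}
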