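#' Normalise an ICD-10-AM code
#'
#' Canonical form: uppercase, dot removed, surrounding whitespace stripped.
#'
#' @param code Character vector of raw codes.
#' @return Character vector of canonical codes.
#' @export
normalize_code <- function(code) {
  stopifnot(is.character(code))
  code <- trimws(code)
  if (any(nchar(code) == 0L)) stop("empty ICD code")
  gsub(".", "", toupper(code), fixed = TRUE)
}

#' ICD-10-AM code groups used as PWID proxies
#'
#' The five code groups, with stated ranges expanded to enumerated prefixes:
#' HIV (B21-B24, Z21), hepatitis C (B17.1, B18.2, Z22.52), substance
#' use-related (Z72.2, Z86.41, T40.1-T40.5, T43.6), substance-use disorders
#' (F11, F14, F15, F19) and homelessness (Z59). Matching is by prefix so
#' child codes (e.g. F11.2) map to their parent category.
#'
#' @return Named list of character vectors of canonical prefixes.
#' @export
default_code_groups <- function() {
  list(
    hiv = c("B21", "B22", "B23", "B24", "Z21"),
    hepatitis_c = c("B171", "B182", "Z2252"),
    substance_related = c("Z722", "Z8641", "T401", "T402", "T403", "T404",
                          "T405", "T436"),
    sud = c("F11", "F14", "F15", "F19"),
    homelessness = c("Z59")
  )
}

#' Substance-specific ICD code map
#'
#' Heroin (T40.1, F11), prescription opioids (T40.2-T40.4, F11),
#' methamphetamine (T43.6, F15) and cocaine (T40.5, F14). Heroin and
#' prescription opioids share F11 by definition, so an F11 code flags both.
#'
#' @return Named list of character vectors of canonical prefixes.
#' @export
default_substance_code_map <- function() {
  list(
    heroin = c("T401", "F11"),
    prescription_opioids = c("T402", "T403", "T404", "F11"),
    methamphetamine = c("T436", "F15"),
    cocaine = c("T405", "F14")
  )
}

#' Evaluate code-group membership for an admission's codes
#'
#' A group is flagged true iff any normalised code starts with any of the
#' group's prefixes.
#'
#' @param codes Character vector of ICD codes (any dialect; normalised
#'   internally). May be empty.
#' @param groups Named list of prefix vectors, see [default_code_groups()].
#' @return Named logical vector, one flag per group.
#' @export
evaluate_code_groups <- function(codes, groups = default_code_groups()) {
  norm <- if (length(codes) > 0L) normalize_code(codes) else character(0)
  vapply(groups, function(prefixes) {
    any(vapply(prefixes, function(p) any(startsWith(norm, p)), logical(1)))
  }, logical(1))
}

#' Default composite PWID proxy rules
#'
#' The evaluated rule set: two conjunctions (hepatitis C + SUD, HIV + SUD)
#' and three threshold rules (at least 3 of the first four groups; at least
#' 3, and at least 4, of all five groups). The HIV + SUD rule is retained
#' even though it can predict zero cases; downstream metrics then report
#' undefined (NA) PPV and F1 rather than dropping the rule.
#'
#' @return Named list of rules; each rule has either `required_groups` or
#'   `k_of_groups = list(k =, groups =)`.
#' @export
default_proxy_rules <- function() {
  four <- c("hiv", "hepatitis_c", "sud", "substance_related")
  five <- c(four, "homelessness")
  list(
    hepc_and_sud = list(required_groups = c("hepatitis_c", "sud")),
    hiv_and_sud = list(required_groups = c("hiv", "sud")),
    any3_of_4 = list(k_of_groups = list(k = 3L, groups = four)),
    any3_of_5 = list(k_of_groups = list(k = 3L, groups = five)),
    any4_of_5 = list(k_of_groups = list(k = 4L, groups = five))
  )
}

#' Apply composite proxy rules to group flags
#'
#' Conjunction rules require every listed group to be flagged; k-of-n rules
#' count distinct flagged groups among the candidates and compare against k.
#'
#' @param group_flags Named logical vector from [evaluate_code_groups()].
#' @param rules Named list of rules, see [default_proxy_rules()].
#' @return Named logical vector, one flag per rule.
#' @export
apply_proxy_rules <- function(group_flags, rules = default_proxy_rules()) {
  vapply(rules, function(rule) {
    if (!is.null(rule$required_groups)) {
      unknown <- setdiff(rule$required_groups, names(group_flags))
      if (length(unknown) > 0L) {
        stop("rule references unknown group(s): ", paste(unknown, collapse = ", "))
      }
      all(group_flags[rule$required_groups])
    } else if (!is.null(rule$k_of_groups)) {
      unknown <- setdiff(rule$k_of_groups$groups, names(group_flags))
      if (length(unknown) > 0L) {
        stop("rule references unknown group(s): ", paste(unknown, collapse = ", "))
      }
      sum(group_flags[rule$k_of_groups$groups]) >= rule$k_of_groups$k
    } else {
      stop("rule must define required_groups or k_of_groups")
    }
  }, logical(1))
}

#' Substance flags from ICD codes
#'
#' @param codes Character vector of ICD codes.
#' @param code_map Named list of prefixes, see
#'   [default_substance_code_map()].
#' @return Named logical vector, one flag per substance.
#' @export
substance_flags <- function(codes, code_map = default_substance_code_map()) {
  evaluate_code_groups(codes, code_map)
}

#' Apply ICD proxy rules across a cohort
#'
#' Convenience wrapper producing the per-admission boolean matrix of rule
#' and substance-flag outcomes used by the ICD evaluation report.
#'
#' @param cohort Data frame from [generate_cohort()] (or any data frame with
#'   an `icd_codes` list-column and `admission_id`).
#' @param groups,rules,code_map Rule configuration, overridable so other
#'   jurisdictions' code lists can be swapped in.
#' @return Data frame: `admission_id`, one logical column per proxy rule and
#'   per substance flag.
#' @export
icd_rule_matrix <- function(cohort, groups = default_code_groups(),
                            rules = default_proxy_rules(),
                            code_map = default_substance_code_map()) {
  res <- lapply(cohort$icd_codes, function(codes) {
    flags <- evaluate_code_groups(codes, groups)
    c(apply_proxy_rules(flags, rules), substance_flags(codes, code_map))
  })
  mat <- do.call(rbind, res)
  out <- data.frame(admission_id = cohort$admission_id, mat,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
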