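#' Note template bank
#'
#' Fragment bank for synthetic discharge-summary text, keyed by documentation
#' phenomenon. Each asserting fragment declares exactly which gold labels it
#' asserts; distractor fragments (negation, third-party use, prescribed
#' context, hepatitis-C serology) assert none but are confusable with label
#' language; filler fragments are neutral clinical prose. Fragment wording is
#' controlled so the keyword reference classifier recovers the asserted
#' labels exactly when distractors are disabled.
#'
#' @return List with elements `assert` (named list label -> character vector
#'   of fragments), `distract` (named list phenomenon -> fragments) and
#'   `filler` (character vector of neutral sentences).
#' @export
note_template_bank <- function() {
  assert <- list(
    idu_current = c(
      "Active IVDU, injected again within the last week.",
      "Reports ongoing injecting drug use, most recently a few days ago."
    ),
    idu_historical = c(
      "Former IVDU with previous injecting drug use years ago.",
      "History of injecting drug use, ceased a long time back."
    ),
    idu_any_only = c(
      "Documented injecting drug use, recency unclear from the notes.",
      "Known IVDU although recency unclear at this admission."
    ),
    heroin = c(
      "Reports heroin use around the time of admission.",
      "Ongoing heroin use disclosed during the ward round."
    ),
    prescription_opioids = c(
      "Escalating oxycodone misuse obtained from the street.",
      "Admits oxycodone misuse well beyond the stated dose."
    ),
    fentanyl = c(
      "Illicit fentanyl use reported this month.",
      "Disclosed intermittent illicit fentanyl use."
    ),
    methamphetamine = c(
      "Ongoing methamphetamine use most weekends.",
      "Reports regular methamphetamine use at home."
    ),
    cocaine = c(
      "Intermittent cocaine use reported socially.",
      "Occasional cocaine use disclosed on admission."
    ),
    cannabis = c(
      "Daily cannabis use reported by the patient.",
      "Long-standing cannabis use most evenings."
    ),
    benzodiazepine = c(
      "Escalating diazepam misuse reported by the patient.",
      "Admits diazepam misuse sourced outside the pharmacy."
    ),
    methadone = c(
      "Continues methadone maintenance via the local clinic.",
      "On methadone program, dosing confirmed with the clinic."
    ),
    buprenorphine = c(
      "On buprenorphine maintenance therapy, dose stable.",
      "Continues buprenorphine through the community program."
    )
  )
  distract <- list(
    negated_idu = c(
      "Denies any injecting drug use on direct questioning.",
      "No injecting drug use reported at any stage."
    ),
    third_party = c(
      "Partner reportedly uses heroin at home.",
      "Housemate known to use heroin, patient exposed at home."
    ),
    prescribed_opioid = c(
      "Oxycodone charted for post-operative pain as required.",
      "Regular oxycodone prescribed for chronic pain management."
    ),
    prescribed_benzo = c(
      "Diazepam prescribed for alcohol withdrawal per protocol.",
      "Diazepam charted on the regular medication list."
    ),
    hepc_mention = c(
      "Hepatitis C antibody detected on admission serology.",
      "Prior hepatitis C infection noted, viral load pending."
    )
  )
  filler <- c(
    "Admitted with cellulitis of the left lower limb.",
    "Blood cultures were taken and intravenous antibiotics commenced.",
    "The admission was complicated by a brief febrile episode overnight.",
    "Transthoracic echocardiogram showed structurally normal valves.",
    "Inflammatory markers trended down over the course of the stay.",
    "The infectious diseases team reviewed the patient daily.",
    "Wound swabs grew sensitive organisms and therapy was rationalised.",
    "Renal function remained stable throughout the admission.",
    "The patient mobilised independently prior to discharge.",
    "Follow up arranged in the outpatient clinic in two weeks.",
    "Oral step-down therapy was continued on discharge.",
    "Social work reviewed the patient regarding accommodation supports.",
    "Repeat imaging showed interval improvement of the collection.",
    "The patient remained afebrile for the final three days."
  )
  list(assert = assert, distract = distract, filler = filler)
}

#' Default synthetic name roster
#'
#' Small roster of invented patient names used both to embed synthetic PHI in
#' generated notes and as the name lexicon for rule-based de-identification.
#'
#' @return Character vector of full names.
#' @export
default_name_roster <- function() {
  first <- c("Alex", "Sam", "Jordan", "Casey", "Morgan", "Riley", "Taylor",
             "Jamie", "Robin", "Ashley", "Lee", "Noah", "Grace", "Liam",
             "Chloe", "Ethan", "Ruby", "Oscar", "Isla", "Henry")
  last <- c("Citizen", "Nguyen", "Smith", "Jones", "Brown", "Wilson",
            "Taylorson", "Martin", "Anderssen", "Thompson", "Walker",
            "Harrison", "Kelly", "Bennett", "Dawson", "Murphy")
  as.vector(outer(first, last, paste))
}

# --- synthetic PHI value generators ------------------------------------------

phi_date <- function() {
  fmt <- sample.int(3L, 1L)
  d <- sprintf("%d", sample.int(28L, 1L))
  m <- sample.int(12L, 1L)
  y <- sample(2018:2022, 1L)
  if (fmt == 1L) {
    sprintf("%02d/%02d/%d", as.integer(d), m, y)
  } else if (fmt == 2L) {
    sprintf("%d-%02d-%02d", y, m, as.integer(d))
  } else {
    paste(d, month.name[m], y)
  }
}

phi_mrn <- function() {
  paste0(sample(1:9, 1L), paste(sample(0:9, 6L, replace = TRUE), collapse = ""))
}

phi_ihi <- function() {
  paste0("800360", paste(sample(0:9, 10L, replace = TRUE), collapse = ""))
}

phi_phone <- function() {
  if (stats::runif(1) < 0.5) {
    sprintf("02 9%03d %04d", sample(0:999, 1L), sample(0:9999, 1L))
  } else {
    sprintf("04%02d %03d %03d", sample(0:99, 1L), sample(0:999, 1L),
            sample(0:999, 1L))
  }
}

phi_address <- function() {
  streets <- c("Wattle", "Banksia", "Acacia", "Bourke", "Crown", "Victoria",
               "Albion", "Palmer", "Forbes", "Riley")
  suffix <- c("Street", "Road", "Avenue", "Lane", "Crescent", "Place")
  paste(sample.int(400L, 1L), sample(streets, 1L), sample(suffix, 1L))
}

# --- note rendering ----------------------------------------------------------

# Draw an asserting fragment set for a gold-label assignment. Recency
# fragments cover idu_any; an "any-only" fragment is used when injecting is
# documented without recency.
select_fragments <- function(gold, bank) {
  frags <- character(0)
  pick <- function(key) sample(bank$assert[[key]], 1L)
  if (gold[["idu_current"]]) frags <- c(frags, pick("idu_current"))
  if (gold[["idu_historical"]]) frags <- c(frags, pick("idu_historical"))
  if (gold[["idu_any"]] && !gold[["idu_current"]] && !gold[["idu_historical"]]) {
    frags <- c(frags, pick("idu_any_only"))
  }
  for (lab in c("heroin", "prescription_opioids", "fentanyl",
                "methamphetamine", "cocaine", "cannabis", "benzodiazepine",
                "methadone", "buprenorphine")) {
    if (gold[[lab]]) {
      if (is.null(bank$assert[[lab]]) || length(bank$assert[[lab]]) == 0L) {
        stop("no asserting fragment for label ", lab)
      }
      frags <- c(frags, pick(lab))
    }
  }
  frags
}

# Distractors are only injected where they do not contradict or accidentally
# assert a gold label under the keyword reference classifier.
select_distractors <- function(gold, bank, rates) {
  out <- character(0)
  add <- function(key) sample(bank$distract[[key]], 1L)
  if (!gold[["idu_any"]] && stats::runif(1) < rates[["negated_idu"]]) {
    out <- c(out, add("negated_idu"))
  }
  if (!gold[["heroin"]] && stats::runif(1) < rates[["third_party"]]) {
    out <- c(out, add("third_party"))
  }
  if (stats::runif(1) < rates[["prescribed_opioid"]]) {
    out <- c(out, add("prescribed_opioid"))
  }
  if (stats::runif(1) < rates[["prescribed_benzo"]]) {
    out <- c(out, add("prescribed_benzo"))
  }
  if (stats::runif(1) < rates[["hepc_mention"]]) {
    out <- c(out, add("hepc_mention"))
  }
  out
}

#' Render a synthetic discharge-summary note
#'
#' Assembles a note that textually asserts every true gold label via at least
#' one fragment, optionally injects distractor fragments and synthetic PHI
#' (with recorded spans), and pads with neutral filler to a target word count
#' drawn upstream from the note-length model. Consecutive content fragments
#' are separated by filler so that the keyword classifier's context windows
#' do not bleed across fragments.
#'
#' @param gold Named logical vector over [pwid_labels()].
#' @param target_words Integer target word count (>= 20).
#' @param bank Fragment bank from [note_template_bank()].
#' @param distractor_rates Named rates, see [default_distractor_rates()].
#' @param phi Logical; embed synthetic PHI and record spans.
#' @param name_roster Character vector of synthetic names for PHI.
#' @return List with `note_text` (single string) and `phi_spans` (data frame
#'   with columns `start`, `end`, `category`; 1-based, half-open
#'   `[start, end)` so `substr(text, start, end - 1)` is the PHI value).
#' @export
render_note <- function(gold, target_words,
                        bank = note_template_bank(),
                        distractor_rates = default_distractor_rates(),
                        phi = TRUE,
                        name_roster = default_name_roster()) {
  validate_gold_labels(gold)
  target_words <- max(as.integer(target_words), 20L)

  # parts: character pieces joined by single spaces; phi_cat marks PHI parts
  parts <- character(0)
  phi_cat <- character(0)
  push <- function(txt, cat = NA_character_) {
    parts <<- c(parts, txt)
    phi_cat <<- c(phi_cat, cat)
  }

  if (isTRUE(phi)) {
    push("Patient"); push(sample(name_roster, 1L), "name")
    push("MRN"); push(phi_mrn(), "mrn")
    push("IHI"); push(phi_ihi(), "ihi")
    push("DOB"); push(phi_date(), "date")
    push("of"); push(phi_address(), "address")
    push("contact"); push(phi_phone(), "phone")
    push("admitted"); push(phi_date(), "date")
    push("under the infectious diseases service.")
  }

  content <- c(select_fragments(gold, bank),
               select_distractors(gold, bank, distractor_rates))
  if (length(content) > 1L) content <- sample(content)
  for (frag in content) {
    push(frag)
    push(sample(bank$filler, 1L))
  }

  count_words <- function() sum(lengths(strsplit(parts, "[ \t]+")))
  while (count_words() < target_words) {
    push(sample(bank$filler, 1L))
  }
  # trim trailing filler words to hit the target exactly (never trims into
  # PHI or content fragments beyond the final filler sentence)
  overshoot <- count_words() - target_words
  if (overshoot > 0L) {
    last_words <- strsplit(parts[length(parts)], " ")[[1]]
    if (length(last_words) > overshoot) {
      parts[length(parts)] <-
        paste(last_words[seq_len(length(last_words) - overshoot)],
              collapse = " ")
    }
  }

  nch <- nchar(parts)
  starts <- cumsum(c(1L, nch[-length(nch)] + 1L))
  note_text <- paste(parts, collapse = " ")
  keep <- !is.na(phi_cat)
  phi_spans <- data.frame(
    start = starts[keep],
    end = starts[keep] + nch[keep],
    category = phi_cat[keep],
    stringsAsFactors = FALSE
  )
  list(note_text = note_text, phi_spans = phi_spans)
}
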