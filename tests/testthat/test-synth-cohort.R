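test_that("cohort generation is bit-reproducible and stable under n changes", {
  cfg <- cohort_config(n_admissions = 40L, seed = 123L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  # per-record substreams: the first 25 records do not depend on cohort size
  small <- generate_cohort(cohort_config(n_admissions = 25L, seed = 123L))
  expect_identical(small$note_text, a$note_text[1:25])
  expect_identical(small$gold_idu_any, a$gold_idu_any[1:25])
})

test_that("degenerate prevalences are honoured exactly", {
  co <- generate_cohort(cohort_config(n_admissions = 10L, pwid_prevalence = 0,
                                      seed = 9L, render_notes = FALSE))
  expect_false(any(co$gold_idu_any))
  expect_false(any(co$gold_idu_current))

  lp <- default_label_prevalences()
  lp$pwid[] <- 1
  co2 <- generate_cohort(cohort_config(n_admissions = 10L, pwid_prevalence = 1,
                                       label_prevalences = lp, seed = 9L,
                                       render_notes = FALSE))
  for (lab in pwid_labels()) {
    expect_true(all(co2[[paste0("gold_", lab)]]), info = lab)
  }
})

test_that("configured Bernoulli quantities converge within 3 binomial SDs", {
  co <- big_cohort()
  n <- nrow(co)
  p0 <- 0.171
  expect_lt(abs(mean(co$gold_idu_any) - p0), 3 * sqrt(p0 * (1 - p0) / n))

  lp <- default_label_prevalences()
  pw <- co$gold_idu_any
  for (lab in c("heroin", "methamphetamine", "methadone", "cannabis",
                "idu_current", "idu_historical", "buprenorphine")) {
    p <- lp$pwid[[lab]]
    obs <- mean(co[[paste0("gold_", lab)]][pw])
    expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / sum(pw)),
              label = paste("pwid", lab))
  }
  for (lab in c("methamphetamine", "methadone", "cannabis")) {
    p <- lp$non_pwid[[lab]]
    obs <- mean(co[[paste0("gold_", lab)]][!pw])
    expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / sum(!pw)),
              label = paste("non-pwid", lab))
  }
  # structurally zero labels stay zero
  expect_false(any(co$gold_heroin[!pw]))
  expect_false(any(co$gold_idu_current[!pw]))
})

test_that("gold label schema invariants hold on every generated record", {
  co <- big_cohort()
  recency <- co$gold_idu_current | co$gold_idu_historical
  expect_true(all(co$gold_idu_any[recency]))
  # current and historical are not mutually exclusive: overlap occurs
  expect_gt(sum(co$gold_idu_current & co$gold_idu_historical), 0)
})

test_that("sample_gold_labels respects its conditional prevalence map", {
  lp <- default_label_prevalences()
  # heroin prevalence 0 among non-PWID: never drawn true
  set.seed(42)
  draws <- replicate(2000, sample_gold_labels(FALSE, lp)[["heroin"]])
  expect_false(any(draws))

  set.seed(43)
  p_md <- lp$pwid[["methadone"]]
  md <- replicate(10000, sample_gold_labels(TRUE, lp)[["methadone"]])
  expect_lt(abs(mean(md) - p_md), 3 * sqrt(p_md * (1 - p_md) / 10000))

  lp$pwid <- lp$pwid[-3]
  expect_error(sample_gold_labels(TRUE, lp), "missing labels")
})

test_that("note length model reproduces the group means", {
  co <- cached("half_prev_notes", function() {
    generate_cohort(cohort_config(n_admissions = 2000L, pwid_prevalence = 0.5,
                                  seed = 555L))
  })
  wc <- lengths(strsplit(co$note_text, "[ ]+"))
  expect_gt(min(wc), 19)
  expect_lt(abs(mean(wc[co$gold_idu_any]) - 350), 15)
  expect_lt(abs(mean(wc[!co$gold_idu_any]) - 290), 15)
})

test_that("notes assert the phenomena their gold labels require", {
  co <- noted_cohort()
  hist_notes <- co$note_text[co$gold_idu_historical]
  expect_true(all(grepl("former|previous|history", tolower(hist_notes))))
  her_notes <- co$note_text[co$gold_heroin]
  expect_true(all(grepl("heroin", tolower(her_notes))))
})

test_that("PHI spans are recorded, in bounds, non-overlapping; empty when disabled", {
  co <- noted_cohort()
  for (i in seq_len(20)) {
    sp <- co$phi_spans[[i]]
    expect_gt(nrow(sp), 0)
    expect_true(all(sp$start >= 1))
    expect_true(all(sp$end <= nchar(co$note_text[i]) + 1L))
    expect_true(all(sp$end > sp$start))
    ord <- order(sp$start)
    expect_true(all(sp$end[ord][-nrow(sp)] <= sp$start[ord][-1]))
    # spans address the actual PHI substrings (half-open convention)
    vals <- substr(rep(co$note_text[i], nrow(sp)), sp$start, sp$end - 1)
    expect_false(any(grepl("^ | $", vals)))
  }
  co2 <- generate_cohort(cohort_config(n_admissions = 5L, seed = 2L,
                                       phi = FALSE))
  expect_true(all(vapply(co2$phi_spans, nrow, integer(1)) == 0L))
})

test_that("assign_icd_codes follows the coding model", {
  gold <- stats::setNames(rep(FALSE, 12), pwid_labels())
  gold[c("idu_any", "heroin")] <- TRUE
  perfect <- list(sensitivity = stats::setNames(rep(1, 5), names(default_code_groups())),
                  fp_rate = stats::setNames(rep(0, 5), names(default_code_groups())))
  set.seed(1)
  codes <- normalize_code(assign_icd_codes(gold, perfect))
  expect_true(any(startsWith(codes, "T401")) || any(startsWith(codes, "F11")))

  none <- list(sensitivity = stats::setNames(rep(0, 5), names(default_code_groups())),
               fp_rate = stats::setNames(rep(0, 5), names(default_code_groups())))
  expect_length(assign_icd_codes(gold, none), 0)

  bad <- perfect
  names(bad$sensitivity)[1] <- "nonsense_group"
  expect_error(assign_icd_codes(gold, bad), "unknown code group")

  # binomial recovery of a configured group sensitivity
  model <- none
  model$sensitivity[["sud"]] <- 0.3
  set.seed(7)
  hits <- replicate(10000, {
    codes <- assign_icd_codes(gold, model)
    any(startsWith(normalize_code(codes), "F1"))
  })
  expect_lt(abs(mean(hits) - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))
})

test_that("simulate_predictions applies per-label sensitivity and specificity", {
  gold <- stats::setNames(rep(c(TRUE, FALSE), c(6, 6)), pwid_labels())
  perfect <- list(sensitivity = stats::setNames(rep(1, 12), pwid_labels()),
                  specificity = stats::setNames(rep(1, 12), pwid_labels()))
  expect_identical(unname(simulate_predictions(gold, perfect)), unname(gold))
  blind <- list(sensitivity = stats::setNames(rep(0, 12), pwid_labels()),
                specificity = stats::setNames(rep(1, 12), pwid_labels()))
  expect_false(any(simulate_predictions(gold, blind)))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_admissions = 0), "positive")
  expect_error(cohort_config(pwid_prevalence = 1.2), "proportions")
  lp <- default_label_prevalences()
  lp$pwid <- lp$pwid[-1]
  expect_error(cohort_config(label_prevalences = lp), "missing labels")
})
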