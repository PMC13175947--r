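test_that("confusion tables count cells correctly and are order-independent", {
  ct <- confusion_table(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
  expect_equal(ct$tp, 1); expect_equal(ct$fn, 1)
  expect_equal(ct$tn, 1); expect_equal(ct$fp, 0)

  g <- c(TRUE, FALSE, TRUE, FALSE, TRUE)
  ct2 <- confusion_table(g, g)
  expect_equal(ct2$fp + ct2$fn, 0)

  perm <- c(3, 1, 5, 2, 4)
  p <- c(TRUE, FALSE, FALSE, TRUE, TRUE)
  expect_equal(unclass(confusion_table(g[perm], p[perm])),
               unclass(confusion_table(g, p)))
  expect_error(confusion_table(g, p[1:3]), "different lengths")
})

test_that("diagnostic metrics reproduce reconstructed published rows to 3 dp", {
  # ICD composite: hepatitis C + substance use disorder
  m <- diagnostic_metrics(recon_icd$hepc_and_sud)
  expect_equal(round(m$f1, 3), 0.431)
  expect_equal(round(m$sensitivity, 3), 0.315)
  expect_equal(round(m$ppv, 3), 0.681)
  expect_equal(round(m$specificity, 3), 0.969)
  expect_equal(round(m$npv, 3), 0.871)
  expect_equal(round(m$accuracy, 3), 0.856)

  # rule predicting zero positives: PPV and F1 undefined, specificity 1
  m0 <- diagnostic_metrics(recon_icd$hiv_and_sud)
  expect_true(is.na(m0$ppv))
  expect_true(is.na(m0$f1))
  expect_equal(m0$specificity, 1)
  expect_equal(m0$sensitivity, 0)
  expect_equal(round(m0$npv, 3), 0.827)

  # best text model, any injecting drug use
  m1 <- diagnostic_metrics(recon_llm_idu)
  expect_equal(round(m1$f1, 3), 0.897)
  expect_equal(round(m1$accuracy, 3), 0.967)
  expect_equal(round(m1$sensitivity, 3), 0.819)
  expect_equal(round(m1$specificity, 3), 0.999)
  expect_equal(round(m1$ppv, 3), 0.992)
  expect_equal(round(m1$npv, 3), 0.963)
})

test_that("diagnostic metrics equal brute-force recomputation on random vectors", {
  set.seed(202)
  for (rep in 1:30) {
    n <- sample(5:80, 1)
    g <- stats::runif(n) < stats::runif(1)
    p <- stats::runif(n) < stats::runif(1)
    m <- diagnostic_metrics(confusion_table(g, p))
    sens <- if (sum(g) > 0) mean(p[g]) else NA_real_
    spec <- if (sum(!g) > 0) mean(!p[!g]) else NA_real_
    ppv <- if (sum(p) > 0) mean(g[p]) else NA_real_
    npv <- if (sum(!p) > 0) mean(!g[!p]) else NA_real_
    expect_equal(m$sensitivity, sens)
    expect_equal(m$specificity, spec)
    expect_equal(m$ppv, ppv)
    expect_equal(m$npv, npv)
    expect_equal(m$accuracy, mean(g == p))
    # identities, whenever defined
    if (!is.na(m$ppv) && !is.na(m$sensitivity) && (m$ppv + m$sensitivity) > 0) {
      expect_equal(m$f1, 2 * m$ppv * m$sensitivity / (m$ppv + m$sensitivity),
                   tolerance = 1e-12)
    }
    if (!is.na(sens) && !is.na(spec)) {
      P <- sum(g); N <- sum(!g)
      expect_equal(m$accuracy, (sens * P + spec * N) / (P + N),
                   tolerance = 1e-12)
    }
  }
})

test_that("bootstrap summaries behave: constants, coverage shape, monotone width", {
  d <- data.frame(x = stats::rnorm(40))
  bs <- bootstrap_ci(d, function(z) 0.5, n_iterations = 200, seed = 3)
  expect_equal(bs$ci_low, 0.5)
  expect_equal(bs$ci_high, 0.5)
  expect_false(bs$flagged)
  expect_lte(bs$ci_low, bs$ci_high)

  # sensitivity CI on the reconstructed any-injecting data
  v <- ct_vectors(recon_llm_idu)
  d2 <- data.frame(gold = v$gold, pred = v$pred)
  sens_stat <- function(z) {
    ct <- confusion_table(z$gold, z$pred)
    if (ct$tp + ct$fn == 0) NA_real_ else ct$tp / (ct$tp + ct$fn)
  }
  bs2 <- bootstrap_ci(d2, sens_stat, n_iterations = 1000, seed = 11)
  expect_lte(bs2$ci_low, bs2$point_estimate)
  expect_gte(bs2$ci_high, bs2$point_estimate)
  expect_equal(bs2$ci_low, 0.753, tolerance = 0.02)
  expect_equal(bs2$ci_high, 0.879, tolerance = 0.02)

  # doubling n shrinks the interval
  widths <- vapply(c(400L, 1600L), function(n) {
    set.seed(77)
    g <- rep(c(TRUE, FALSE), c(n / 4, 3 * n / 4))
    p <- ifelse(g, stats::runif(n) < 0.8, stats::runif(n) < 0.02)
    b <- bootstrap_ci(data.frame(gold = g, pred = p), sens_stat,
                      n_iterations = 400, seed = 5)
    b$ci_high - b$ci_low
  }, numeric(1))
  expect_lt(widths[2], widths[1])

  # mostly-undefined statistics are flagged, not silently NA
  d3 <- data.frame(x = 1:5)
  bs3 <- bootstrap_ci(d3, function(z) NA_real_, n_iterations = 50, seed = 1)
  expect_true(bs3$flagged)
  expect_equal(bs3$prop_defined, 0)
})

test_that("prevalence-weighted F1 weights by gold counts and handles undefined labels", {
  one <- list(a = confusion_counts(9, 1, 1, 20))
  w1 <- prevalence_weighted_f1(one)
  expect_equal(w1$value, diagnostic_metrics(one$a)$f1)

  two <- list(perfect = confusion_counts(30, 0, 0, 10),
              hopeless = confusion_counts(0, 0, 10, 30))
  w2 <- prevalence_weighted_f1(two)
  expect_equal(w2$value, 0.75)          # (30*1 + 10*0) / 40
  expect_equal(w2$macro_f1, 0.5)
  expect_equal(sum(w2$weights), 1)

  # undefined F1 (no gold, no predicted positives) contributes 0, flagged
  three <- list(a = confusion_counts(5, 0, 0, 5),
                b = confusion_counts(0, 0, 0, 10))
  w3 <- prevalence_weighted_f1(three, gold_counts = c(a = 5, b = 0))
  expect_equal(w3$n_undefined, 1L)
  expect_equal(w3$value, 1)

  expect_error(prevalence_weighted_f1(list(z = confusion_counts(0, 0, 0, 4))),
               "zero gold prevalence")
})

test_that("weighted F1 is label-order invariant and equals macro F1 at equal counts", {
  tabs <- list(x = confusion_counts(8, 2, 2, 20),
               y = confusion_counts(5, 5, 5, 17),
               z = confusion_counts(10, 1, 0, 21))
  a <- prevalence_weighted_f1(tabs)
  b <- prevalence_weighted_f1(rev(tabs))
  expect_equal(a$value, b$value)
  expect_equal(a$macro_f1, b$macro_f1)

  eq <- list(x = confusion_counts(8, 3, 2, 10), y = confusion_counts(6, 1, 4, 12))
  w <- prevalence_weighted_f1(eq)
  expect_equal(w$value, w$macro_f1)
})

test_that("model comparison ranks by weighted F1 and matches the configured error ordering", {
  co <- study_cohort_nonotes()
  gold <- cohort_labels(co, "gold")

  perfect <- gold
  always_false <- gold
  for (lab in pwid_labels()) always_false[[lab]] <- FALSE
  res <- compare_models(gold, list(perfect = perfect, nothing = always_false),
                        n_iterations = 50, seed = 2)
  expect_identical(res$model[1], "perfect")
  expect_equal(res$weighted_f1[1], 1)

  # three simulated models with strictly ordered error rates
  make_model <- function(sens, spec, seed) {
    em <- list(sensitivity = stats::setNames(rep(sens, 12), pwid_labels()),
               specificity = stats::setNames(rep(spec, 12), pwid_labels()))
    set.seed(seed)
    out <- gold
    for (i in seq_len(nrow(gold))) {
      g <- unlist(gold[i, pwid_labels()])
      out[i, pwid_labels()] <- as.list(simulate_predictions(g, em))
    }
    out
  }
  models <- list(good = make_model(0.95, 0.99, 1),
                 fair = make_model(0.75, 0.95, 2),
                 poor = make_model(0.45, 0.85, 3))
  rk <- compare_models(gold, models, n_iterations = 50, seed = 4)
  expect_identical(rk$model, c("good", "fair", "poor"))

  # one model: single row
  expect_equal(nrow(compare_models(gold, models["good"],
                                   n_iterations = 20, seed = 1)), 1L)
})

test_that("per-label evaluation recovers configured error rates within 3 binomial SDs", {
  co <- big_cohort()
  gold <- cohort_labels(co, "gold")
  pred <- cohort_labels(co, "pred")
  em <- default_prediction_error()
  for (lab in c("idu_any", "heroin", "benzodiazepine", "idu_current")) {
    ct <- confusion_table(gold[[lab]], pred[[lab]])
    n_pos <- ct$tp + ct$fn
    n_neg <- ct$fp + ct$tn
    sens_cfg <- em$sensitivity[[lab]]
    spec_cfg <- em$specificity[[lab]]
    expect_lt(abs(ct$tp / n_pos - sens_cfg),
              3 * sqrt(sens_cfg * (1 - sens_cfg) / n_pos) + 1e-9,
              label = paste(lab, "sens"))
    expect_lt(abs(ct$tn / n_neg - spec_cfg),
              3 * sqrt(spec_cfg * (1 - spec_cfg) / n_neg) + 1e-9,
              label = paste(lab, "spec"))
  }
})
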