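test_that("mcc matches hand values, the direct formula, and its symmetries", {
  expect_equal(mcc(confusion_counts(10, 0, 0, 10)), 1)
  # reconstructed male subgroup of the emulated study
  expect_equal(round(mcc(recon_groups$male), 3), 0.871)

  set.seed(31)
  for (rep in 1:40) {
    ct <- confusion_counts(sample(0:30, 1), sample(0:30, 1),
                           sample(0:30, 1), sample(0:30, 1))
    f <- c(ct$tp + ct$fp, ct$tp + ct$fn, ct$tn + ct$fp, ct$tn + ct$fn)
    oracle <- if (any(f == 0)) NA_real_ else
      (ct$tp * ct$tn - ct$fp * ct$fn) / sqrt(prod(f))
    expect_equal(mcc(ct), oracle, tolerance = 1e-12)
    # class-swap symmetry: tp<->tn, fp<->fn
    swapped <- confusion_counts(ct$tn, ct$fn, ct$fp, ct$tp)
    expect_equal(mcc(swapped), mcc(ct), tolerance = 1e-12)
  }
})

test_that("per-group fairness metrics reproduce reconstructed subgroup values", {
  # build one vector set holding all six subgroup blocks of the age/sex/
  # Indigenous reconstructions, then audit each attribute separately
  blocks <- lapply(recon_groups, ct_vectors)
  check_attr <- function(groups, expected_dp, expected_mcc) {
    gold <- unlist(lapply(groups, function(g) blocks[[g]]$gold))
    pred <- unlist(lapply(groups, function(g) blocks[[g]]$pred))
    grp <- rep(groups, vapply(groups, function(g) length(blocks[[g]]$gold),
                              numeric(1)))
    gm <- group_fairness_metrics(gold, pred, grp, n_iterations = 50, seed = 1)
    for (g in groups) {
      dp <- gm$estimate[gm$group == g & gm$metric == "demographic_parity"]
      expect_equal(round(dp, 3), expected_dp[[g]], info = g)
      m <- gm$estimate[gm$group == g & gm$metric == "mcc"]
      expect_equal(round(m, 3), expected_mcc[[g]], info = g)
    }
    gm
  }
  gm_age <- check_attr(c("age_lt52", "age_ge52"),
                       c(age_lt52 = 0.756, age_ge52 = 0.964),
                       c(age_lt52 = 0.914, age_ge52 = 0.720))
  gm_sex <- check_attr(c("female", "male"),
                       c(female = 0.850, male = 0.860),
                       c(female = 0.910, male = 0.871))
  gm_ind <- check_attr(c("aboriginal", "non_indig"),
                       c(aboriginal = 0.579, non_indig = 0.883),
                       c(aboriginal = 0.870, non_indig = 0.878))

  # parity ratios and 80%-rule flags from the reconstructions
  pr_age <- parity_ratios(gm_age)
  expect_equal(round(pr_age$ratio[pr_age$metric == "tpr"], 3), 0.606)
  expect_true(pr_age$flag[pr_age$metric == "tpr"])
  expect_equal(round(pr_age$ratio[pr_age$metric == "mcc"], 3), 0.787)
  expect_true(pr_age$flag[pr_age$metric == "mcc"])
  expect_false(pr_age$flag[pr_age$metric == "tnr"])

  pr_ind <- parity_ratios(gm_ind)
  expect_equal(round(pr_ind$ratio[pr_ind$metric == "demographic_parity"], 3),
               0.656)
  expect_true(pr_ind$flag[pr_ind$metric == "demographic_parity"])
  expect_false(pr_ind$flag[pr_ind$metric == "tpr"])

  pr_sex <- parity_ratios(gm_sex)
  expect_true(all(round(pr_sex$ratio, 3) >= 0.939))
  expect_false(any(pr_sex$flag))
})

test_that("per-group metrics equal pooled brute-force on partitioned vectors", {
  set.seed(91)
  n <- 300
  gold <- stats::runif(n) < 0.3
  pred <- ifelse(gold, stats::runif(n) < 0.8, stats::runif(n) < 0.1)
  grp <- sample(c("u", "v", "w"), n, replace = TRUE)
  gm <- group_fairness_metrics(gold, pred, grp, n_iterations = 10, seed = 1)
  for (g in c("u", "v", "w")) {
    sel <- grp == g
    dm <- diagnostic_metrics(confusion_table(gold[sel], pred[sel]))
    expect_equal(gm$estimate[gm$group == g & gm$metric == "tpr"], dm$sensitivity)
    expect_equal(gm$estimate[gm$group == g & gm$metric == "ppv"], dm$ppv)
    expect_equal(gm$estimate[gm$group == g & gm$metric == "demographic_parity"],
                 mean(!pred[sel]))
  }
})

test_that("duplicated groups give unit parity ratios; identical behaviour is unflagged", {
  v <- ct_vectors(recon_groups$male)
  gold <- c(v$gold, v$gold)
  pred <- c(v$pred, v$pred)
  grp <- rep(c("g1", "g2"), each = length(v$gold))
  gm <- group_fairness_metrics(gold, pred, grp, n_iterations = 20, seed = 2)
  pr <- parity_ratios(gm)
  expect_true(all(pr$ratio == 1))
  expect_false(any(pr$flag))
  expect_true(all(pr$ratio > 0 & pr$ratio <= 1))
})

test_that("parity ratios are invariant to group labelling order", {
  v1 <- ct_vectors(recon_groups$age_lt52)
  v2 <- ct_vectors(recon_groups$age_ge52)
  gold <- c(v1$gold, v2$gold); pred <- c(v1$pred, v2$pred)
  grp_a <- rep(c("young", "old"), c(length(v1$gold), length(v2$gold)))
  grp_b <- rep(c("z_young", "a_old"), c(length(v1$gold), length(v2$gold)))
  ra <- parity_ratios(group_fairness_metrics(gold, pred, grp_a,
                                             n_iterations = 10, seed = 3))
  rb <- parity_ratios(group_fairness_metrics(gold, pred, grp_b,
                                             n_iterations = 10, seed = 3))
  expect_equal(ra$ratio[order(ra$metric)], rb$ratio[order(rb$metric)])
})

test_that("unknown attributes are excluded and counted; undefined metrics handled", {
  gold <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  pred <- c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE)
  grp <- c("a", "a", "b", "b", NA, NA)
  gm <- group_fairness_metrics(gold, pred, grp, n_iterations = 10, seed = 1)
  expect_equal(attr(gm, "n_excluded"), 2L)
  expect_setequal(unique(gm$group), c("a", "b"))
  # group b has no gold positives: tpr undefined there, excluded with warning
  w <- capture_warnings(pr <- parity_ratios(gm))
  expect_true(any(grepl("undefined", w)))
  expect_false("tpr" %in% pr$metric && any(is.na(pr$ratio)))
})

test_that("fairness audit dichotomises age at the cohort median and omits unknowns", {
  co <- study_cohort_nonotes()
  fa <- fairness_audit(co, n_iterations = 20, seed = 5)
  expect_setequal(names(fa), c("age", "sex", "indigenous_status"))
  expect_equal(attr(fa, "age_cut"), stats::median(co$age))
  expect_equal(length(unique(fa$age$metrics$group)), 2L)
  n_unknown <- sum(co$indigenous_status == "Unknown")
  expect_equal(attr(fa$indigenous_status$metrics, "n_excluded"), n_unknown)
  expect_true(all(fa$age$parity$ratio > 0 & fa$age$parity$ratio <= 1))
})
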