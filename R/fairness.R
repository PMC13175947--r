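#' Matthews correlation coefficient
#'
#' Balanced single-number summary of a 2x2 confusion table,
#' (tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn)), in \[-1, 1\].
#' Undefined (NA) when any marginal factor is zero.
#'
#' @param ct A `confusion_table`.
#' @return Numeric scalar or `NA`.
#' @export
mcc <- function(ct) {
  stopifnot(inherits(ct, "confusion_table"))
  f <- c(ct$tp + ct$fp, ct$tp + ct$fn, ct$tn + ct$fp, ct$tn + ct$fn)
  if (any(f == 0)) return(NA_real_)
  (ct$tp * ct$tn - ct$fp * ct$fn) / sqrt(prod(f))
}

fairness_metric_names <- function() {
  c("demographic_parity", "tpr", "tnr", "ppv", "npv", "mcc")
}

# all six group fairness metrics from raw vectors; DP is the proportion of
# the group predicted NEGATIVE (one minus the predicted-positive rate)
group_metric_values <- function(gold, pred) {
  ct <- confusion_table(gold, pred)
  dm <- diagnostic_metrics(ct)
  c(demographic_parity = safe_div(ct$fn + ct$tn, ct$n),
    tpr = dm$sensitivity, tnr = dm$specificity,
    ppv = dm$ppv, npv = dm$npv, mcc = mcc(ct))
}

#' Per-group fairness metrics with bootstrap confidence intervals
#'
#' Splits records by a protected attribute and computes, per group:
#' demographic parity (proportion predicted negative within the group), true
#' positive rate, true negative rate, PPV, NPV and the Matthews correlation
#' coefficient, each with a percentile bootstrap CI from resampling within
#' the group. Records with an unknown (`NA`) attribute are excluded and
#' counted; empty groups are dropped with a warning.
#'
#' @param gold,pred Logical vectors for a single label (typically any
#'   injecting drug use).
#' @param group Character or factor vector of group membership, `NA` for
#'   unknown.
#' @param n_iterations Bootstrap replicates.
#' @param seed Integer seed.
#' @return Data frame with one row per (group, metric): `group`, `n`,
#'   `n_gold_positive`, `metric`, `estimate`, `ci_low`, `ci_high`. Attribute
#'   `n_excluded` records how many unknown-attribute records were omitted.
#' @export
group_fairness_metrics <- function(gold, pred, group,
                                   n_iterations = 1000L, seed = 1L) {
  stopifnot(length(gold) == length(pred), length(gold) == length(group))
  group <- as.character(group)
  known <- !is.na(group)
  n_excluded <- sum(!known)
  gold <- gold[known]; pred <- pred[known]; group <- group[known]
  levels <- sort(unique(group))
  out <- list()
  for (gi in seq_along(levels)) {
    g_rows <- group == levels[gi]
    if (sum(g_rows) == 0L) {
      warning("group ", levels[gi], " has no records; excluded")
      next
    }
    g <- gold[g_rows]; p <- pred[g_rows]
    point <- group_metric_values(g, p)
    ng <- length(g)
    set.seed(seed + gi)
    boots <- matrix(NA_real_, nrow = n_iterations,
                    ncol = length(fairness_metric_names()),
                    dimnames = list(NULL, fairness_metric_names()))
    for (b in seq_len(n_iterations)) {
      bi <- sample.int(ng, ng, replace = TRUE)
      boots[b, ] <- group_metric_values(g[bi], p[bi])
    }
    for (m in fairness_metric_names()) {
      def <- boots[, m][!is.na(boots[, m])]
      ci <- if (length(def) > 0L) {
        unname(stats::quantile(def, c(0.025, 0.975)))
      } else c(NA_real_, NA_real_)
      out[[length(out) + 1L]] <- data.frame(
        group = levels[gi], n = ng, n_gold_positive = sum(g),
        metric = m, estimate = unname(point[[m]]),
        ci_low = ci[1], ci_high = ci[2],
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_excluded") <- n_excluded
  res
}

#' Parity ratios and 80%-rule flags
#'
#' For each fairness metric, the parity ratio is the minimum group value
#' divided by the maximum. Ratios below 0.80 are flagged as failing the 80%
#' rule. Groups with an undefined value for a metric are excluded from its
#' min/max with a warning; a metric undefined in every group is omitted.
#' Per-group relative ratios (each group's value divided by the
#' best-performing group's) are attached as attribute `"per_group"`.
#'
#' @param metrics Data frame from [group_fairness_metrics()] (requires at
#'   least two groups).
#' @param threshold Fairness threshold (default 0.80).
#' @return Object of class `parity_report`: data frame with `metric`,
#'   `ratio`, `min_group`, `max_group`, `flag`.
#' @export
parity_ratios <- function(metrics, threshold = 0.80) {
  stopifnot(length(unique(metrics$group)) >= 2L)
  out <- list()
  per_group <- list()
  for (m in unique(metrics$metric)) {
    sub <- metrics[metrics$metric == m, ]
    undef <- is.na(sub$estimate)
    if (any(undef)) {
      warning("metric ", m, ": undefined in group(s) ",
              paste(sub$group[undef], collapse = ", "),
              "; excluded from parity ratio")
      sub <- sub[!undef, ]
    }
    if (nrow(sub) < 2L) next
    lo <- which.min(sub$estimate); hi <- which.max(sub$estimate)
    ratio <- sub$estimate[lo] / sub$estimate[hi]
    out[[length(out) + 1L]] <- data.frame(
      metric = m, ratio = ratio,
      min_group = sub$group[lo], max_group = sub$group[hi],
      flag = ratio < threshold, stringsAsFactors = FALSE
    )
    per_group[[m]] <- stats::setNames(sub$estimate / sub$estimate[hi], sub$group)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "per_group") <- per_group
  structure(res, class = c("parity_report", "data.frame"))
}

#' Full fairness audit of one label across demographic attributes
#'
#' Audits a classifier for a single label (by default any injecting drug
#' use) across age dichotomised at the cohort median, sex, and Indigenous
#' status ("Unknown" treated as missing and omitted with a count, as in the
#' emulated study).
#'
#' @param cohort Data frame from [generate_cohort()] (needs `age`, `sex`,
#'   `indigenous_status`).
#' @param gold,pred Logical vectors aligned with `cohort` rows.
#' @param n_iterations,seed Bootstrap controls.
#' @return List with one element per attribute: `metrics` (per-group data
#'   frame) and `parity` (parity report). The age cut used is attached as
#'   attribute `"age_cut"`.
#' @export
fairness_audit <- function(cohort, gold = cohort$gold_idu_any,
                           pred = cohort$pred_idu_any,
                           n_iterations = 1000L, seed = 1L) {
  age_cut <- stats::median(cohort$age)
  age_group <- ifelse(cohort$age < age_cut,
                      sprintf("age<%.0f", age_cut), sprintf("age>=%.0f", age_cut))
  indig <- ifelse(cohort$indigenous_status == "Unknown", NA_character_,
                  cohort$indigenous_status)
  attrs <- list(age = age_group, sex = cohort$sex, indigenous_status = indig)
  out <- lapply(seq_along(attrs), function(k) {
    gm <- group_fairness_metrics(gold, pred, attrs[[k]],
                                 n_iterations = n_iterations,
                                 seed = seed + 100L * k)
    list(metrics = gm, parity = parity_ratios(gm))
  })
  names(out) <- names(attrs)
  attr(out, "age_cut") <- age_cut
  out
}
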