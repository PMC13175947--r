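#' Confusion table for one binary label
#'
#' @param gold Logical vector of gold labels.
#' @param pred Logical vector of predictions, aligned with `gold` (align by
#'   admission upstream, e.g. via [align_predictions()]).
#' @return Object of class `confusion_table`: list with integer `tp`, `fp`,
#'   `fn`, `tn` and `n`.
#' @export
confusion_table <- function(gold, pred) {
  if (length(gold) != length(pred)) {
    stop("gold and pred have different lengths (", length(gold), " vs ",
         length(pred), ")")
  }
  stopifnot(is.logical(gold), is.logical(pred), !anyNA(gold), !anyNA(pred))
  ct <- list(
    tp = sum(gold & pred), fp = sum(!gold & pred),
    fn = sum(gold & !pred), tn = sum(!gold & !pred)
  )
  ct$n <- ct$tp + ct$fp + ct$fn + ct$tn
  structure(ct, class = "confusion_table")
}

#' Build a confusion table from counts
#'
#' Used to reconstruct published confusion tables from printed group sizes
#' and metrics.
#'
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @return `confusion_table` object.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, n = tp + fp + fn + tn),
            class = "confusion_table")
}

safe_div <- function(num, den) if (den == 0) NA_real_ else num / den

#' Diagnostic metrics from a confusion table
#'
#' Sensitivity, specificity, positive and negative predictive values,
#' accuracy and F1. Any metric with a zero denominator is undefined and
#' returned as `NA` (e.g. PPV of a rule that predicts no positives).
#'
#' @param ct A `confusion_table`.
#' @return Object of class `diagnostic_metrics`: named list of the six
#'   metrics plus `n_positive_gold` and `n_predicted_positive`.
#' @export
diagnostic_metrics <- function(ct) {
  stopifnot(inherits(ct, "confusion_table"))
  # F1 is the harmonic mean of PPV and sensitivity, so it is undefined
  # whenever either constituent is (e.g. a rule predicting no positives)
  f1 <- if (ct$tp + ct$fp == 0 || ct$tp + ct$fn == 0) {
    NA_real_
  } else {
    safe_div(2 * ct$tp, 2 * ct$tp + ct$fp + ct$fn)
  }
  structure(list(
    sensitivity = safe_div(ct$tp, ct$tp + ct$fn),
    specificity = safe_div(ct$tn, ct$tn + ct$fp),
    ppv = safe_div(ct$tp, ct$tp + ct$fp),
    npv = safe_div(ct$tn, ct$tn + ct$fn),
    accuracy = safe_div(ct$tp + ct$tn, ct$n),
    f1 = f1,
    n_positive_gold = ct$tp + ct$fn,
    n_predicted_positive = ct$tp + ct$fp
  ), class = "diagnostic_metrics")
}

#' Percentile bootstrap of a record-level statistic
#'
#' Resamples records with replacement (same size), evaluates the statistic
#' on each replicate and returns percentile 2.5/97.5 bounds over the defined
#' replicate values. Resampling is at the record (admission) level so that
#' when the statistic spans several labels their correlation is preserved.
#'
#' @param data Data frame (or list of equal-length vectors) of records.
#' @param statistic Function of a resampled `data` returning a scalar
#'   (possibly `NA` when undefined on that replicate).
#' @param n_iterations Number of bootstrap replicates (default 1000).
#' @param seed Integer seed for reproducibility.
#' @param conf Confidence level (default 0.95).
#' @return Object of class `bootstrap_summary`: `point_estimate`, `ci_low`,
#'   `ci_high`, `n_iterations`, `seed`, `prop_defined` and `flagged` (`TRUE`
#'   when the statistic was undefined on more than half the replicates).
#' @export
bootstrap_ci <- function(data, statistic, n_iterations = 1000L, seed = 1L,
                         conf = 0.95) {
  if (is.data.frame(data)) {
    n <- nrow(data)
    take <- function(idx) data[idx, , drop = FALSE]
  } else if (is.list(data)) {
    n <- length(data[[1]])
    take <- function(idx) lapply(data, `[`, idx)
  } else {
    n <- length(data)
    take <- function(idx) data[idx]
  }
  if (n < 1L) stop("no records to resample")
  point <- statistic(data)
  set.seed(seed)
  vals <- vapply(seq_len(n_iterations), function(b) {
    as.numeric(statistic(take(sample.int(n, n, replace = TRUE))))
  }, numeric(1))
  defined <- vals[!is.na(vals)]
  prop_defined <- length(defined) / n_iterations
  if (length(defined) == 0L) {
    ci <- c(NA_real_, NA_real_)
  } else {
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(defined, c(alpha, 1 - alpha)))
  }
  structure(list(point_estimate = point, ci_low = ci[1], ci_high = ci[2],
                 n_iterations = n_iterations, seed = seed,
                 prop_defined = prop_defined,
                 flagged = prop_defined < 0.5),
            class = "bootstrap_summary")
}

# shared bootstrap index matrix: one resampling of admissions reused across
# labels and metrics, preserving cross-label correlation
bootstrap_indices <- function(n, n_iterations, seed) {
  set.seed(seed)
  matrix(sample.int(n, n * n_iterations, replace = TRUE),
         nrow = n_iterations, ncol = n, byrow = TRUE)
}

#' Per-label diagnostic metrics with bootstrap confidence intervals
#'
#' Evaluates every label's confusion table and diagnostic metrics, with
#' percentile bootstrap CIs from a single set of admission-level resamples
#' shared across labels.
#'
#' @param gold,pred Data frames with `admission_id` and logical label
#'   columns (aligned or alignable by `admission_id`).
#' @param labels Labels to evaluate (default [default_report_labels()]).
#' @param n_iterations Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return Data frame, one row per (label, metric): `label`, `metric`,
#'   `estimate`, `ci_low`, `ci_high`, `n_positive_gold`,
#'   `n_predicted_positive`.
#' @export
evaluate_labels <- function(gold, pred, labels = default_report_labels(),
                            n_iterations = 1000L, seed = 1L) {
  al <- align_predictions(gold, pred)
  n <- nrow(al$gold)
  idx <- bootstrap_indices(n, n_iterations, seed)
  metrics <- c("f1", "accuracy", "sensitivity", "specificity", "ppv", "npv")
  out <- list()
  for (lab in labels) {
    g <- al$gold[[lab]]
    p <- al$pred[[lab]]
    dm <- diagnostic_metrics(confusion_table(g, p))
    boots <- matrix(NA_real_, nrow = n_iterations, ncol = length(metrics),
                    dimnames = list(NULL, metrics))
    for (b in seq_len(n_iterations)) {
      bi <- idx[b, ]
      bm <- diagnostic_metrics(confusion_table(g[bi], p[bi]))
      boots[b, ] <- unlist(bm[metrics])
    }
    for (m in metrics) {
      def <- boots[, m][!is.na(boots[, m])]
      ci <- if (length(def) > 0L) {
        unname(stats::quantile(def, c(0.025, 0.975)))
      } else c(NA_real_, NA_real_)
      out[[length(out) + 1L]] <- data.frame(
        label = lab, metric = m, estimate = dm[[m]],
        ci_low = ci[1], ci_high = ci[2],
        n_positive_gold = dm$n_positive_gold,
        n_predicted_positive = dm$n_predicted_positive,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Prevalence-weighted average F1 across labels
#'
#' Per-label F1 scores averaged with weights proportional to each label's
#' gold-positive count, so frequent conditions carry proportionate influence
#' on the aggregate. Labels whose F1 is undefined (no predicted and no gold
#' positives in the resample) contribute 0 with a warning flag rather than
#' being dropped, keeping low-prevalence labels in the aggregate. Also
#' returns the macro (unweighted mean) F1.
#'
#' @param tables Named list of `confusion_table`s, one per included label.
#' @param gold_counts Optional named gold-positive counts; defaults to
#'   `tp + fn` of each table.
#' @return Object of class `weighted_f1`: `value`, `macro_f1`, `weights`,
#'   `included_labels`, `n_undefined`.
#' @export
prevalence_weighted_f1 <- function(tables, gold_counts = NULL) {
  stopifnot(length(tables) >= 1L)
  labs <- names(tables)
  if (is.null(gold_counts)) {
    gold_counts <- vapply(tables, function(ct) ct$tp + ct$fn, numeric(1))
  } else {
    gold_counts <- gold_counts[labs]
  }
  if (sum(gold_counts) == 0) {
    stop("all labels have zero gold prevalence; weighted F1 undefined")
  }
  f1 <- vapply(tables, function(ct) diagnostic_metrics(ct)$f1, numeric(1))
  n_undef <- sum(is.na(f1))
  f1[is.na(f1)] <- 0
  weights <- gold_counts / sum(gold_counts)
  structure(list(value = sum(weights * f1),
                 macro_f1 = mean(f1),
                 weights = weights,
                 included_labels = labs,
                 n_undefined = n_undef),
            class = "weighted_f1")
}

# weighted F1 of aligned label data frames (no CI)
weighted_f1_value <- function(gold, pred, labels) {
  tables <- lapply(labels, function(lab) confusion_table(gold[[lab]], pred[[lab]]))
  names(tables) <- labels
  prevalence_weighted_f1(tables)
}

#' Compare models by prevalence-weighted average F1
#'
#' Computes each model's weighted F1 with a percentile bootstrap CI
#' (resampling admissions jointly across labels) and ranks models in
#' descending order; ties are broken by macro F1 and then model name.
#'
#' @param gold Data frame with `admission_id` and label columns.
#' @param predictions Named list of prediction data frames (one per model).
#' @param labels Labels included in the aggregate (default
#'   [default_report_labels()]).
#' @param n_iterations Bootstrap replicates.
#' @param seed Integer seed (shared resamples across models, so the
#'   comparison is paired).
#' @return Data frame: `model`, `weighted_f1`, `ci_low`, `ci_high`,
#'   `macro_f1`, sorted best first.
#' @export
compare_models <- function(gold, predictions,
                           labels = default_report_labels(),
                           n_iterations = 1000L, seed = 1L) {
  stopifnot(length(predictions) >= 1L, !is.null(names(predictions)))
  n <- nrow(gold)
  idx <- bootstrap_indices(n, n_iterations, seed)
  rows <- lapply(names(predictions), function(model) {
    al <- align_predictions(gold, predictions[[model]])
    wf <- weighted_f1_value(al$gold, al$pred, labels)
    reps <- vapply(seq_len(n_iterations), function(b) {
      bi <- idx[b, ]
      g <- al$gold[bi, , drop = FALSE]
      p <- al$pred[bi, , drop = FALSE]
      counts <- vapply(labels, function(lab) sum(g[[lab]]), numeric(1))
      if (sum(counts) == 0) return(NA_real_)
      weighted_f1_value(g, p, labels)$value
    }, numeric(1))
    def <- reps[!is.na(reps)]
    ci <- if (length(def) > 0L) {
      unname(stats::quantile(def, c(0.025, 0.975)))
    } else c(NA_real_, NA_real_)
    data.frame(model = model, weighted_f1 = wf$value,
               ci_low = ci[1], ci_high = ci[2], macro_f1 = wf$macro_f1,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(-res$weighted_f1, -res$macro_f1, res$model), ]
  rownames(res) <- NULL
  res
}

#' Format an estimate with its interval
#'
#' Report rendering convention: three decimal places, "est (lo, hi)", `NA`
#' for undefined estimates.
#'
#' @param est,lo,hi Numeric vectors.
#' @return Character vector.
#' @export
format_est_ci <- function(est, lo, hi) {
  ifelse(is.na(est), "NA",
         sprintf("%.3f (%.3f, %.3f)", est, lo, hi))
}
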