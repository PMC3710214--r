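#' Evaluate predictions against assigned phenotypes
#'
#' Internal validation of the algorithm: confusion counts and
#' sensitivity/specificity for the Hurler vs non-Hurler dichotomy
#' (`H` = positive; `HS` and `S` = negative). Indeterminate predictions and
#' unlabeled records are excluded from the confusion matrix but counted and
#' reported. Undefined ratios (empty denominator) are returned as `NA`,
#' never coerced to 0 or 1.
#'
#' @param cohort a labeled `mpsi_cohort`.
#' @param predictions an `mpsi_prediction` whose `patient_id`s all occur in
#'   `cohort`.
#' @return An object of class `"mpsi_evaluation"`: `n_total`,
#'   `n_classifiable`, `n_indeterminate`, `n_unlabeled`, `tp`, `fp`, `tn`,
#'   `fn`, `sensitivity`, `specificity` (fractions, `NA` when undefined),
#'   and `per_step`, a named count of decisive verdicts per step.
#' @examples
#' coh <- mpsi_cohort()
#' ev <- evaluate(coh, predict(mpsi_model(), coh))
#' ev$sensitivity  # 1
#' @export
evaluate <- function(cohort, predictions) {
  stopifnot(inherits(cohort, "mpsi_cohort"),
            inherits(predictions, "mpsi_prediction"))
  idx <- match(predictions$patient_id, cohort$patient_id)
  if (anyNA(idx)) {
    stop(sprintf("prediction id(s) not in cohort: %s",
                 paste(predictions$patient_id[is.na(idx)], collapse = ", ")),
         call. = FALSE)
  }
  truth <- binary_label(cohort$phenotype[idx])
  pred <- predictions$verdict

  unlabeled <- is.na(truth)
  indet <- pred == "indeterminate"
  use <- !unlabeled & !indet
  tp <- sum(use & truth == "H" & pred == "H")
  fn <- sum(use & truth == "H" & pred == "non-H")
  tn <- sum(use & truth == "non-H" & pred == "non-H")
  fp <- sum(use & truth == "non-H" & pred == "H")

  ratio <- function(num, den) if (den == 0L) NA_real_ else num / den
  per_step <- table(factor(predictions$decisive_step,
                           levels = c("genotype", "activity", "clinical",
                                      "none")))
  structure(list(
    n_total = nrow(predictions),
    n_classifiable = sum(use),
    n_indeterminate = sum(indet),
    n_unlabeled = sum(unlabeled),
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    per_step = c(per_step)
  ), class = "mpsi_evaluation")
}

#' @export
print.mpsi_evaluation <- function(x, ...) {
  fmt_pct <- function(frac) {
    if (is.na(frac)) "undefined" else sprintf("%d%%", percent_int(frac))
  }
  cat("Evaluation (positive class = Hurler)\n")
  cat(sprintf("  patients: %d total, %d classifiable, %d indeterminate, %d unlabeled\n",
              x$n_total, x$n_classifiable, x$n_indeterminate, x$n_unlabeled))
  cat(sprintf("  confusion: TP %d  FP %d  TN %d  FN %d\n",
              x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  sensitivity %s (%d/%d), specificity %s (%d/%d)\n",
              fmt_pct(x$sensitivity), x$tp, x$tp + x$fn,
              fmt_pct(x$specificity), x$tn, x$tn + x$fp))
  cat("  decisive step:",
      paste(sprintf("%s %d", names(x$per_step), x$per_step), collapse = ", "),
      "\n")
  invisible(x)
}

#' Evaluate the activity step's three zones on a cohort
#'
#' Rule-in and rule-out performance of a threshold pair on the labeled,
#' activity-bearing subset of a cohort (see [derive_thresholds()] for the
#' zone conventions).
#'
#' @param cohort a labeled `mpsi_cohort`.
#' @param thresholds an [activity_thresholds()] object.
#' @return An `"mpsi_zones"` report.
#' @examples
#' evaluate_step2_zones(mpsi_cohort())
#' @export
evaluate_step2_zones <- function(cohort, thresholds = activity_thresholds()) {
  stopifnot(inherits(cohort, "mpsi_cohort"),
            inherits(thresholds, "mpsi_thresholds"))
  keep <- !is.na(cohort$idua_activity) & !is.na(cohort$phenotype)
  if (!any(keep)) {
    stop("no labeled records with an activity measurement", call. = FALSE)
  }
  lab <- binary_label(cohort$phenotype[keep])
  act <- cohort$idua_activity[keep]
  zone_report(thresholds, act[lab == "H"], act[lab == "non-H"])
}
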