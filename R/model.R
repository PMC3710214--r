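#' The three-step MPS I phenotype-severity prediction model
#'
#' Constructs the classifier that predicts, from data obtainable in the
#' first month of life, whether a newborn MPS I patient will develop the
#' severe Hurler phenotype (`H`, for whom early haematopoietic stem cell
#' transplantation is indicated) or an attenuated phenotype (`non-H`,
#' treated with enzyme replacement). Prediction proceeds in three steps,
#' each of which either decides or defers to the next:
#'
#' 1. \strong{Genotype}: both alleles on the severe-mutation list calls `H`.
#' 2. \strong{Residual IDUA activity} in cultured fibroblasts: at or below
#'    the lower threshold calls `H`; above the upper threshold calls
#'    `non-H`; the gray zone in between defers. A missing measurement also
#'    defers.
#' 3. \strong{Clinical findings}: upper respiratory tract obstruction or
#'    inguinal hernia present calls `H`; both known-absent calls `non-H`.
#'    Preterm births defer under the default policy.
#'
#' Patients undecided after all three steps are `indeterminate` — a
#' first-class verdict, never silently coerced.
#'
#' @param severe_list severe-mutation list (default: the packaged
#'   25-mutation list, [mpsi_severe_mutations()]).
#' @param thresholds an [activity_thresholds()] object (default 0.32/0.66
#'   nmol·mg^-1·hr^-1).
#' @param preterm_policy `"skip-clinical"` (default) or `"use-clinical"`;
#'   see [classify_by_clinical()].
#' @return An object of class `"mpsi_model"`.
#' @examples
#' m <- mpsi_model()
#' pred <- predict(m, mpsi_cohort())
#' table(pred$verdict)
#' @seealso [predict.mpsi_model()], [evaluate()], [derive_thresholds()]
#' @export
mpsi_model <- function(severe_list = mpsi_severe_mutations(),
                       thresholds = activity_thresholds(),
                       preterm_policy = c("skip-clinical", "use-clinical")) {
  stopifnot(inherits(thresholds, "mpsi_thresholds"))
  preterm_policy <- match.arg(preterm_policy)
  severe_list <- structure(unique(normalize_allele(as.character(severe_list))),
                           class = "mpsi_mutation_list")
  structure(list(severe_list = severe_list, thresholds = thresholds,
                 preterm_policy = preterm_policy),
            class = "mpsi_model")
}

#' @export
print.mpsi_model <- function(x, ...) {
  cat("MPS I phenotype-severity prediction model (genotype -> activity -> clinical)\n")
  cat(sprintf("  severe-mutation list: %d alleles\n", length(x$severe_list)))
  cat(sprintf("  activity thresholds:  %g / %g nmol/mg/hr\n",
              x$thresholds$lower, x$thresholds$upper))
  cat(sprintf("  preterm policy:       %s\n", x$preterm_policy))
  invisible(x)
}

#' Predict phenotype severity for a cohort
#'
#' Applies the three-step algorithm to every patient. Step order is fixed
#' and a decision is final: a severe-genotype verdict is never revisited by
#' activity or clinical data. Patients lacking an activity measurement skip
#' from step 1 directly to the clinical step.
#'
#' @param object an [mpsi_model()].
#' @param newdata an `mpsi_cohort` data.frame (see [read_cohort()]).
#' @param ... unused.
#' @return A data.frame of class `"mpsi_prediction"`, one row per patient:
#'   `patient_id`, `verdict` (`"H"`, `"non-H"`, `"indeterminate"`),
#'   `decisive_step` (`"genotype"`, `"activity"`, `"clinical"`, `"none"`),
#'   and the per-step outcomes `genotype_step`, `activity_step`,
#'   `clinical_step` (`NA` for steps not reached). The full audit trace is
#'   attached as `attr(, "trace")`, a list of per-patient data.frames with
#'   columns `step`, `verdict`, `rationale`.
#' @export
predict.mpsi_model <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "mpsi_cohort"))
  n <- nrow(newdata)
  verdict <- character(n); decisive <- character(n)
  g_step <- a_step <- c_step <- rep(NA_character_, n)
  trace <- vector("list", n)
  preterm <- !is_term(newdata)

  g_all <- classify_by_genotype(newdata, object$severe_list)
  for (i in seq_len(n)) {
    steps <- data.frame(step = character(0), verdict = character(0),
                        rationale = character(0))
    g_step[i] <- g_all[i]
    steps <- rbind(steps, data.frame(
      step = "genotype", verdict = g_all[i],
      rationale = if (g_all[i] == "H") {
        sprintf("both alleles (%s, %s) on the severe list",
                newdata$allele1[i], newdata$allele2[i])
      } else "at least one allele not on the severe list"))
    if (g_all[i] == "H") {
      verdict[i] <- "H"; decisive[i] <- "genotype"
      trace[[i]] <- steps
      next
    }

    act <- newdata$idua_activity[i]
    if (!is.na(act)) {
      za <- classify_by_activity(act, object$thresholds)
      a_step[i] <- za
      steps <- rbind(steps, data.frame(
        step = "activity", verdict = za,
        rationale = sprintf("activity %g vs zones (<= %g | <= %g | above)",
                            act, object$thresholds$lower,
                            object$thresholds$upper)))
      if (za != "intermediate") {
        verdict[i] <- za; decisive[i] <- "activity"
        trace[[i]] <- steps
        next
      }
    } else {
      steps <- rbind(steps, data.frame(
        step = "activity", verdict = "pass",
        rationale = "no activity measurement available"))
    }

    zc <- classify_by_clinical(newdata$urt_obstruction[i],
                               newdata$inguinal_hernia[i],
                               preterm[i], object$preterm_policy)
    c_step[i] <- zc
    steps <- rbind(steps, data.frame(
      step = "clinical", verdict = zc,
      rationale = sprintf("URT obstruction %s, inguinal hernia %s%s",
                          newdata$urt_obstruction[i],
                          newdata$inguinal_hernia[i],
                          if (preterm[i]) " (preterm)" else "")))
    if (zc %in% c("H", "non-H")) {
      verdict[i] <- zc; decisive[i] <- "clinical"
    } else {
      verdict[i] <- "indeterminate"; decisive[i] <- "none"
    }
    trace[[i]] <- steps
  }

  out <- data.frame(patient_id = newdata$patient_id, verdict = verdict,
                    decisive_step = decisive, genotype_step = g_step,
                    activity_step = a_step, clinical_step = c_step,
                    stringsAsFactors = FALSE)
  attr(out, "trace") <- setNames(trace, newdata$patient_id)
  class(out) <- c("mpsi_prediction", "data.frame")
  out
}

#' @export
print.mpsi_prediction <- function(x, ...) {
  cat(sprintf("Predictions for %d patients: %d H, %d non-H, %d indeterminate\n",
              nrow(x), sum(x$verdict == "H"), sum(x$verdict == "non-H"),
              sum(x$verdict == "indeterminate")))
  print(as.data.frame(x)[, c("patient_id", "verdict", "decisive_step")])
  invisible(x)
}

#' Summarize a model against a labeled cohort
#'
#' @param object an [mpsi_model()].
#' @param cohort a labeled `mpsi_cohort`; when supplied the summary reports
#'   the full internal-validation [evaluate()] result.
#' @param ... unused.
#' @return The model invisibly; prints the evaluation when a cohort is
#'   given.
#' @export
summary.mpsi_model <- function(object, cohort = NULL, ...) {
  print(object)
  if (!is.null(cohort)) {
    print(evaluate(cohort, predict(object, cohort)))
  }
  invisible(object)
}

#' Plot the activity zones of a model over a cohort
#'
#' Strip chart of residual IDUA activity by phenotype with the rule-in and
#' rule-out thresholds as dashed lines.
#'
#' @param x an [mpsi_model()].
#' @param cohort an `mpsi_cohort` with activity values.
#' @param ... passed to [graphics::stripchart()].
#' @return The model, invisibly.
#' @export
plot.mpsi_model <- function(x, cohort = mpsi_cohort(), ...) {
  keep <- !is.na(cohort$idua_activity) & !is.na(cohort$phenotype)
  act <- cohort$idua_activity[keep]
  phen <- factor(cohort$phenotype[keep], levels = c("H", "HS", "S"))
  graphics::stripchart(act ~ phen, vertical = TRUE, method = "jitter",
                       pch = 19, ylab = "Residual IDUA activity (nmol/mg/hr)",
                       xlab = "Assigned phenotype", ...)
  graphics::abline(h = c(x$thresholds$lower, x$thresholds$upper), lty = 2)
  invisible(x)
}

#' Export a prediction report as JSON
#'
#' Serializes predictions (with their audit traces) to the JSON report
#' format: an array of `{patient_id, verdict, decisive_step, trace: [{step,
#' verdict, rationale}]}` objects. The report structure is described by the
#' schema shipped at `inst/schema/prediction-report.json` and is checked
#' against it structurally before writing.
#'
#' @param predictions an `mpsi_prediction` (from [predict.mpsi_model()]).
#' @param path output path, or `NULL` to return the JSON string.
#' @return `path` (or the JSON string), invisibly.
#' @export
write_prediction_report <- function(predictions, path = NULL) {
  stopifnot(inherits(predictions, "mpsi_prediction"))
  trace <- attr(predictions, "trace")
  report <- lapply(seq_len(nrow(predictions)), function(i) {
    tr <- trace[[i]]
    list(patient_id = predictions$patient_id[i],
         verdict = predictions$verdict[i],
         decisive_step = predictions$decisive_step[i],
         trace = lapply(seq_len(nrow(tr)), function(j) {
           list(step = tr$step[j], verdict = tr$verdict[j],
                rationale = tr$rationale[j])
         }))
  })
  validate_prediction_report(report)
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(invisible(as.character(json)))
  writeLines(json, path)
  invisible(path)
}

# minimal structural validation against the shipped schema's requirements
validate_prediction_report <- function(report) {
  ok_verdict <- c("H", "non-H", "indeterminate")
  ok_step <- c("genotype", "activity", "clinical", "none")
  for (entry in report) {
    stopifnot(is.character(entry$patient_id), nzchar(entry$patient_id),
              entry$verdict %in% ok_verdict,
              entry$decisive_step %in% ok_step,
              (entry$verdict == "indeterminate") ==
                (entry$decisive_step == "none"),
              length(entry$trace) >= 1L)
    for (s in entry$trace) {
      stopifnot(s$step %in% c("genotype", "activity", "clinical"),
                is.character(s$verdict), is.character(s$rationale))
    }
  }
  invisible(TRUE)
}
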