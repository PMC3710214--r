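#' Severe-genotype test (algorithm step 1)
#'
#' A genotype predicts the Hurler phenotype when \emph{both} alleles are on
#' the severe-mutation list (homozygosity or compound heterozygosity for
#' listed mutations). The rule is one-sided: alleles absent from the list
#' are non-informative, never evidence for an attenuated phenotype, because
#' the effect of attenuated-associated mutations can vary with allelic
#' context and modifier genes. The test is symmetric in allele order.
#'
#' @param allele1,allele2 character vectors of alleles (normalized
#'   internally).
#' @param severe_list a severe-mutation list (see [read_mutation_list()]);
#'   defaults to the packaged 25-mutation list.
#' @return Logical vector: `TRUE` where both alleles are listed.
#' @examples
#' is_severe_genotype("p.W402X", "p.Q70X")   # TRUE
#' is_severe_genotype("p.A327P", "p.R383H")  # FALSE: p.R383H unlisted
#' @export
is_severe_genotype <- function(allele1, allele2,
                               severe_list = mpsi_severe_mutations()) {
  sev <- normalize_allele(as.character(severe_list))
  normalize_allele(allele1) %in% sev & normalize_allele(allele2) %in% sev
}

#' Genotype step verdicts for a cohort
#'
#' @param cohort an `mpsi_cohort` data.frame.
#' @param severe_list severe-mutation list.
#' @return Character vector, one per patient: `"H"` (both alleles listed) or
#'   `"pass"` (step cannot decide — never `"non-H"`).
#' @export
classify_by_genotype <- function(cohort,
                                 severe_list = mpsi_severe_mutations()) {
  ifelse(is_severe_genotype(cohort$allele1, cohort$allele2, severe_list),
         "H", "pass")
}

#' Activity thresholds for the three-zone enzyme step
#'
#' Bundles the rule-in (lower) and rule-out (upper) residual-activity
#' cut-offs, in nmol·mg^-1·hr^-1. Activity at or below `lower` calls Hurler
#' (the lower bound is inclusive); activity strictly above `upper` calls
#' non-Hurler; the half-open interval `(lower, upper]` is the indeterminate
#' gray zone. Packaged defaults are 0.32 and 0.66.
#'
#' @param lower,upper positive reals with `lower < upper`.
#' @return An object of class `"mpsi_thresholds"`.
#' @export
activity_thresholds <- function(lower = 0.32, upper = 0.66) {
  stopifnot(is.numeric(lower), is.numeric(upper),
            length(lower) == 1L, length(upper) == 1L,
            is.finite(lower), is.finite(upper), lower > 0, lower < upper)
  structure(list(lower = lower, upper = upper), class = "mpsi_thresholds")
}

#' @export
print.mpsi_thresholds <- function(x, ...) {
  cat(sprintf(
    "Activity thresholds (nmol/mg/hr): H-zone <= %g < gray zone <= %g < non-H zone\n",
    x$lower, x$upper))
  invisible(x)
}

#' Three-zone activity classification (algorithm step 2)
#'
#' @param activity numeric vector of residual IDUA activities
#'   (nmol·mg^-1·hr^-1); `NA` passes through as `NA`.
#' @param thresholds an [activity_thresholds()] object.
#' @return Character vector: `"H"` (activity <= lower), `"non-H"`
#'   (activity > upper) or `"intermediate"`.
#' @examples
#' classify_by_activity(c(0.25, 0.32, 0.43, 0.77), activity_thresholds())
#' @export
classify_by_activity <- function(activity, thresholds = activity_thresholds()) {
  stopifnot(inherits(thresholds, "mpsi_thresholds"))
  if (any(activity < 0, na.rm = TRUE)) {
    stop("negative activity is outside the assay domain", call. = FALSE)
  }
  if (any(!is.finite(activity) & !is.na(activity))) {
    stop("activity must be finite", call. = FALSE)
  }
  ifelse(is.na(activity), NA_character_,
         ifelse(activity <= thresholds$lower, "H",
                ifelse(activity > thresholds$upper, "non-H", "intermediate")))
}

#' Derive rule-in/rule-out activity cut-offs from labeled data
#'
#' Computes the two cut-offs that define the three activity zones:
#'
#' * lower (rule-in): the largest observed activity `v` such that every
#'   sample with activity `<= v` is Hurler — the highest cut point with
#'   100 percent observed rule-in specificity. Cross-class ties at a
#'   candidate break toward the smaller H-zone.
#' * upper (rule-out): the largest observed Hurler activity, so that no
#'   Hurler sample lies above it — 100 percent observed rule-out
#'   sensitivity.
#'
#' Boundaries are reported at observed data values, not interpolated
#' midpoints. If the lowest observed value is non-H the classes are not
#' separable at any point: `separable = FALSE` and the H-zone collapses to
#' width 0 (`lower = 0`).
#'
#' @param activities numeric vector of observed activities.
#' @param labels parallel vector of labels; `"H"` is the positive class,
#'   anything else (`"non-H"`, `"HS"`, `"S"`) the negative class.
#' @return An object of class `"mpsi_zones"`: `thresholds`,
#'   `rule_in_sensitivity`, `rule_in_specificity`, `rule_out_sensitivity`,
#'   `rule_out_specificity` (fractions), `n_intermediate`, `n_pos`, `n_neg`,
#'   `separable`.
#' @examples
#' coh <- mpsi_cohort()
#' keep <- !is.na(coh$idua_activity) & !is.na(coh$phenotype)
#' derive_thresholds(coh$idua_activity[keep], coh$phenotype[keep])
#' @export
derive_thresholds <- function(activities, labels) {
  stopifnot(length(activities) == length(labels),
            all(is.finite(activities)), all(activities >= 0))
  lab <- binary_label(as.character(labels))
  lab[is.na(lab)] <- "non-H"
  if (!any(lab == "H") || !any(lab == "non-H")) {
    stop("derive_thresholds needs at least one sample in each class",
         call. = FALSE)
  }
  pos <- activities[lab == "H"]
  neg <- activities[lab == "non-H"]

  upper <- max(pos)
  # candidate rule-in boundaries: observed H values strictly below every non-H
  cand <- pos[pos < min(neg)]
  separable <- length(cand) > 0L
  lower <- if (separable) max(cand) else 0
  if (lower >= upper) {
    # degenerate: the gray zone vanishes; keep lower strictly below upper
    lower <- if (separable) upper else 0
  }
  thr <- if (separable && lower < upper) {
    activity_thresholds(lower, upper)
  } else {
    structure(list(lower = lower, upper = upper), class = "mpsi_thresholds")
  }
  zone_report(thr, pos, neg, separable = separable)
}

# Performance of a threshold pair on observed labeled activities.
zone_report <- function(thresholds, pos, neg, separable = TRUE) {
  zp <- classify_by_activity_raw(pos, thresholds)
  zn <- classify_by_activity_raw(neg, thresholds)
  structure(list(
    thresholds = thresholds,
    # rule-in: call H iff activity <= lower
    rule_in_sensitivity = mean(zp == "H"),
    rule_in_specificity = mean(zn != "H"),
    # rule-out: call non-H iff activity > upper
    rule_out_sensitivity = mean(zp != "non-H"),
    rule_out_specificity = mean(zn == "non-H"),
    n_intermediate = sum(zp == "intermediate") + sum(zn == "intermediate"),
    n_pos = length(pos), n_neg = length(neg),
    separable = separable
  ), class = "mpsi_zones")
}

# zone membership without the constructor's lower < upper requirement
classify_by_activity_raw <- function(activity, thresholds) {
  ifelse(activity <= thresholds$lower, "H",
         ifelse(activity > thresholds$upper, "non-H", "intermediate"))
}

#' @export
print.mpsi_zones <- function(x, ...) {
  cat("Three-zone activity classification\n")
  cat(sprintf("  thresholds: lower %g, upper %g (nmol/mg/hr)%s\n",
              x$thresholds$lower, x$thresholds$upper,
              if (x$separable) "" else "  [classes not separable]"))
  cat(sprintf("  rule-in  (<= lower -> H):     sensitivity %d%%, specificity %d%%\n",
              percent_int(x$rule_in_sensitivity),
              percent_int(x$rule_in_specificity)))
  cat(sprintf("  rule-out (> upper -> non-H):  sensitivity %d%%, specificity %d%%\n",
              percent_int(x$rule_out_sensitivity),
              percent_int(x$rule_out_specificity)))
  cat(sprintf("  gray zone: %d of %d samples\n", x$n_intermediate,
              x$n_pos + x$n_neg))
  invisible(x)
}

# integer percent, round half-up (82.35 -> 82, 55.55.. -> 56, 88.9 -> 89)
percent_int <- function(frac) {
  if (is.na(frac)) return(NA_integer_)
  as.integer(floor(frac * 100 + 0.5))
}

#' Clinical-findings tiebreak (algorithm step 3)
#'
#' Intermediate patients are classified from two early-life findings:
#' signs of upper respiratory tract obstruction (excessive snoring,
#' continuously runny nose, obstructive apneas, feeding difficulty from
#' nasal obstruction in the first month) and inguinal hernia. Either finding
#' present calls Hurler; both known-absent calls non-Hurler; otherwise the
#' step passes through (absence of evidence on one feature is not evidence
#' of absence). Preterm births (<37+0 weeks) pass through under the default
#' policy because prematurity itself causes both findings.
#'
#' @param urt,hernia character vectors coded `"present"`, `"absent"`,
#'   `"unknown"`.
#' @param preterm logical vector; `TRUE` marks birth before 37+0 weeks.
#' @param preterm_policy `"skip-clinical"` (default: preterm passes through)
#'   or `"use-clinical"`.
#' @return Character vector: `"H"`, `"non-H"` or `"pass"`.
#' @examples
#' classify_by_clinical("present", "unknown", preterm = FALSE)  # "H"
#' classify_by_clinical("absent", "absent", preterm = FALSE)    # "non-H"
#' classify_by_clinical("absent", "unknown", preterm = FALSE)   # "pass"
#' @export
classify_by_clinical <- function(urt, hernia, preterm,
                                 preterm_policy = c("skip-clinical",
                                                    "use-clinical")) {
  preterm_policy <- match.arg(preterm_policy)
  stopifnot(all(urt %in% c("present", "absent", "unknown")),
            all(hernia %in% c("present", "absent", "unknown")))
  n <- max(length(urt), length(hernia), length(preterm))
  urt <- rep_len(urt, n); hernia <- rep_len(hernia, n)
  preterm <- rep_len(preterm, n)
  verdict <- ifelse(urt == "present" | hernia == "present", "H",
                    ifelse(urt == "absent" & hernia == "absent",
                           "non-H", "pass"))
  if (preterm_policy == "skip-clinical") {
    verdict[preterm] <- "pass"
  }
  verdict
}
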