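#' Screen clinical features for association with phenotype severity
#'
#' The univariate screen that selected the clinical step's features: for
#' each tri-state finding, records born before 37+0 weeks are excluded
#' (prematurity itself causes respiratory signs and hernias), unknowns are
#' dropped, and the 2x2 table of phenotype class (H vs non-H) against
#' finding (present vs absent) is tested with the two-sided exact test. The
#' p-value is only computed when at least `min_n` informative records are
#' available and both table margins are non-zero; sparse features are
#' reported with `NA`, mirroring how rarely-documented newborn findings
#' (hepatomegaly, hydrocephalus, ...) cannot be screened retrospectively.
#'
#' @param cohort a labeled `mpsi_cohort`.
#' @param features character vector of tri-state column names to screen
#'   (default: all tri-state columns in the cohort).
#' @param min_n minimum informative records for a p-value (default 10).
#' @return A data.frame of class `"mpsi_screen"`, one row per feature,
#'   sorted by p-value (`NA` last): `feature`, `n_available`, and the
#'   contingency cells `h_present`, `h_absent`, `nonh_present`,
#'   `nonh_absent`, `p_value`.
#' @examples
#' feature_screen(mpsi_cohort())
#' @export
feature_screen <- function(cohort, features = tristate_columns(cohort),
                           min_n = 10L) {
  stopifnot(inherits(cohort, "mpsi_cohort"),
            all(features %in% names(cohort)))
  term <- is_term(cohort)
  lab <- binary_label(cohort$phenotype)
  rows <- lapply(features, function(f) {
    v <- cohort[[f]]
    use <- term & !is.na(lab) & v %in% c("present", "absent")
    a <- sum(use & lab == "H" & v == "present")
    b <- sum(use & lab == "H" & v == "absent")
    c_ <- sum(use & lab == "non-H" & v == "present")
    d <- sum(use & lab == "non-H" & v == "absent")
    n <- a + b + c_ + d
    margins_ok <- (a + b) > 0 && (c_ + d) > 0 && (a + c_) > 0 && (b + d) > 0
    p <- if (n >= min_n && margins_ok) {
      fisher_exact_two_sided(a, b, c_, d)
    } else {
      NA_real_
    }
    data.frame(feature = f, n_available = n, h_present = a, h_absent = b,
               nonh_present = c_, nonh_absent = d, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mpsi_screen", "data.frame")
  out
}

#' @export
print.mpsi_screen <- function(x, ...) {
  cat("Clinical-feature screen (term births, H vs non-H, two-sided exact test)\n")
  y <- as.data.frame(x)
  y$p_value <- ifelse(is.na(y$p_value), "not computed",
                      sprintf("%.4g", y$p_value))
  print(y, row.names = FALSE)
  invisible(x)
}
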