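#' Read a patient cohort file
#'
#' Reads a delimited cohort table (comma or tab, auto-detected from the
#' header line) with one row per patient. Expected header columns:
#' \code{patient_id, phenotype, gestational_age, allele1, allele2,
#' idua_activity, urt_obstruction, inguinal_hernia}, followed by zero or
#' more \code{feat_<name>} columns holding additional tri-state clinical
#' findings.
#'
#' Cell conventions follow clinical-chart coding: phenotype is one of
#' \code{H} (Hurler), \code{HS} (Hurler-Scheie), \code{S} (Scheie) or
#' \code{X} (unknown); tri-state findings are \code{+} (present), \code{-}
#' (absent), \code{X} (not available); \code{X} or the empty string mark any
#' other missing value. Unknown is kept distinct from absent throughout.
#'
#' @param path path to the cohort file (UTF-8).
#' @return A data.frame of class `"mpsi_cohort"` with columns `patient_id`
#'   (character), `phenotype` (`"H"`, `"HS"`, `"S"` or `NA`), `ga_weeks`,
#'   `ga_days` (integer, `NA` when unknown), `allele1`, `allele2` (canonical
#'   allele strings), `idua_activity` (numeric, nmol·mg^-1·hr^-1, `NA` when
#'   not measured), and tri-state finding columns coded `"present"`,
#'   `"absent"`, `"unknown"`.
#' @examples
#' coh <- mpsi_cohort()
#' nrow(coh)                  # 30
#' table(coh$phenotype)       # 17 H, 6 HS, 7 S
#' @seealso [write_cohort()], [mpsi_cohort()] for the packaged cohort.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cohort file not found: %s", path), call. = FALSE)
  }
  header <- readLines(path, n = 1L, encoding = "UTF-8")
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- read.table(path, header = TRUE, sep = sep, colClasses = "character",
                    check.names = FALSE, na.strings = NULL, quote = "\"",
                    encoding = "UTF-8", strip.white = TRUE)
  required <- c("patient_id", "phenotype", "gestational_age", "allele1",
                "allele2", "idua_activity", "urt_obstruction",
                "inguinal_hernia")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop(sprintf("cohort file lacks required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  feat_cols <- grep("^feat_", names(raw), value = TRUE)

  id <- trimws(raw$patient_id)
  if (anyDuplicated(id)) {
    stop(sprintf("duplicate patient_id: %s",
                 paste(unique(id[duplicated(id)]), collapse = ", ")),
         call. = FALSE)
  }

  phen <- toupper(trimws(raw$phenotype))
  bad <- !phen %in% c("H", "HS", "S", "X", "")
  if (any(bad)) {
    stop(sprintf("unknown phenotype label(s): %s",
                 paste(unique(phen[bad]), collapse = ", ")), call. = FALSE)
  }
  phen[phen %in% c("X", "")] <- NA_character_

  ga <- parse_gestational_age(raw$gestational_age)

  act_raw <- trimws(raw$idua_activity)
  act <- rep(NA_real_, nrow(raw))
  has_act <- !(toupper(act_raw) == "X" | act_raw == "")
  act[has_act] <- suppressWarnings(as.numeric(act_raw[has_act]))
  if (any(has_act & is.na(act))) {
    stop(sprintf("unparseable idua_activity for patient(s): %s",
                 paste(id[has_act & is.na(act)], collapse = ", ")),
         call. = FALSE)
  }
  if (any(act < 0, na.rm = TRUE)) {
    stop("negative idua_activity is not a valid enzyme measurement",
         call. = FALSE)
  }

  out <- data.frame(
    patient_id = id,
    phenotype = phen,
    ga_weeks = ga$weeks,
    ga_days = ga$days,
    allele1 = normalize_allele(raw$allele1),
    allele2 = normalize_allele(raw$allele2),
    idua_activity = act,
    stringsAsFactors = FALSE
  )
  for (col in c("urt_obstruction", "inguinal_hernia", feat_cols)) {
    out[[col]] <- parse_tristate(raw[[col]], col)
  }
  class(out) <- c("mpsi_cohort", "data.frame")
  out
}

parse_tristate <- function(x, col) {
  s <- toupper(trimws(x))
  out <- rep(NA_character_, length(s))
  out[s == "+"] <- "present"
  out[s == "-"] <- "absent"
  out[s %in% c("X", "")] <- "unknown"
  bad <- is.na(out)
  if (any(bad)) {
    stop(sprintf("invalid tri-state value(s) in %s: %s (expected +, -, X)",
                 col, paste(unique(s[bad]), collapse = ", ")), call. = FALSE)
  }
  out
}

#' Write a patient cohort file
#'
#' Inverse of [read_cohort()]: serializes a cohort back to the delimited
#' text format, using `X` for all missing values and `+`/`-`/`X` tri-state
#' coding. `read_cohort(write_cohort(x, f))` reproduces `x` field by field.
#'
#' @param cohort an `mpsi_cohort` data.frame.
#' @param path output path.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, sep = ",") {
  stopifnot(inherits(cohort, "mpsi_cohort"))
  tri_cols <- tristate_columns(cohort)
  out <- data.frame(
    patient_id = cohort$patient_id,
    phenotype = ifelse(is.na(cohort$phenotype), "X", cohort$phenotype),
    gestational_age = format_gestational_age(cohort$ga_weeks, cohort$ga_days),
    allele1 = cohort$allele1,
    allele2 = cohort$allele2,
    idua_activity = ifelse(is.na(cohort$idua_activity), "X",
                           format(cohort$idua_activity, trim = TRUE)),
    stringsAsFactors = FALSE
  )
  for (col in tri_cols) {
    out[[col]] <- c(present = "+", absent = "-", unknown = "X")[cohort[[col]]]
  }
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

tristate_columns <- function(cohort) {
  c("urt_obstruction", "inguinal_hernia",
    grep("^feat_", names(cohort), value = TRUE))
}

#' The packaged 30-patient MPS I cohort
#'
#' The reference cohort used to construct and internally validate the
#' prediction algorithm: 30 MPS I patients (17 Hurler, 6 Hurler-Scheie,
#' 7 Scheie), phenotyped at >18 months from the clinical course. Residual
#' fibroblast IDUA activity is available for 18 patients; upper respiratory
#' tract obstruction and inguinal hernia in the first month of life are
#' recorded as tri-state findings.
#'
#' @return An `mpsi_cohort` data.frame with 30 rows (see [read_cohort()]).
#' @export
mpsi_cohort <- function() {
  read_cohort(system.file("extdata", "mpsi_cohort.csv",
                          package = "mpsipredict", mustWork = TRUE))
}

#' @export
print.mpsi_cohort <- function(x, ...) {
  lab <- table(factor(x$phenotype, levels = c("H", "HS", "S")), useNA = "no")
  cat(sprintf("MPS I cohort: %d patients (%d H, %d HS, %d S, %d unlabeled)\n",
              nrow(x), lab[["H"]], lab[["HS"]], lab[["S"]],
              sum(is.na(x$phenotype))))
  cat(sprintf("IDUA activity available for %d\n",
              sum(!is.na(x$idua_activity))))
  print(as.data.frame(head(x, 10)))
  if (nrow(x) > 10) cat(sprintf("... and %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

# H vs non-H dichotomy used throughout evaluation: HS and S map to non-H.
binary_label <- function(phenotype) {
  ifelse(is.na(phenotype), NA_character_,
         ifelse(phenotype == "H", "H", "non-H"))
}

is_term <- function(cohort) {
  total <- 7L * cohort$ga_weeks + cohort$ga_days
  is.na(total) | total >= 259L
}
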