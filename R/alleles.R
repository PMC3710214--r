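#' Normalize an IDUA allele string
#'
#' Variant alleles appear in clinical reports with inconsistent spacing,
#' case and substitution glyphs ("c.474-2A > G", "P.w402x"). This function
#' reduces each raw string to a canonical form so that severe-list membership
#' is an exact string comparison. The namespace is taken from the mandatory
#' prefix: \code{"p."} for protein-level notation, \code{"c."} for
#' coding-DNA-level notation. Tokens are compared case-insensitively (stored
#' uppercase); no further HGVS grammar validation is attempted, because list
#' matching needs opaque exact keys rather than parsed variants.
#'
#' @param raw character vector of raw allele strings, each with a
#'   \code{"p."} or \code{"c."} prefix (any case, surrounding whitespace
#'   allowed).
#' @return A character vector of canonical alleles, e.g. \code{"p.W402X"},
#'   \code{"c.134DEL12"}. Normalization is idempotent:
#'   \code{normalize_allele(normalize_allele(x))} equals
#'   \code{normalize_allele(x)}.
#' @examples
#' normalize_allele(c(" p.W402X ", "c.474-2A > G", "P.w402x"))
#' @seealso [read_mutation_list()], [is_severe_genotype()]
#' @export
normalize_allele <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  stopifnot(is.character(raw))
  out <- vapply(raw, normalize_allele1, character(1), USE.NAMES = FALSE)
  out
}

normalize_allele1 <- function(raw) {
  s <- gsub("\\s+", "", raw)
  # fullwidth '>' occurs in copy-pasted reports; fold to ASCII
  s <- gsub("＞", ">", s)
  if (!nzchar(s)) {
    stop("malformed allele: empty string", call. = FALSE)
  }
  prefix <- tolower(substr(s, 1, 2))
  if (nchar(s) < 3L || !prefix %in% c("p.", "c.")) {
    stop(sprintf("malformed allele: %s (expected a 'p.' or 'c.' prefix)",
                 dQuote(raw)), call. = FALSE)
  }
  token <- toupper(substr(s, 3, nchar(s)))
  paste0(prefix, token)
}

#' Namespace and token of a canonical allele
#'
#' @param allele character vector of canonical alleles (see
#'   [normalize_allele()]).
#' @return `allele_namespace()` returns `"protein"` or `"coding"`;
#'   `allele_token()` returns the prefix-free token.
#' @examples
#' allele_namespace(normalize_allele("p.W402X"))
#' allele_token(normalize_allele("c.134del12"))
#' @export
allele_namespace <- function(allele) {
  ifelse(substr(allele, 1, 2) == "p.", "protein", "coding")
}

#' @rdname allele_namespace
#' @export
allele_token <- function(allele) {
  substr(allele, 3, nchar(allele))
}

#' Read a severe-mutation list
#'
#' Reads a plain-text list of alleles (one per line, \code{#} comments and
#' blank lines ignored), normalizes each and returns the deduplicated set.
#' Homozygosity or compound heterozygosity for alleles on this list is the
#' genotype-level Hurler rule (step 1 of the prediction algorithm).
#'
#' @param path path to the list file.
#' @return Character vector of unique canonical alleles, in first-appearance
#'   order, of class `"mpsi_mutation_list"`.
#' @examples
#' sev <- mpsi_severe_mutations()
#' length(sev)  # 25
#' @seealso [mpsi_severe_mutations()] for the packaged default list.
#' @export
read_mutation_list <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("mutation list file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  alleles <- character(0)
  for (i in keep) {
    a <- tryCatch(normalize_allele1(lines[i]), error = function(e) {
      stop(sprintf("%s (line %d of %s)", conditionMessage(e), i, path),
           call. = FALSE)
    })
    alleles <- c(alleles, a)
  }
  structure(unique(alleles), class = "mpsi_mutation_list")
}

#' The packaged severe-mutation list
#'
#' The 25 IDUA mutations reported in the literature to reliably predict a
#' Hurler phenotype when both alleles carry one of them.
#'
#' @return Character vector of 25 canonical alleles
#'   (class `"mpsi_mutation_list"`).
#' @export
mpsi_severe_mutations <- function() {
  read_mutation_list(system.file("extdata", "severe_mutations.txt",
                                 package = "mpsipredict", mustWork = TRUE))
}

#' @export
print.mpsi_mutation_list <- function(x, ...) {
  cat(sprintf("Severe-mutation list: %d alleles\n", length(x)))
  print(unclass(x))
  invisible(x)
}
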