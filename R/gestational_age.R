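#' Parse gestational age strings
#'
#' Gestational age is recorded as completed weeks plus days, e.g.
#' \code{"37 + 0"} or \code{"33+6"}. \code{"X"} or the empty string mark a
#' missing value. Term birth is defined as 37+0 weeks (259 days) or later;
#' clinical signs of earlier births are treated as potentially confounded by
#' prematurity. Records with unknown gestational age are treated as term
#' (the population prior) but flagged via `known = FALSE`.
#'
#' @param raw character vector of `"W + D"` strings or missing markers.
#' @return A data.frame with one row per input: `weeks`, `days`,
#'   `total_days` (all `NA` when unknown), `known` (logical), and `term`
#'   (logical; `TRUE` for unknown by policy).
#' @examples
#' parse_gestational_age(c("37 + 0", "33 + 6", "X"))
#' @export
parse_gestational_age <- function(raw) {
  n <- length(raw)
  weeks <- days <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    s <- trimws(raw[i])
    if (is.na(s) || s == "" || toupper(s) == "X") next
    m <- regmatches(s, regexec("^([0-9]+)\\s*\\+\\s*([0-9]+)$", s))[[1]]
    if (length(m) != 3L) {
      stop(sprintf("cannot parse gestational age: %s", dQuote(raw[i])),
           call. = FALSE)
    }
    w <- as.integer(m[2]); d <- as.integer(m[3])
    if (d > 6L) {
      stop(sprintf("gestational-age days must be 0-6: %s", dQuote(raw[i])),
           call. = FALSE)
    }
    if (w < 20L) {
      stop(sprintf("gestational age below 20 weeks: %s", dQuote(raw[i])),
           call. = FALSE)
    }
    weeks[i] <- w; days[i] <- d
  }
  total <- 7L * weeks + days
  data.frame(weeks = weeks, days = days, total_days = total,
             known = !is.na(total),
             term = is.na(total) | total >= 259L)
}

format_gestational_age <- function(weeks, days) {
  ifelse(is.na(weeks), "X", paste(weeks, "+", days))
}
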