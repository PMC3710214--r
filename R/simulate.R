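#' Configuration for the synthetic-cohort generator
#'
#' Parameters of the generative model behind [simulate_cohort()]. Defaults
#' are moment-matched to the packaged 30-patient reference cohort:
#' phenotype mix 17:6:7 (H:HS:S); 14 of 17 Hurler patients carrying two
#' severe-list alleles; per-phenotype log-normal residual activities whose
#' central mass reproduces the observed per-phenotype ranges (H roughly
#' 0.23-0.58, HS straddling the gray zone, S roughly 1.05-1.70
#' nmol·mg^-1·hr^-1); clinical-sign prevalences equal to the observed
#' term-cohort fractions; and per-field missingness at the observed rates.
#'
#' @param n_patients cohort size (default 30).
#' @param phenotype_probs named numeric simplex over `H`, `HS`, `S`.
#' @param severe_allele_pool,attenuated_allele_pool allele pools to draw
#'   genotypes from; the attenuated pool must be disjoint from the severe
#'   list in use.
#' @param p_both_severe_given_H probability that a Hurler patient carries
#'   two severe-pool alleles (default 14/17). Non-H patients never do.
#' @param activity_distributions named list per phenotype, each
#'   `c(meanlog, sdlog)` on the nmol·mg^-1·hr^-1 scale.
#' @param feature_prevalence named list per finding, each `c(H = , nonH = )`
#'   Bernoulli rates.
#' @param missingness named rates (between 0 and 1) for `idua_activity`,
#'   `urt_obstruction`, `inguinal_hernia`, `gestational_age`.
#' @param preterm_rate fraction of births before 37+0 weeks (default 3/30).
#' @param seed integer RNG seed.
#' @return A list of class `"mpsi_sim_config"`.
#' @export
sim_config <- function(n_patients = 30L,
                       phenotype_probs = c(H = 17, HS = 6, S = 7) / 30,
                       severe_allele_pool = c("p.W402X", "p.Q70X", "p.L218P",
                                              "c.134del12", "p.A327P"),
                       attenuated_allele_pool = c("p.R383H", "p.P533R",
                                                  "p.N348K", "p.D315Y",
                                                  "p.R505G", "c.474-2A>G",
                                                  "p.A367E", "c.1650del117",
                                                  "c.494-1G>A", "p.H425fs"),
                       p_both_severe_given_H = 14 / 17,
                       activity_distributions = list(
                         H = c(meanlog = -1.05, sdlog = 0.31),
                         HS = c(meanlog = -0.13, sdlog = 0.65),
                         S = c(meanlog = 0.30, sdlog = 0.23)),
                       feature_prevalence = list(
                         urt_obstruction = c(H = 7 / 9, nonH = 1 / 10),
                         inguinal_hernia = c(H = 4 / 9, nonH = 0 / 10)),
                       missingness = c(idua_activity = 12 / 30,
                                       urt_obstruction = 11 / 30,
                                       inguinal_hernia = 9 / 30,
                                       gestational_age = 3 / 30),
                       preterm_rate = 3 / 30,
                       seed = 1L) {
  stopifnot(n_patients >= 1L,
            length(phenotype_probs) == 3L,
            abs(sum(phenotype_probs) - 1) < 1e-8,
            all(phenotype_probs >= 0),
            p_both_severe_given_H >= 0, p_both_severe_given_H <= 1,
            all(unlist(missingness) >= 0), all(unlist(missingness) <= 1),
            preterm_rate >= 0, preterm_rate <= 1,
            all(vapply(activity_distributions,
                       function(d) d[["sdlog"]] > 0, logical(1))))
  structure(list(
    n_patients = as.integer(n_patients),
    phenotype_probs = phenotype_probs,
    severe_allele_pool = normalize_allele(severe_allele_pool),
    attenuated_allele_pool = normalize_allele(attenuated_allele_pool),
    p_both_severe_given_H = p_both_severe_given_H,
    activity_distributions = activity_distributions,
    feature_prevalence = feature_prevalence,
    missingness = missingness,
    preterm_rate = preterm_rate,
    seed = as.integer(seed)
  ), class = "mpsi_sim_config")
}

#' Simulate a synthetic MPS I cohort
#'
#' Draws an artificial cohort with the statistical structure the prediction
#' algorithm assumes: phenotype labels from the configured mix, genotypes
#' such that only Hurler patients can carry two severe-pool alleles,
#' phenotype-conditional log-normal residual activities, phenotype-dependent
#' Bernoulli clinical findings, and per-field missingness. Ground-truth
#' labels are emitted in the phenotype column so simulated cohorts flow
#' through the same evaluation path as the packaged fixture. Reproducible:
#' the configured seed fully determines the output.
#'
#' @param config an [sim_config()].
#' @return An `mpsi_cohort` data.frame.
#' @examples
#' coh <- simulate_cohort(sim_config(n_patients = 50, seed = 7))
#' table(coh$phenotype)
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "mpsi_sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  phen <- sample(c("H", "HS", "S"), n, replace = TRUE,
                 prob = config$phenotype_probs)
  is_h <- phen == "H"

  # gestational age
  preterm <- runif(n) < config$preterm_rate
  weeks <- ifelse(preterm, sample(33:36, n, replace = TRUE),
                  sample(37:41, n, replace = TRUE))
  days <- sample(0:6, n, replace = TRUE)
  ga_missing <- runif(n) < config$missingness[["gestational_age"]]
  weeks[ga_missing] <- NA_integer_
  days[ga_missing] <- NA_integer_

  # genotypes: H draws two severe-pool alleles with the configured
  # probability and otherwise two attenuated alleles; non-H never carries
  # two severe alleles
  sev <- config$severe_allele_pool
  att <- config$attenuated_allele_pool
  a1 <- a2 <- character(n)
  both_severe <- is_h & runif(n) < config$p_both_severe_given_H
  for (i in seq_len(n)) {
    if (both_severe[i]) {
      a1[i] <- sample(sev, 1); a2[i] <- sample(sev, 1)
    } else if (is_h[i]) {
      a1[i] <- sample(att, 1); a2[i] <- sample(att, 1)
    } else {
      a1[i] <- if (runif(1) < 0.5) sample(sev, 1) else sample(att, 1)
      a2[i] <- sample(att, 1)
    }
  }

  # phenotype-conditional activities, then missingness mask
  act <- numeric(n)
  for (ph in c("H", "HS", "S")) {
    d <- config$activity_distributions[[ph]]
    k <- sum(phen == ph)
    if (k) act[phen == ph] <- rlnorm(k, d[["meanlog"]], d[["sdlog"]])
  }
  act[runif(n) < config$missingness[["idua_activity"]]] <- NA_real_

  draw_finding <- function(name) {
    rate <- config$feature_prevalence[[name]]
    p <- ifelse(is_h, rate[["H"]], rate[["nonH"]])
    v <- ifelse(runif(n) < p, "present", "absent")
    v[runif(n) < config$missingness[[name]]] <- "unknown"
    v
  }
  urt <- draw_finding("urt_obstruction")
  hernia <- draw_finding("inguinal_hernia")

  out <- data.frame(
    patient_id = sprintf("S%03d", seq_len(n)),
    phenotype = phen,
    ga_weeks = as.integer(weeks), ga_days = as.integer(days),
    allele1 = a1, allele2 = a2,
    idua_activity = round(act, 3),
    urt_obstruction = urt, inguinal_hernia = hernia,
    stringsAsFactors = FALSE
  )
  class(out) <- c("mpsi_cohort", "data.frame")
  out
}

#' Threshold-recovery experiment on simulated cohorts
#'
#' Repeatedly simulates a cohort, re-derives the activity cut-offs from the
#' labeled simulated activities, evaluates the full three-step algorithm
#' with the derived thresholds, and summarizes the recovered boundaries and
#' performance across replicates. Replicate `r` uses seed `seed + r - 1`.
#'
#' @param config an [sim_config()]; its seed is the base seed.
#' @param n_reps number of replicates (>= 1).
#' @return A list of class `"mpsi_recovery"`: `per_rep` (data.frame with
#'   `rep`, `lower`, `upper`, `separable`, `n_intermediate`, `sensitivity`,
#'   `specificity`, `n_indeterminate`) and `summary` (mean and sd of each
#'   numeric column).
#' @export
recovery_experiment <- function(config = sim_config(), n_reps = 20L) {
  stopifnot(inherits(config, "mpsi_sim_config"), n_reps >= 1L)
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    coh <- simulate_cohort(cfg)
    keep <- !is.na(coh$idua_activity) & !is.na(coh$phenotype)
    zones <- derive_thresholds(coh$idua_activity[keep], coh$phenotype[keep])
    model <- mpsi_model(severe_list = config$severe_allele_pool,
                        thresholds = zones$thresholds)
    ev <- evaluate(coh, predict(model, coh))
    rows[[r]] <- data.frame(
      rep = r,
      lower = zones$thresholds$lower, upper = zones$thresholds$upper,
      separable = zones$separable, n_intermediate = zones$n_intermediate,
      sensitivity = ev$sensitivity, specificity = ev$specificity,
      n_indeterminate = ev$n_indeterminate)
  }
  per_rep <- do.call(rbind, rows)
  num <- c("lower", "upper", "n_intermediate", "sensitivity",
           "specificity", "n_indeterminate")
  summary <- data.frame(
    quantity = num,
    mean = vapply(per_rep[num], function(v) mean(v, na.rm = TRUE),
                  numeric(1)),
    sd = vapply(per_rep[num], function(v) stats::sd(v, na.rm = TRUE),
                numeric(1)))
  rownames(summary) <- NULL
  structure(list(per_rep = per_rep, summary = summary),
            class = "mpsi_recovery")
}

#' @export
print.mpsi_recovery <- function(x, ...) {
  cat(sprintf("Threshold-recovery experiment: %d replicates\n",
              nrow(x$per_rep)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Read a flat key-value simulation config file
#'
#' Lines of the form `key = value` (comma-separated vectors allowed; `#`
#' comments ignored). Recognized keys: `n_patients`, `seed`, `preterm_rate`,
#' `p_both_severe_given_H`, `phenotype_probs` (3 values H,HS,S),
#' `severe_allele_pool`, `attenuated_allele_pool` (allele lists),
#' `missingness_<field>`, `activity_<phenotype>` (meanlog, sdlog),
#' `prevalence_<finding>` (H rate, non-H rate). Unset keys keep the
#' [sim_config()] defaults.
#'
#' @param path config file path.
#' @return An `mpsi_sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  lines <- sub("#.*$", "", readLines(path, warn = FALSE))
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) {
    stop(sprintf("cannot parse config line: %s", dQuote(lines[bad][1])),
         call. = FALSE)
  }
  keys <- vapply(kv, function(p) trimws(p[1]), character(1))
  vals <- lapply(kv, function(p) trimws(strsplit(p[2], ",")[[1]]))
  names(vals) <- keys

  args <- list()
  num <- function(v) as.numeric(v)
  if ("n_patients" %in% keys) args$n_patients <- as.integer(vals$n_patients)
  if ("seed" %in% keys) args$seed <- as.integer(vals$seed)
  if ("preterm_rate" %in% keys) args$preterm_rate <- num(vals$preterm_rate)
  if ("p_both_severe_given_H" %in% keys) {
    args$p_both_severe_given_H <- num(vals$p_both_severe_given_H)
  }
  if ("phenotype_probs" %in% keys) {
    args$phenotype_probs <- setNames(num(vals$phenotype_probs),
                                     c("H", "HS", "S"))
  }
  if ("severe_allele_pool" %in% keys) {
    args$severe_allele_pool <- vals$severe_allele_pool
  }
  if ("attenuated_allele_pool" %in% keys) {
    args$attenuated_allele_pool <- vals$attenuated_allele_pool
  }
  defaults <- sim_config()
  miss <- defaults$missingness
  for (f in names(miss)) {
    k <- paste0("missingness_", f)
    if (k %in% keys) miss[[f]] <- num(vals[[k]])
  }
  args$missingness <- miss
  act <- defaults$activity_distributions
  for (ph in names(act)) {
    k <- paste0("activity_", ph)
    if (k %in% keys) {
      act[[ph]] <- setNames(num(vals[[k]]), c("meanlog", "sdlog"))
    }
  }
  args$activity_distributions <- act
  prev <- defaults$feature_prevalence
  for (f in names(prev)) {
    k <- paste0("prevalence_", f)
    if (k %in% keys) prev[[f]] <- setNames(num(vals[[k]]), c("H", "nonH"))
  }
  args$feature_prevalence <- prev
  do.call(sim_config, args)
}
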