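# Build a small cohort through the file interface so every in-code fixture
# exercises the same parsing path as user data.
make_cohort <- function(patient_id, phenotype = "X", gestational_age = "40 + 0",
                        allele1 = "p.W402X", allele2 = "p.R383H",
                        idua_activity = "X", urt_obstruction = "X",
                        inguinal_hernia = "X", ...) {
  df <- data.frame(patient_id = patient_id, phenotype = phenotype,
                   gestational_age = gestational_age, allele1 = allele1,
                   allele2 = allele2, idua_activity = idua_activity,
                   urt_obstruction = urt_obstruction,
                   inguinal_hernia = inguinal_hernia, ...,
                   stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  read_cohort(path)
}

# labeled activities of the packaged cohort (9 H vs 9 non-H)
fixture_activities <- function() {
  coh <- mpsi_cohort()
  keep <- !is.na(coh$idua_activity) & !is.na(coh$phenotype)
  list(activity = coh$idua_activity[keep],
       label = binary_phenotype(coh$phenotype[keep]),
       phenotype = coh$phenotype[keep])
}

# independent brute-force oracle: exact two-sided Mann-Whitney p by
# enumerating every assignment of the pooled values to the two groups
brute_force_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(a, b) {
    sum(outer(a, b, "<")) + 0.5 * sum(outer(a, b, "=="))
  }
  mu <- n1 * n2 / 2
  u_obs <- min(u_of(x, y), u_of(y, x))
  idx <- utils::combn(n1 + n2, n1)
  us <- apply(idx, 2, function(i) {
    min(u_of(pooled[i], pooled[-i]), u_of(pooled[-i], pooled[i]))
  })
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}
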