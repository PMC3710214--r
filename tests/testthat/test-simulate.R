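no_missing <- c(idua_activity = 0, urt_obstruction = 0,
                inguinal_hernia = 0, gestational_age = 0)

test_that("simulation is seed-deterministic down to the written file", {
  cfg <- sim_config(n_patients = 100, seed = 1L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(a, f1); write_cohort(b, f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed produces a different cohort
  expect_false(identical(a, simulate_cohort(sim_config(n_patients = 100,
                                                       seed = 2L))))
})

test_that("generated cohorts respect the configured structure", {
  all_h <- simulate_cohort(sim_config(n_patients = 40,
                                      phenotype_probs = c(H = 1, HS = 0,
                                                          S = 0),
                                      seed = 3L))
  expect_true(all(all_h$phenotype == "H"))

  coh <- simulate_cohort(sim_config(n_patients = 400, seed = 4L))
  expect_s3_class(coh, "mpsi_cohort")
  expect_equal(nrow(coh), 400L)
  # non-H patients never carry two severe-pool alleles
  sev <- sim_config()$severe_allele_pool
  both <- is_severe_genotype(coh$allele1, coh$allele2, sev)
  expect_equal(sum(both & coh$phenotype != "H"), 0L)
  # activities positive wherever observed
  expect_true(all(coh$idua_activity > 0, na.rm = TRUE))
  expect_error(sim_config(phenotype_probs = c(H = 0.5, HS = 0.5, S = 0.5)))
})

test_that("a fully informative configuration gives perfect internal validation", {
  cfg <- sim_config(
    n_patients = 60, seed = 9L, p_both_severe_given_H = 1,
    activity_distributions = list(H = c(meanlog = log(0.2), sdlog = 0.15),
                                  HS = c(meanlog = log(2), sdlog = 0.15),
                                  S = c(meanlog = log(2), sdlog = 0.15)),
    missingness = no_missing, preterm_rate = 0)
  coh <- simulate_cohort(cfg)
  ev <- evaluate(coh, predict(mpsi_model(), coh))
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 1)
  expect_equal(ev$n_indeterminate, 0L)
})

test_that("empirical prevalences converge to the configured rates", {
  cfg <- sim_config(n_patients = 10000L, seed = 12L,
                    missingness = no_missing)
  coh <- simulate_cohort(cfg)
  for (f in c("urt_obstruction", "inguinal_hernia")) {
    for (cls in c("H", "nonH")) {
      rate <- cfg$feature_prevalence[[f]][[cls]]
      sel <- if (cls == "H") coh$phenotype == "H" else coh$phenotype != "H"
      obs <- mean(coh[[f]][sel] == "present")
      tol <- 3 * sqrt(max(rate * (1 - rate), 1e-4) / sum(sel))
      expect_lt(abs(obs - rate), tol + 1e-9)
    }
  }
})

test_that("threshold recovery lands inside the generating gap on separated data", {
  cfg <- sim_config(
    n_patients = 30, seed = 500L, p_both_severe_given_H = 1,
    activity_distributions = list(H = c(meanlog = log(0.2), sdlog = 0.15),
                                  HS = c(meanlog = log(2), sdlog = 0.15),
                                  S = c(meanlog = log(2), sdlog = 0.15)),
    missingness = no_missing)
  rec <- recovery_experiment(cfg, n_reps = 20)
  expect_equal(nrow(rec$per_rep), 20L)
  expect_true(all(rec$per_rep$separable))
  # boundaries stay between the H support and the non-H support
  expect_true(all(rec$per_rep$lower > 0.1))
  expect_true(all(rec$per_rep$upper < 1.0))
  expect_true(all(rec$per_rep$lower <= rec$per_rep$upper))
  expect_true(all(rec$per_rep$sensitivity == 1))
  expect_true(all(rec$per_rep$specificity == 1))

  one <- recovery_experiment(cfg, n_reps = 1)
  expect_equal(one$summary$mean,
               unlist(one$per_rep[1, c("lower", "upper", "n_intermediate",
                                       "sensitivity", "specificity",
                                       "n_indeterminate")],
                      use.names = FALSE))
})

test_that("the gray zone widens as the class distributions overlap more", {
  mean_gray <- function(nonh_meanlog) {
    cfg <- sim_config(
      n_patients = 60, seed = 100L,
      activity_distributions = list(
        H = c(meanlog = log(0.2), sdlog = 0.3),
        HS = c(meanlog = nonh_meanlog, sdlog = 0.3),
        S = c(meanlog = nonh_meanlog, sdlog = 0.3)),
      missingness = no_missing)
    mean(recovery_experiment(cfg, n_reps = 5)$per_rep$n_intermediate)
  }
  gray <- vapply(c(log(2.0), log(0.8), log(0.35)), mean_gray, numeric(1))
  expect_true(!is.unsorted(gray))
})

test_that("flat key-value config files override only the keys they set", {
  tmp <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# synthetic cohort settings",
               "n_patients = 55", "seed = 42",
               "phenotype_probs = 0.5, 0.25, 0.25",
               "missingness_idua_activity = 0",
               "activity_H = -1.2, 0.2",
               "prevalence_inguinal_hernia = 0.5, 0.1"), tmp)
  cfg <- read_sim_config(tmp)
  expect_equal(cfg$n_patients, 55L)
  expect_equal(cfg$seed, 42L)
  expect_equal(unname(cfg$phenotype_probs), c(0.5, 0.25, 0.25))
  expect_equal(cfg$missingness[["idua_activity"]], 0)
  expect_equal(unname(cfg$activity_distributions$H), c(-1.2, 0.2))
  expect_equal(unname(cfg$feature_prevalence$inguinal_hernia), c(0.5, 0.1))
  # untouched keys keep defaults
  expect_equal(cfg$preterm_rate, sim_config()$preterm_rate)
  writeLines("nonsense without equals", tmp)
  expect_error(read_sim_config(tmp), "cannot parse")
})
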