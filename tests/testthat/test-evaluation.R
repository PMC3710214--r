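test_that("internal validation of the full algorithm is perfect on the cohort", {
  coh <- mpsi_cohort()
  ev <- evaluate(coh, predict(mpsi_model(), coh))
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 1)
  expect_equal(ev$n_indeterminate, 1L)
  expect_equal(ev$n_classifiable, 29L)
  expect_equal(ev$tp + ev$fp + ev$tn + ev$fn, ev$n_classifiable)
  expect_equal(unname(ev$per_step),
               c(genotype = 14L, activity = 10L, clinical = 5L, none = 1L),
               ignore_attr = TRUE)
})

test_that("the genotype step alone reaches 82% sensitivity at full specificity", {
  coh <- mpsi_cohort()
  pred <- predict(mpsi_model(), coh)
  # evaluated as a binary screen: unflagged patients count as negative calls
  pred$verdict <- ifelse(pred$genotype_step == "H", "H", "non-H")
  pred$decisive_step <- "genotype"
  ev <- evaluate(coh, pred)
  expect_equal(ev$sensitivity, 14 / 17)
  expect_equal(floor(ev$sensitivity * 100 + 0.5), 82)
  expect_equal(ev$specificity, 1)
})

test_that("evaluation accounting is order-invariant and honest about gaps", {
  coh <- mpsi_cohort()
  pred <- predict(mpsi_model(), coh)
  set.seed(4)
  shuffled <- coh[sample(nrow(coh)), ]
  class(shuffled) <- class(coh)
  ev1 <- evaluate(coh, pred)
  ev2 <- evaluate(shuffled, pred)
  expect_equal(ev1[names(ev1) != "per_step"], ev2[names(ev2) != "per_step"])

  # empty prediction set: counts zero, ratios flagged undefined
  empty <- coh[0, ]
  class(empty) <- class(coh)
  ev0 <- evaluate(coh, predict(mpsi_model(), empty))
  expect_equal(ev0$n_classifiable, 0L)
  expect_true(is.na(ev0$sensitivity))
  expect_true(is.na(ev0$specificity))

  # unlabeled records are excluded but counted
  coh2 <- coh
  coh2$phenotype[1] <- NA
  ev3 <- evaluate(coh2, pred)
  expect_equal(ev3$n_unlabeled, 1L)
  expect_equal(ev3$n_classifiable, 28L)

  bogus <- pred
  bogus$patient_id[1] <- "ghost"
  expect_error(evaluate(coh, bogus), "ghost")
})

test_that("zone evaluation matches confusion counts from zone-only predictions", {
  coh <- mpsi_cohort()
  t <- activity_thresholds(0.32, 0.66)
  z <- evaluate_step2_zones(coh, t)
  expect_equal(z$rule_in_sensitivity, 5 / 9)
  expect_equal(z$rule_in_specificity, 1)
  expect_equal(z$rule_out_sensitivity, 1)
  expect_equal(z$rule_out_specificity, 8 / 9)
  expect_equal(z$n_intermediate, 5L)

  # activity-only predictions on the activity-bearing subset
  sub <- coh[!is.na(coh$idua_activity), ]
  class(sub) <- class(coh)
  pred <- predict(mpsi_model(), sub)
  zone <- classify_by_activity(sub$idua_activity, t)
  pred$verdict <- ifelse(zone == "intermediate", "indeterminate", zone)
  pred$decisive_step <- ifelse(zone == "intermediate", "none", "activity")
  ev <- evaluate(sub, pred)
  expect_equal(ev$tp, round(z$rule_in_sensitivity * z$n_pos))
  expect_equal(ev$fp, round((1 - z$rule_in_specificity) * z$n_neg))
  expect_equal(ev$tn, round(z$rule_out_specificity * z$n_neg))
  expect_equal(ev$fn, round((1 - z$rule_out_sensitivity) * z$n_pos))
  expect_equal(ev$n_indeterminate, z$n_intermediate)
})

test_that("widening the gray zone never hurts rule-in specificity or rule-out sensitivity", {
  coh <- mpsi_cohort()
  base <- evaluate_step2_zones(coh, activity_thresholds(0.32, 0.66))
  set.seed(17)
  for (rep in 1:15) {
    lo <- runif(1, 0.01, 0.32)
    hi <- runif(1, 0.66, 3)
    wide <- evaluate_step2_zones(coh, activity_thresholds(lo, hi))
    expect_gte(wide$rule_in_specificity, base$rule_in_specificity)
    expect_gte(wide$rule_out_sensitivity, base$rule_out_sensitivity)
    expect_gte(wide$n_intermediate, 0L)
  }

  # extreme thresholds push everything into the gray zone
  z <- evaluate_step2_zones(coh, activity_thresholds(1e-9, 10))
  expect_equal(z$n_intermediate, 18L)
  # boundaries at the observed extremes: only the minimum leaves the zone
  obs <- fixture_activities()$activity
  z2 <- evaluate_step2_zones(coh, activity_thresholds(min(obs), max(obs)))
  expect_equal(z2$n_intermediate,
               length(obs) - sum(obs == min(obs)) - sum(obs > max(obs)))
})
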