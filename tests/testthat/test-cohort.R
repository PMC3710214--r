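test_that("allele normalization strips whitespace, folds case and namespaces the prefix", {
  expect_equal(normalize_allele(" p.W402X "), "p.W402X")
  expect_equal(normalize_allele("c.134del12"), "c.134DEL12")
  expect_equal(normalize_allele("P.w402x"), "p.W402X")
  expect_equal(normalize_allele("c.494-1G > A"), "c.494-1G>A")
  expect_equal(allele_namespace(normalize_allele(c("p.W402X", "c.134del12"))),
               c("protein", "coding"))
  expect_equal(allele_token(normalize_allele("c.134del12")), "134DEL12")

  # idempotent round trip and comparison invariance to case/whitespace
  raws <- c(" p.W402X", "C.474-2a > g", "p.q70x ", "c.704INS5")
  once <- normalize_allele(raws)
  expect_identical(normalize_allele(once), once)
  expect_identical(normalize_allele(toupper(raws)), once)

  expect_error(normalize_allele("W402X"), "malformed allele")
  expect_error(normalize_allele("  "), "malformed allele")
  expect_error(normalize_allele("p."), "malformed allele")
})

test_that("gestational age parses weeks + days with 37+0 as the term boundary", {
  ga <- parse_gestational_age(c("37 + 0", "33 + 6", "X", "41+2", ""))
  expect_equal(ga$total_days, c(259L, 237L, NA, 289L, NA))
  expect_equal(ga$term, c(TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(ga$known, c(TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_error(parse_gestational_age("37 + 7"), "days must be 0-6")
  expect_error(parse_gestational_age("forty"), "cannot parse")
})

test_that("the packaged cohort matches its printed source", {
  path <- system.file("extdata", "mpsi_cohort.csv", package = "mpsipredict")
  expect_equal(unname(tools::md5sum(path)),
               "0189d2b006c6962351cb0a95534841ba")
  coh <- mpsi_cohort()
  expect_equal(nrow(coh), 30L)
  expect_equal(sum(coh$phenotype == "H"), 17L)
  expect_equal(sum(coh$phenotype %in% c("HS", "S")), 13L)
  expect_equal(sum(!is.na(coh$idua_activity)), 18L)
  # spot checks against printed cells
  expect_equal(coh$allele2[coh$patient_id == "5"], "c.134DEL12")
  expect_equal(coh$idua_activity[coh$patient_id == "16"], 0.32)
  expect_equal(coh$idua_activity[coh$patient_id == "23"], 2.43)
  expect_true(is.na(coh$ga_weeks[coh$patient_id == "10"]))
  expect_equal(coh$urt_obstruction[coh$patient_id == "26"], "unknown")
})

test_that("cohort files round-trip and reject malformed input", {
  coh <- mpsi_cohort()
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, tmp)
  back <- read_cohort(tmp)
  expect_equal(as.data.frame(back), as.data.frame(coh))

  # tab-separated variant is auto-detected
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(coh, tmp2, sep = "\t")
  expect_equal(as.data.frame(read_cohort(tmp2)), as.data.frame(coh))

  # header-only file yields an empty cohort
  tmp3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste("patient_id", "phenotype", "gestational_age", "allele1",
                   "allele2", "idua_activity", "urt_obstruction",
                   "inguinal_hernia", sep = ","), tmp3)
  expect_equal(nrow(read_cohort(tmp3)), 0L)

  expect_error(make_cohort(c("a", "a")), "duplicate patient_id")
  expect_error(make_cohort("a", phenotype = "Hurler"), "unknown phenotype")
  expect_error(make_cohort("a", idua_activity = "low"),
               "unparseable idua_activity")
  expect_error(make_cohort("a", urt_obstruction = "yes"), "tri-state")
})

test_that("extra feat_ columns are carried as tri-state findings", {
  coh <- make_cohort(c("a", "b"), feat_kyphosis = c("+", "X"))
  expect_equal(coh$feat_kyphosis, c("present", "unknown"))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, tmp)
  expect_equal(as.data.frame(read_cohort(tmp)), as.data.frame(coh))
})

test_that("the severe-mutation list loads, normalizes and deduplicates", {
  sev <- mpsi_severe_mutations()
  expect_length(sev, 25L)
  expect_true(normalize_allele("p.A327P") %in% sev)
  expect_true(normalize_allele("c.1190-1G > A") %in% sev)
  expect_false(normalize_allele("p.R383H") %in% sev)

  tmp <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("p.W402X", "# comment", "P.w402x", ""), tmp)
  expect_length(read_mutation_list(tmp), 1L)

  writeLines(c("p.W402X", "402X"), tmp)
  expect_error(read_mutation_list(tmp), "line 2")
})
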