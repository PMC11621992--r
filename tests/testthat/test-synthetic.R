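test_that("generation is deterministic for a fixed seed", {
  cfg <- synth_config()
  expect_identical(generate_jem(cfg, 7), generate_jem(cfg, 7))
  jm <- generate_jem(cfg, 7)
  a <- generate_cohort(cfg, jm, 7, n_total = 300)
  b <- generate_cohort(cfg, jm, 7, n_total = 300)
  expect_identical(a$participants, b$participants)
  expect_identical(a$jobs, b$jobs)
  expect_false(identical(a$jobs, generate_cohort(cfg, jm, 8, n_total = 300)$jobs))
})

test_that("synthetic JEM matches its configured structure", {
  cfg <- synth_config()
  jm <- generate_jem(cfg, 13)
  expect_equal(nrow(jm), 2 * cfg$n_isco_codes)
  frac <- mean(jm$prevalence[jm$field_kind == "E"] > 0)
  # binomial fluctuation around 0.62 at n = 468
  expect_lt(abs(frac - cfg$frac_exposed_codes),
            3 * sqrt(0.62 * 0.38 / cfg$n_isco_codes))
  ex <- jm[jm$field_kind == "E" & jm$prevalence > 0, ]
  hx <- jm[jm$field_kind == "H" & jm$prevalence > 0, ]
  rho <- cor(ex$intensity, hx$intensity, method = "spearman")
  expect_gt(rho, 0.84); expect_lt(rho, 0.98)
  # an all-unexposed JEM makes the downstream design inestimable, gracefully
  cfg0 <- synth_config(frac_exposed_codes = 0)
  jm0 <- generate_jem(cfg0, 13)
  expect_error(generate_cohort(cfg0, jm0, 13, n_total = 200),
               "inestimable synthetic design")
})

test_that("generator output round-trips through the package readers", {
  st <- small_study()
  dir <- tempfile()
  write_synthetic(st$syn, st$jm, dir)
  jm2 <- load_jem(file.path(dir, "jem.csv"))
  expect_equal(as.data.frame(jm2), as.data.frame(st$jm))
  cohort <- load_cohort(file.path(dir, "participants.csv"),
                        file.path(dir, "jobs.csv"))
  expect_equal(nrow(cohort$participants), nrow(st$syn$participants))
  expect_equal(nrow(cohort$jobs), nrow(st$syn$jobs))
  expect_equal(nrow(cohort$rejects), 0)
  expect_equal(cohort$jobs$start_year, st$syn$jobs$start_year)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$true_log_or, st$syn$truth$true_log_or)
})

test_that("attribution methods order participant-level exposure prevalence", {
  st <- small_study()
  exc <- apply_exclusions(st$syn[c("participants", "jobs")])
  refs <- reference_years(exc$participants,
                          median_dx_interview_gap(exc$participants))
  prof <- exposure_profiles(exc$participants, exc$jobs, st$jm, refs,
                            labels = "lag1")
  pe <- tapply(prof$exposed[prof$field_kind == "E"],
               prof$method[prof$field_kind == "E"], mean)
  expect_gt(pe[["M1"]], pe[["M2"]])
  expect_gt(pe[["M2"]], pe[["M3"]])
  # tuned toward the observed pattern: most exposed under M1, few under M3
  expect_gt(pe[["M1"]], 0.75)
  expect_lt(pe[["M3"]], 0.25)
})

test_that("configured exclusion defects surface in the ledger", {
  cfg <- synth_config(exclusion_rates = c(source_info = 0.05,
                                          missing_education = 0.02,
                                          chronology = 0.02,
                                          nonstandard_only = 0.02,
                                          unknown_occupation = 0.02))
  jm <- generate_jem(cfg, 17)
  syn <- generate_cohort(cfg, jm, 17, n_total = 1500)
  exc <- apply_exclusions(syn[c("participants", "jobs")])
  led <- exc$ledger
  tot <- rowSums(led$excluded)
  expect_true(all(tot > 0))
  expect_equal(led$initial, led$final + colSums(led$excluded))
  # roughly the configured rates overall
  expect_equal(sum(tot) / sum(led$initial), 0.13, tolerance = 0.35)
})
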