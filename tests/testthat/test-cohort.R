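write_cohort_files <- function(pt, jb) {
  pp <- tempfile(fileext = ".csv"); jp <- tempfile(fileext = ".csv")
  utils::write.csv(pt, pp, row.names = FALSE)
  utils::write.csv(jb, jp, row.names = FALSE)
  list(participants = pp, jobs = jp)
}

test_that("cohort loading types records and flags orphans", {
  pt <- participants_df(c("P1", "P2"), status = c("glioma", "control"),
                        diagnosis_year = c(2001, NA))
  jb <- rbind(spells_df("P1", 1990, 1995),
              spells_df("P1", 1996, 2000, isco = "2000"),
              spells_df("P2", 1985, 1979))   # end < start: loaded, not dropped
  f <- write_cohort_files(pt, jb)
  cohort <- load_cohort(f$participants, f$jobs)
  expect_equal(nrow(cohort$participants), 2)
  expect_equal(nrow(cohort$jobs), 3)
  expect_equal(nrow(cohort$rejects), 0)

  jb_orphan <- rbind(jb, spells_df("P9", 1990, 1991))
  f2 <- write_cohort_files(pt, jb_orphan)
  expect_error(load_cohort(f2$participants, f2$jobs), "orphan-spell")

  # incoherent case years go to the rejects report, not silently dropped
  pt_bad <- rbind(pt, participants_df("P3", status = "glioma",
                                      diagnosis_year = 2005,
                                      interview_year = 2002))
  f3 <- write_cohort_files(pt_bad, jb)
  c3 <- load_cohort(f3$participants, f3$jobs)
  expect_equal(nrow(c3$participants), 2)
  expect_equal(c3$rejects$reason, "case without coherent diagnosis/interview years")
})

test_that("exclusions run in order, count once, and conserve totals", {
  pt <- participants_df(sprintf("P%d", 1:7),
                        status = c("glioma", rep("control", 6)),
                        diagnosis_year = c(2001, rep(NA, 6)))
  pt$education[3] <- "missing"
  jb <- rbind(
    spells_df("P1", 1990, 2000),                              # clean case
    spells_df("P2", 1990, 2000, source_uncertain = TRUE),     # crit 1
    spells_df("P3", 1990, 1985),                              # crit 2 AND 3
    spells_df("P4", 1995, 1990),                              # crit 3
    spells_df("P5", 1990, 2000, isco = "0000", nonstandard = TRUE), # crit 4
    spells_df("P6", 1990, 2000),
    spells_df("P6", 2001, 2001, isco = "UNKNOWN"),            # crit 5
    spells_df("P7", 1990, 1995, isco = "0000", nonstandard = TRUE),
    spells_df("P7", 1996, 2000))                              # retained
  exc <- apply_exclusions(list(participants = pt, jobs = jb))
  led <- exc$ledger
  expect_equal(unname(led$excluded[, "control"]), c(1, 1, 1, 1, 1))
  expect_equal(unname(led$final), c(1, 0, 1))
  # order sensitivity: P3 matched education (2) before chronology (3)
  expect_true("P4" %in% pt$pid[!pt$pid %in% exc$participants$pid])
  expect_setequal(exc$participants$pid, c("P1", "P7"))
  # nonstandard-alongside-real spells retained
  expect_equal(sum(exc$jobs$pid == "P7"), 2)
  # conservation, per group
  expect_equal(led$initial, led$final + colSums(led$excluded))
  # idempotence
  exc2 <- apply_exclusions(exc[c("participants", "jobs")])
  expect_equal(exc2$participants$pid, exc$participants$pid)
  expect_true(all(exc2$ledger$excluded == 0))
})

test_that("no-violation cohorts pass through with an all-zero ledger", {
  pt <- participants_df(c("A", "B"), status = c("meningioma", "control"),
                        diagnosis_year = c(2000, NA))
  jb <- rbind(spells_df("A", 1980, 1999), spells_df("B", 1985, 2001))
  exc <- apply_exclusions(list(participants = pt, jobs = jb))
  expect_true(all(exc$ledger$excluded == 0))
  expect_equal(unname(exc$ledger$final), unname(exc$ledger$initial))
})

test_that("median diagnosis-interview gap and reference dates", {
  mk <- function(gaps) participants_df(sprintf("C%d", seq_along(gaps)),
                                       status = "glioma",
                                       diagnosis_year = 2002 - gaps,
                                       interview_year = 2002)
  expect_equal(median_dx_interview_gap(mk(c(0, 1, 1))), 1)
  expect_equal(median_dx_interview_gap(mk(c(0, 2))), 1)
  expect_equal(median_dx_interview_gap(mk(c(0, 0, 0))), 0)
  expect_error(median_dx_interview_gap(participants_df("X")), "undefined gap")

  pt <- rbind(mk(0), participants_df("K", interview_year = 2003))
  pt$diagnosis_year[1] <- 2002
  expect_equal(reference_years(pt, 1), c(2002, 2002))
  expect_equal(reference_years(pt, 0), c(2002, 2003))
  # half-up rounding of a fractional median gap
  expect_equal(reference_years(pt, 0.5)[2], 2002)
  pt$diagnosis_year[1] <- NA
  expect_error(reference_years(pt, 1), "data error")
})

test_that("cohort summary reports within-status percentages", {
  pt <- rbind(participants_df(c("A", "B", "C"), sex = c("F", "F", "M")),
              participants_df("D", status = "glioma", diagnosis_year = 2001,
                              sex = "M"))
  s <- cohort_summary(pt)
  f <- s[s$status == "control" & s$variable == "sex" & s$level == "F", ]
  expect_equal(f$n, 2)
  expect_equal(f$pct, 100 * 2 / 3)
})
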