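test_that("yearly series applies the attribution methods and overlap averaging", {
  jm <- tiny_jem()
  # one spell 1990-1994 at intensity 2.0 under M1
  s <- yearly_series(spells_df("P1", 1990, 1994), jm, "M1", "E")
  expect_equal(s$years, 1990:1994)
  expect_equal(s$values, rep(2, 5))
  # overlapping spells at 2.0 and 0.0 average to 1.0
  sp <- rbind(spells_df("P1", 1990, 1991),
              spells_df("P1", 1990, 1991, isco = "4000"))  # prevalence 0
  s2 <- yearly_series(sp, jm, "M1", "E")
  expect_equal(s2$values, c(1, 1))
  # Method-2 prevalence gate: code 2000 has prevalence 0.03 < 0.05
  sp3 <- spells_df("P1", 1990, 1992, isco = "2000")
  expect_equal(yearly_series(sp3, jm, "M2", "E", threshold = 0.05)$values,
               rep(0, 3))
  expect_equal(yearly_series(sp3, jm, "M1", "E")$values, rep(0.5, 3))
  # gate comparison is >=: prevalence exactly at the threshold stays exposed
  expect_equal(yearly_series(sp3, jm, "M2", "E", threshold = 0.03)$values,
               rep(0.5, 3))
  # Method-3 source gate
  expect_equal(yearly_series(spells_df("P1", 1990, 1990), jm, "M3", "E")$values, 0)
  expect_equal(yearly_series(spells_df("P1", 1990, 1990,
                                       source_reported = TRUE),
                             jm, "M3", "E")$values, 2)
  # contract: chronology must be resolved upstream
  expect_error(yearly_series(spells_df("P1", 1990, 1980), jm),
               "contract violation")
  expect_error(yearly_series(spells_df("P1", NA, 1990), jm),
               "contract violation")
})

test_that("cumulative, window, years-worked and TWA follow the year conventions", {
  jm <- tiny_jem()
  s <- yearly_series(spells_df("P1", 1998, 2000, isco = "2000"), jm)  # 0.5/yr
  expect_equal(cumulative_exposure(s, 2001, 1), 1.5)
  expect_equal(cumulative_exposure(s, 2001, 10), 0)

  s2 <- yearly_series(spells_df("P1", 1990, 1999, isco = "2000"), jm)
  expect_equal(cumulative_exposure(s2, 2000, 5), 6 * 0.5)  # 1990..1995

  s3 <- yearly_series(spells_df("P1", 1991, 2000), jm)  # 2.0 on 1991..2000
  expect_equal(window_exposure(s3, 2001, 1, 4), 4 * 2)   # 1997..2000
  expect_equal(window_exposure(s3, 2001, 5, 9), 5 * 2)   # 1992..1996
  expect_equal(window_exposure(s3, 2030, 1, 4), 0)

  expect_equal(years_worked(s3, 2001, "lag1"), 10)
  expect_equal(years_worked(s3, 2001, "win1_4"), 4)
  expect_equal(years_worked(s3, 2030, "win1_4"), 0)

  expect_equal(twa_exposure(6, 3), 2)
  expect_equal(twa_exposure(0, 0), 0)
  expect_error(twa_exposure(1, 0), "contract violation")
})

test_that("cohort profiles equal the naive per-participant oracle", {
  st <- small_study()
  exc <- apply_exclusions(st$syn[c("participants", "jobs")])
  sub <- exc$participants
  refs <- reference_years(sub, median_dx_interview_gap(sub))
  thr <- list(E = median_prevalence_threshold(st$jm, "E"),
              H = median_prevalence_threshold(st$jm, "H"))
  prof <- exposure_profiles(sub, exc$jobs, st$jm, refs, thresholds = thr)

  set.seed(31)
  picks <- sample(nrow(sub), 25)
  for (i in picks) {
    sp <- exc$jobs[exc$jobs$pid == sub$pid[i], ]
    for (m in c("M1", "M2", "M3")) for (f in c("E", "H"))
      for (lab in c("lag1", "lag10", "win5_9")) {
        want <- naive_metric(sp, st$jm, m, f, thr[[f]], refs[i], lab)
        got <- prof[prof$pid == sub$pid[i] & prof$method == m &
                    prof$field_kind == f & prof$label == lab, ]
        expect_equal(got$cumulative, unname(want["cumulative"]), tolerance = 1e-12)
        expect_equal(got$years_worked, unname(want["years_worked"]))
        expect_equal(got$twa, unname(want["twa"]), tolerance = 1e-12)
      }
  }
  # TWA never exceeds the maximum yearly intensity (bounded average)
  expect_true(all(prof$twa <= max(st$jm$intensity) + 1e-12))
  # exposed flag is value > 0
  expect_equal(prof$exposed, prof$cumulative > 0)
})

test_that("lag-window partition, lag monotonicity and method nesting hold cohort-wide", {
  st <- small_study()
  exc <- apply_exclusions(st$syn[c("participants", "jobs")])
  sub <- exc$participants
  refs <- reference_years(sub, median_dx_interview_gap(sub))
  prof <- exposure_profiles(sub, exc$jobs, st$jm, refs)
  for (m in c("M1", "M2", "M3")) for (f in c("E", "H")) {
    g <- function(lab, col = "cumulative") {
      x <- prof[prof$method == m & prof$field_kind == f & prof$label == lab, ]
      x[match(sub$pid, x$pid), col]
    }
    expect_equal(g("lag1"), g("win1_4") + g("win5_9") + g("lag10"),
                 tolerance = 1e-10)
    expect_true(all(g("lag10") <= g("lag5") + 1e-12))
    expect_true(all(g("lag5") <= g("lag1") + 1e-12))
  }
  for (f in c("E", "H")) for (lab in c("lag1", "win1_4")) {
    g <- function(m, col) {
      x <- prof[prof$method == m & prof$field_kind == f & prof$label == lab, ]
      x[match(sub$pid, x$pid), col]
    }
    expect_true(all(g("M2", "cumulative") <= g("M1", "cumulative") + 1e-12))
    expect_true(all(g("M3", "cumulative") <= g("M1", "cumulative") + 1e-12))
    expect_true(all(g("M1", "exposed") | !g("M2", "exposed")))
    expect_true(all(g("M1", "exposed") | !g("M3", "exposed")))
  }
})
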