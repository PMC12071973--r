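test_that("patient table parses, with header-only files giving empty tables", {
  expect_equal(nrow(read_patients(patients_csv())), 0L)

  path <- patients_csv(c(
    "P1,2017-2018,2017-03-01,2018-01-15,2020-01-01,Female,White,Solid tumor,4.5",
    "P2,2022-2023,2022-06-10,,2024-06-01,male,hispanic/latino,Neuro-oncology,12"
  ))
  p <- read_patients(path)
  expect_equal(p$cohort, c("2017-2018", "2022-2023"))
  expect_equal(p$dx_date, as.Date(c("2017-03-01", "2022-06-10")))
  expect_true(is.na(p$eot_date[2]))
  # category strings are canonicalized case-insensitively
  expect_equal(p$sex[2], "Male")
  expect_equal(p$race[2], "Hispanic/Latino")
})

test_that("patient validation rejects bad schemas, dates and anchor order", {
  bad_cols <- write_temp_csv(c("patient_id,cohort,dx_date", "P1,c,2020-01-01"))
  expect_error(read_patients(bad_cols), "censor_date")

  bad_date <- patients_csv(
    "P1,c,2020-13-40,,2021-01-01,Female,White,Solid tumor,3")
  expect_error(read_patients(bad_date), "row 2.*dx_date")

  eot_before_dx <- patients_csv(
    "P1,c,2020-06-01,2020-01-01,2021-01-01,Female,White,Solid tumor,3")
  expect_error(read_patients(eot_before_dx), "eot_date precedes dx_date")

  dup <- patients_csv(c(
    "P1,c,2020-01-01,,2021-01-01,Female,White,Solid tumor,3",
    "P1,c,2020-02-01,,2021-01-01,Male,White,Solid tumor,4"
  ))
  expect_error(read_patients(dup), "duplicate patient_id")

  bad_race <- patients_csv(
    "P1,c,2020-01-01,,2021-01-01,Female,Martian,Solid tumor,3")
  expect_error(read_patients(bad_race), "unknown race 'Martian'")
})

test_that("event table parses and rejects unknown instruments", {
  expect_equal(nrow(read_events(events_csv())), 0L)

  ev <- read_events(events_csv("P1,SWA,2022-03-01"))
  expect_equal(ev$instrument, "SWA")
  expect_equal(ev$date, as.Date("2022-03-01"))

  ev <- read_events(events_csv("P1,pba,2022-03-01"))
  expect_equal(ev$instrument, "PBA")

  expect_error(read_events(events_csv("P1,psych,2022-03-01")),
               "unknown instrument.*psych")
})

test_that("attach_events joins, deduplicates and enforces the date range", {
  patients <- read_patients(patients_csv(
    "P1,c,2020-01-10,,2021-01-01,Female,White,Solid tumor,3"))

  # same-day duplicates of one instrument collapse to a single event
  ev <- read_events(events_csv(c("P1,SWA,2020-02-01", "P1,swa,2020-02-01",
                                 "P1,PBA,2020-02-01")))
  joined <- attach_events(patients, ev)
  expect_equal(nrow(joined$events[[1]]), 2L)

  # pre-diagnosis events are dropped with a warning, record stays valid
  ev <- read_events(events_csv(c("P1,SWA,2020-01-05", "P1,SWA,2020-03-01")))
  expect_warning(joined <- attach_events(patients, ev),
                 "1 pre-diagnosis.*P1")
  expect_equal(joined$events[[1]]$date, as.Date("2020-03-01"))
  expect_error(attach_events(patients, ev, out_of_range = "error"),
               "pre-diagnosis")

  # post-censor events likewise
  ev <- read_events(events_csv("P1,PBA,2021-06-01"))
  expect_warning(joined <- attach_events(patients, ev), "1 post-censor")
  expect_equal(nrow(joined$events[[1]]), 0L)

  # orphan events are an error listing the unknown ids
  ev <- read_events(events_csv("PX,SWA,2020-03-01"))
  expect_error(attach_events(patients, ev), "unknown patient_id.*PX")
})

test_that("attach_events is idempotent on already-clean event tables", {
  patients <- read_patients(patients_csv(
    "P1,c,2020-01-10,,2021-01-01,Female,White,Solid tumor,3"))
  ev <- read_events(events_csv(c("P1,SWA,2020-02-01", "P1,PBA,2020-04-01")))
  once <- attach_events(patients, ev)
  twice <- attach_events(once[names(once) != "events"], ev)
  expect_identical(once$events, twice$events)
})

test_that("patient and event tables round-trip through write and read", {
  sim <- generate_cohort(scenario_config(
    cohorts = list(list(label = "rt", n = 8L,
                        dx_window = as.Date(c("2020-01-01", "2020-06-30")),
                        level_mixture = c("2" = 0.5, "4" = 0.5))),
    seed = 7L))
  pp <- tempfile(fileext = ".csv")
  pe <- tempfile(fileext = ".csv")
  readr::write_csv(sim$patients, pp)
  readr::write_csv(sim$events, pe)
  expect_equal(as.data.frame(read_patients(pp)), as.data.frame(sim$patients))
  expect_equal(as.data.frame(read_events(pe)), as.data.frame(sim$events))
})

test_that("scores round-trip losslessly and carry audit-flag columns", {
  sim <- generate_cohort(scenario_config(
    cohorts = list(list(label = "rt", n = 10L,
                        dx_window = as.Date(c("2020-01-01", "2020-06-30")),
                        level_mixture = c("1" = 0.2, "3" = 0.4, "5" = 0.4))),
    seed = 11L))
  scored <- score_cohort(attach_events(sim$patients, sim$events))
  expect_true(all(grepl("^crit_", names(scored)[-(1:5)])))
  expect_true(all(unlist(scored[c("swa_level", "pba_level", "combined_level")]) %in% 1:5))

  path <- tempfile(fileext = ".csv")
  write_scores(scored, path)
  back <- read_scores(path)
  expect_equal(as.data.frame(back), as.data.frame(scored))

  # empty input produces a header-only file
  write_scores(scored[0, ], path)
  expect_equal(nrow(read_scores(path)), 0L)
})
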