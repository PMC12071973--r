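# Hand-evaluated fixtures for the three track ladders. Each expected level
# was worked out clause by clause on a calendar before implementation.

rec <- function(dx, eot = NULL, censor, swa = NULL, pba = NULL) {
  patient_record(dx_date = dx, eot_date = eot, censor_date = censor,
                 swa = if (is.null(swa)) NULL else as.Date(swa),
                 pba = if (is.null(pba)) NULL else as.Date(pba))
}

test_that("SWA ladder: none, any-time, initial, first-year, lifetime", {
  # no SWA at all
  expect_equal(swa_track_level(rec("2020-01-01", censor = "2022-01-01")), 1L)

  # single SWA 200 days after diagnosis, no post-EOT SWA
  expect_equal(swa_track_level(
    rec("2020-01-01", eot = "2020-10-27", censor = "2022-06-01",
        swa = "2020-07-19")), 2L)

  # initial within one month: day 30 is in, day 31 is out
  expect_equal(swa_track_level(
    rec("2020-01-01", censor = "2021-06-01", swa = "2020-01-31")), 3L)
  expect_equal(swa_track_level(
    rec("2020-01-01", censor = "2021-06-01", swa = "2020-02-01")), 2L)

  # initial + every assessable annual anniversary window (two assessable)
  expect_equal(swa_track_level(
    rec("2020-01-01", eot = "2020-10-27", censor = "2023-11-27",
        swa = c("2020-01-11", "2021-10-27", "2022-10-27", "2023-10-27"))), 5L)

  # same history but the second annual window missed
  expect_equal(swa_track_level(
    rec("2020-01-01", eot = "2020-10-27", censor = "2023-11-27",
        swa = c("2020-01-11", "2021-10-27"))), 4L)

  # only one annual window assessable: lifetime clause unattainable, capped at 4
  expect_equal(swa_track_level(
    rec("2020-01-01", eot = "2020-10-27", censor = "2022-06-01",
        swa = c("2020-01-11", "2021-10-27"))), 4L)
})

test_that("PBA ladder: counts, initial-in-treatment, full schedule", {
  expect_equal(pba_track_level(rec("2020-01-01", censor = "2022-01-01")), 1L)

  # exactly one PBA, 90 days after diagnosis
  expect_equal(pba_track_level(
    rec("2020-01-01", eot = "2021-01-01", censor = "2022-01-01",
        pba = "2020-03-31")), 2L)

  # two PBAs but the first one after treatment ended
  expect_equal(pba_track_level(
    rec("2020-01-01", eot = "2020-06-01", censor = "2022-01-01",
        pba = c("2020-07-01", "2020-09-01"))), 3L)

  # initial during treatment plus one follow-up
  expect_equal(pba_track_level(
    rec("2020-01-01", eot = "2021-02-01", censor = "2022-01-01",
        pba = c("2020-03-01", "2020-07-19"))), 4L)

  # full schedule: initial within 4 weeks, every quarterly bin, EOT window,
  # twice in the post-treatment year, both assessable annual windows
  expect_equal(pba_track_level(
    rec("2022-03-01", eot = "2022-12-01", censor = "2025-06-01",
        pba = c("2022-03-20", "2022-06-01", "2022-09-01", "2022-11-20",
                "2023-04-01", "2023-11-25", "2024-12-01"))), 5L)

  # same history minus the second-quarter contact: a quarterly bin is empty
  expect_equal(pba_track_level(
    rec("2022-03-01", eot = "2022-12-01", censor = "2025-06-01",
        pba = c("2022-03-20", "2022-09-01", "2022-11-20",
                "2023-04-01", "2023-11-25", "2024-12-01"))), 4L)
})

test_that("combined ladder joins the SWA gate with the PBA clauses", {
  r <- rec("2020-01-01", censor = "2022-01-01")
  expect_equal(combined_level(r), 1L)

  # late SWA + PBA: the one-month SWA gate blocks anything above 2
  expect_equal(combined_level(
    rec("2020-01-01", eot = "2021-01-01", censor = "2022-01-01",
        swa = "2020-02-15", pba = "2020-04-10")), 2L)

  # timely SWA + one PBA any time
  expect_equal(combined_level(
    rec("2020-01-01", eot = "2021-01-01", censor = "2022-01-01",
        swa = "2020-01-21", pba = "2020-04-10")), 3L)

  # SWA-only history: PBA track 1, combined capped at 2
  s <- score_record(rec("2020-01-01", eot = "2021-01-01", censor = "2022-01-01",
                        swa = c("2020-01-05", "2020-06-01")))
  expect_equal(s$pba_level, 1L)
  expect_lte(s$combined_level, 2L)

  # PBA-only history: has events, so not level 1; gate keeps it at 2
  expect_equal(combined_level(
    rec("2020-01-01", eot = "2021-01-01", censor = "2022-01-01",
        pba = c("2020-02-01", "2020-05-01"))), 2L)

  # fully compliant on both instruments
  s <- score_record(rec(
    "2022-03-01", eot = "2022-12-01", censor = "2025-06-01",
    swa = c("2022-03-10", "2023-12-01", "2024-12-05"),
    pba = c("2022-03-20", "2022-06-01", "2022-09-01", "2022-11-20",
            "2023-04-01", "2023-11-25", "2024-12-01")))
  expect_equal(s[c("swa_level", "pba_level", "combined_level")],
               list(swa_level = 5L, pba_level = 5L, combined_level = 5L))
})

test_that("audit criteria statuses track the level decisions", {
  s <- score_record(rec("2020-01-01", eot = "2020-12-01", censor = "2021-02-01",
                        swa = "2020-01-15", pba = "2020-02-10"))
  expect_equal(unname(s$criteria[["swa_initial"]]), "met")
  expect_equal(unname(s$criteria[["pba_initial_4wk"]]), "unmet")
  # the first annual window closes after the censor date
  expect_equal(unname(s$criteria[["swa_annual_lifetime"]]), "not_assessable")
  expect_true(all(s$criteria %in% c("met", "unmet", "not_assessable")))
})

test_that("a newly diagnosed patient cannot score high by vacuity", {
  # censor right after diagnosis: no follow-up window has closed, yet the
  # record must not be granted levels whose requirements were never testable
  s <- score_record(rec("2020-01-01", censor = "2020-02-15",
                        swa = "2020-01-10", pba = c("2020-01-20", "2020-02-10")))
  expect_equal(s$swa_level, 3L)
  expect_equal(s$pba_level, 4L)
  expect_equal(s$combined_level, 3L)
})

test_that("score_cohort returns one scored row per patient", {
  sim <- generate_cohort(scenario_config(
    cohorts = list(list(label = "a", n = 6L,
                        dx_window = as.Date(c("2020-01-01", "2020-03-01")),
                        level_mixture = c("2" = 1))),
    seed = 3L))
  scored <- score_cohort(attach_events(sim$patients, sim$events))
  expect_equal(nrow(scored), 6L)
  expect_equal(scored$combined_level, rep(2L, 6L))
  expect_error(score_cohort(sim$patients), "attach_events")
})
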