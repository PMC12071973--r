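#' Scenario configuration for synthetic cohorts
#'
#' Defines the study conditions a synthetic cohort emulates: cohort sizes and
#' diagnosis-date windows, the target adherence-level mixture per cohort, the
#' treatment-duration distribution, the follow-up horizon past end of
#' treatment, and the timing jitter applied within requirement windows. All
#' randomness flows from the single integer `seed`.
#'
#' @param cohorts a list of cohort specs, each a list with `label` (string),
#'   `n` (>= 1), `dx_window` (length-2 `Date` vector) and `level_mixture`
#'   (named numeric vector, names in `"1"`..`"5"`, summing to 1).
#' @param treatment_duration_days length-2 numeric range; durations are drawn
#'   uniformly (in days) between the two values.
#' @param followup_horizon_months months between end of treatment and the
#'   censor date; 30 months keeps two annual anniversary windows assessable so
#'   every level through 5 is attainable.
#' @param jitter_days maximum day perturbation applied to events placed at
#'   window midpoints; jitter never moves an event across its window boundary.
#' @param track which score the level mixture targets: `"combined"` (default),
#'   `"SWA"` or `"PBA"`.
#' @param seed integer seed.
#' @return a validated `scenario_config` list.
#' @seealso [default_scenario()], [generate_record()], [generate_cohort()]
#' @export
scenario_config <- function(cohorts, treatment_duration_days = c(180, 900),
                            followup_horizon_months = 30, jitter_days = 7,
                            track = c("combined", "SWA", "PBA"), seed = 101L) {
  track <- match.arg(track)
  stopifnot(length(treatment_duration_days) == 2L,
            treatment_duration_days[1] > 0,
            treatment_duration_days[2] >= treatment_duration_days[1],
            followup_horizon_months >= 0, jitter_days >= 0,
            is.numeric(seed), length(seed) == 1L)
  if (!length(cohorts)) stop("at least one cohort is required", call. = FALSE)
  for (co in cohorts) {
    if (is.null(co$label) || is.null(co$n) || is.null(co$dx_window) ||
        is.null(co$level_mixture)) {
      stop("each cohort needs label, n, dx_window and level_mixture",
           call. = FALSE)
    }
    if (co$n < 1L) stop("cohort n must be >= 1", call. = FALSE)
    mix <- co$level_mixture
    if (is.null(names(mix)) || !all(names(mix) %in% as.character(1:5)) ||
        any(mix < 0) || abs(sum(mix) - 1) > 1e-9) {
      stop("level_mixture must be named by levels 1..5 and sum to 1",
           call. = FALSE)
    }
    dxw <- as.Date(co$dx_window)
    if (length(dxw) != 2L || anyNA(dxw) || dxw[2] < dxw[1]) {
      stop("dx_window must be two ordered dates", call. = FALSE)
    }
  }
  structure(
    list(cohorts = cohorts,
         treatment_duration_days = treatment_duration_days,
         followup_horizon_months = followup_horizon_months,
         jitter_days = jitter_days, track = track, seed = as.integer(seed)),
    class = c("scenario_config", "list")
  )
}

#' Default two-cohort scenario
#'
#' Two cohorts matching the published study design: 68 patients diagnosed
#' 2017-2018 and 82 diagnosed 2022-2023, with combined-level mixtures whose
#' expectations are 2.0 and 3.0, echoing the reported cohort means
#' (demonstration conditions, not a validation claim).
#'
#' @param seed integer seed (default 101).
#' @return a `scenario_config`.
#' @export
default_scenario <- function(seed = 101L) {
  scenario_config(
    cohorts = list(
      list(label = "2017-2018", n = 68L,
           dx_window = as.Date(c("2017-01-01", "2018-12-31")),
           level_mixture = c("1" = 0.30, "2" = 0.45, "3" = 0.20, "4" = 0.05)),
      list(label = "2022-2023", n = 82L,
           dx_window = as.Date(c("2022-01-01", "2023-12-31")),
           level_mixture = c("2" = 0.30, "3" = 0.45, "4" = 0.20, "5" = 0.05))
    ),
    seed = seed
  )
}

# integer jitter in [-j, j] that never crosses [lo, hi]
place_in <- function(lo, hi, jitter, mid = lo + floor(as.numeric(hi - lo) / 2)) {
  j <- as.integer(jitter)
  d <- mid + (sample.int(2L * j + 1L, 1L) - j - 1L)
  min(max(d, lo), hi)
}

rint <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

# SWA dates achieving exactly the target track level; higher-level
# requirements are deliberately left unmet
swa_dates_for_level <- function(level, dx, eot, censor, jitter, rubric) {
  iw <- rubric$swa$initial_window_days
  ann <- rubric$annual$anniversary_months
  tol <- rubric$annual$tolerance_months
  if (level == 1L) return(as.Date(character(0)))
  if (level == 2L) return(dx + iw + 1L + rint(0L, 60L))
  initial <- place_in(dx, dx + iw, jitter, mid = dx + floor(iw / 2))
  if (level == 3L) return(initial)
  if (level == 4L) {
    a1 <- place_in(add_months(eot, ann - tol), add_months(eot, ann + tol),
                   jitter, mid = add_months(eot, ann))
    return(c(initial, a1)) # later annual windows deliberately missed
  }
  K <- 0L
  repeat {
    if (add_months(eot, ann * (K + 1L) + tol) > censor) break
    K <- K + 1L
  }
  anns <- as.Date(vapply(seq_len(K), function(k) {
    place_in(add_months(eot, ann * k - tol), add_months(eot, ann * k + tol),
             jitter, mid = add_months(eot, ann * k))
  }, numeric(1)))
  c(initial, anns)
}

full_pba_schedule <- function(dx, eot, censor, jitter, rubric) {
  r <- rubric
  ann <- r$annual$anniversary_months
  tol <- r$annual$tolerance_months
  ev <- place_in(dx, dx + r$pba$initial_window_days, jitter,
                 mid = dx + floor(r$pba$initial_window_days / 2))
  bm <- r$pba$treatment_bin_months
  i <- 1L
  bins <- as.Date(character(0))
  repeat {
    close <- add_months(dx, bm * i)
    if (close > eot) break
    bins <- c(bins, place_in(add_months(dx, bm * (i - 1L)), close - 1L, jitter))
    i <- i + 1L
  }
  n_bins <- i - 1L
  # end-of-treatment contact, kept strictly after EOT so it also counts
  # toward the post-treatment-year pair
  eot_ev <- eot + 1L + rint(0L, max(1L, as.integer(jitter)))
  midyear <- add_months(eot, 4L) + (sample.int(2L * as.integer(jitter) + 1L, 1L) -
                                      as.integer(jitter) - 1L)
  K <- 0L
  repeat {
    if (add_months(eot, ann * (K + 1L) + tol) > censor) break
    K <- K + 1L
  }
  anns <- as.Date(vapply(seq_len(K), function(k) {
    place_in(add_months(eot, ann * k - tol), add_months(eot, ann * k + tol),
             jitter, mid = add_months(eot, ann * k))
  }, numeric(1)))
  list(initial = ev, bins = bins, n_bins = n_bins, eot_ev = eot_ev,
       midyear = midyear, annuals = anns, K = K)
}

pba_dates_for_level <- function(level, dx, eot, censor, jitter, rubric) {
  if (level == 1L) return(as.Date(character(0)))
  dur <- as.integer(eot - dx)
  if (level == 2L) return(dx + rint(0L, max(1L, min(dur, 365L))))
  if (level == 3L) {
    # both assessments after treatment ends: follow-up present but the
    # initial contact falls outside active treatment
    return(c(eot + 1L + rint(0L, 20L), eot + 30L + rint(0L, 20L)))
  }
  sched <- full_pba_schedule(dx, eot, censor, jitter, rubric)
  if (level == 5L) {
    return(c(sched$initial, sched$bins, sched$eot_ev, sched$midyear,
             sched$annuals))
  }
  # level 4: full schedule with one level-5 criterion deliberately violated,
  # chosen uniformly among the modes this record's shape allows
  modes <- "late_initial"
  if (sched$n_bins >= 2L) modes <- c(modes, "miss_bin")
  if (sched$K >= 1L) modes <- c(modes, "miss_annual")
  mode <- modes[sample.int(length(modes), 1L)]
  if (mode == "late_initial") {
    sched$initial <- dx + rubric$pba$initial_window_days + 1L + rint(0L, 14L)
  } else if (mode == "miss_bin") {
    sched$bins <- sched$bins[-sched$n_bins]
  } else {
    sched$annuals <- sched$annuals[-sched$K]
  }
  c(sched$initial, sched$bins, sched$eot_ev, sched$midyear, sched$annuals)
}

sample_demographics <- function(cohort_label) {
  ref <- reference_demographics()
  ref <- if (cohort_label %in% ref$cohort) {
    ref[ref$cohort == cohort_label, ]
  } else {
    pooled_percentages(ref)
  }
  pick <- function(dim_name) {
    sub <- ref[ref$dimension == dim_name, ]
    sub$category[sample.int(nrow(sub), 1L, prob = sub$n / sum(sub$n))]
  }
  bin <- pick("Age at Diagnosis")
  idx <- match(bin, age_bin_labels)
  lo <- c(0, 1, 3, 5, 8, 11, 15, 19)[idx]
  hi <- c(0, 2, 4, 7, 10, 14, 18, 25)[idx]
  list(
    sex = pick("Sex"), race = pick("Racial Identity"),
    dx_group = pick("Diagnosis Group"),
    age_at_dx = round(min(lo + stats::runif(1) * (hi - lo + 1), 25), 2)
  )
}

#' Generate one patient record scoring exactly a target level
#'
#' Construction by inversion: assessments are placed at requirement-window
#' midpoints (then jittered within bounds) so that the record scores exactly
#' `level` on `track` under [score_record()], and one criterion of the next
#' level is deliberately violated. Uses the current RNG state; seed via
#' `set.seed()` or use [generate_cohort()].
#'
#' @param track `"combined"`, `"SWA"` or `"PBA"`.
#' @param level target level 1..5.
#' @param config a [scenario_config()].
#' @param patient_id,cohort identifiers for the generated record.
#' @param dx_window optional length-2 `Date` vector overriding the cohort's
#'   diagnosis window.
#' @param rubric rubric the construction inverts (default rubric).
#' @return a one-row patient tibble with events attached.
#' @export
generate_record <- function(track, level, config = default_scenario(),
                            patient_id = "P1", cohort = NULL,
                            dx_window = NULL, rubric = default_rubric()) {
  track <- match.arg(track, c("combined", "SWA", "PBA"))
  level <- as.integer(level)
  stopifnot(level >= 1L, level <= 5L)
  hz <- config$followup_horizon_months
  ann <- rubric$annual$anniversary_months
  tol <- rubric$annual$tolerance_months

  needed <- 0
  if (track %in% c("SWA", "combined")) {
    if (level >= 4L) needed <- ann + tol
    if (level == 5L) needed <- 2L * ann + tol
  }
  if (track %in% c("PBA", "combined")) {
    if (level == 3L && track == "PBA") needed <- max(needed, 2)
    if (level >= 4L) needed <- max(needed, ann + tol)
  }
  if (hz < needed) {
    stop(sprintf(
      "target (%s, level %d) unattainable: followup_horizon_months = %s but %d months past EOT are required",
      track, level, format(hz), as.integer(needed)), call. = FALSE)
  }

  if (is.null(cohort)) cohort <- config$cohorts[[1L]]$label
  if (is.null(dx_window)) {
    hit <- which(vapply(config$cohorts, function(co) co$label == cohort,
                        logical(1)))
    dx_window <- if (length(hit)) as.Date(config$cohorts[[hit[1L]]]$dx_window)
                 else as.Date(c("2020-01-01", "2020-12-31"))
  }

  dx <- dx_window[1L] + rint(0L, as.integer(dx_window[2L] - dx_window[1L]))
  dur <- as.integer(round(stats::runif(1, config$treatment_duration_days[1],
                                       config$treatment_duration_days[2])))
  eot <- dx + dur
  censor <- add_months(eot, hz)
  j <- config$jitter_days

  swa <- as.Date(character(0))
  pba <- as.Date(character(0))
  if (track == "SWA") {
    swa <- swa_dates_for_level(level, dx, eot, censor, j, rubric)
  } else if (track == "PBA") {
    pba <- pba_dates_for_level(level, dx, eot, censor, j, rubric)
  } else {
    if (level == 2L) {
      swa <- swa_dates_for_level(2L, dx, eot, censor, j, rubric)
    } else if (level == 3L) {
      swa <- swa_dates_for_level(3L, dx, eot, censor, j, rubric)
      pba <- dx + rint(0L, max(1L, min(dur, 365L)))
    } else if (level >= 4L) {
      swa <- swa_dates_for_level(level, dx, eot, censor, j, rubric)
      pba <- pba_dates_for_level(level, dx, eot, censor, j, rubric)
    }
  }

  demo <- sample_demographics(cohort)
  patient_record(
    patient_id = patient_id, cohort = cohort, dx_date = dx, eot_date = eot,
    censor_date = censor, swa = swa, pba = pba, sex = demo$sex,
    race = demo$race, dx_group = demo$dx_group, age_at_dx = demo$age_at_dx
  )
}

#' Generate synthetic patient and event tables
#'
#' Draws each patient's target level from the cohort's level mixture, builds
#' the record by inversion with [generate_record()], and returns the two flat
#' tables in the CSV schema of [read_patients()] / [read_events()]. Each
#' patient is generated under its own seed derived from the scenario seed, so
#' output is deterministic given the seed and patients are independent.
#'
#' @param config a [scenario_config()].
#' @return a list with tibbles `patients` and `events`, plus the sampled
#'   `target_levels`.
#' @export
generate_cohort <- function(config = default_scenario()) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  n_total <- sum(vapply(config$cohorts, function(co) as.integer(co$n),
                        integer(1)))
  patient_seeds <- sample.int(.Machine$integer.max - 1L, n_total)

  records <- vector("list", n_total)
  targets <- integer(n_total)
  idx <- 0L
  for (co in config$cohorts) {
    mix <- co$level_mixture
    lv <- as.integer(names(mix))[
      sample.int(length(mix), co$n, replace = TRUE, prob = mix)]
    for (i in seq_len(co$n)) {
      idx <- idx + 1L
      targets[idx] <- lv[i]
      set.seed(patient_seeds[idx])
      records[[idx]] <- generate_record(
        track = config$track, level = lv[i], config = config,
        patient_id = sprintf("P%04d", idx), cohort = co$label
      )
    }
  }
  patients <- dplyr::bind_rows(records)
  events_list <- lapply(seq_len(nrow(patients)), function(i) {
    ev <- patients$events[[i]]
    if (nrow(ev) == 0L) return(NULL)
    tibble(patient_id = patients$patient_id[i], instrument = ev$instrument,
           date = ev$date)
  })
  events <- dplyr::bind_rows(events_list)
  if (nrow(events) == 0L) events <- empty_events()
  patients$events <- NULL
  list(patients = patients, events = events, target_levels = targets)
}
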