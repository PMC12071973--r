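#' @importFrom tibble tibble as_tibble
#' @importFrom stats setNames
NULL

instrument_levels <- c("SWA", "PBA")
sex_levels <- c("Female", "Male", "Intersex")
race_levels <- c(
  "White", "Asian American", "African American", "Hispanic/Latino",
  "American Indian/Alaskan Native", "Native Hawaiian/Pacific Islander",
  "Multiracial"
)
dx_group_levels <- c(
  "Non-oncology transplant", "Leukemia/Lymphoma", "Neuro-oncology",
  "Solid tumor"
)

patient_columns <- c("patient_id", "cohort", "dx_date", "eot_date",
                     "censor_date", "sex", "race", "dx_group", "age_at_dx")
event_columns <- c("patient_id", "instrument", "date")

# case-insensitive canonicalization against an allowed vocabulary;
# returns NA where no match
canonicalize <- function(x, levels) {
  idx <- match(tolower(trimws(x)), tolower(levels))
  levels[idx]
}

read_csv_strict <- function(path, required) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE, show_col_types = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

# collect row-level problems, then fail once listing all of them
fail_rows <- function(problems) {
  if (length(problems)) {
    stop(paste(problems, collapse = "\n"), call. = FALSE)
  }
}

#' Read a patient table
#'
#' Reads the long-format patient table: one row per patient with the cohort
#' label, anchor dates (diagnosis, optional end of treatment, censor) and
#' demographics. Dates must be ISO-8601 (`YYYY-MM-DD`); `eot_date` may be
#' empty. Category columns are matched case-insensitively against the
#' published vocabularies for sex, racial identity and diagnosis group.
#'
#' @param path path to a CSV file with columns `patient_id`, `cohort`,
#'   `dx_date`, `eot_date`, `censor_date`, `sex`, `race`, `dx_group`,
#'   `age_at_dx`.
#' @return a tibble with one validated row per patient (no events attached;
#'   see [attach_events()]).
#' @export
read_patients <- function(path) {
  df <- read_csv_strict(path, patient_columns)
  if (nrow(df) == 0L) {
    return(empty_patients())
  }
  problems <- character(0)
  row_no <- seq_len(nrow(df)) + 1L # file row, counting the header

  dup <- duplicated(df$patient_id)
  if (any(dup)) {
    stop("duplicate patient_id(s): ",
         paste(unique(df$patient_id[dup]), collapse = ", "), call. = FALSE)
  }

  dx <- parse_iso_date(df$dx_date)
  censor <- parse_iso_date(df$censor_date)
  eot_raw <- df$eot_date
  eot_missing <- is.na(eot_raw) | trimws(eot_raw) == ""
  eot <- parse_iso_date(ifelse(eot_missing, NA, eot_raw))

  for (i in seq_len(nrow(df))) {
    where <- paste0("row ", row_no[i], " (patient ", df$patient_id[i], "): ")
    if (is.na(dx[i])) {
      problems <- c(problems, paste0(where, "unparseable dx_date '", df$dx_date[i], "'"))
    }
    if (is.na(censor[i])) {
      problems <- c(problems, paste0(where, "unparseable censor_date '", df$censor_date[i], "'"))
    }
    if (!eot_missing[i] && is.na(eot[i])) {
      problems <- c(problems, paste0(where, "unparseable eot_date '", df$eot_date[i], "'"))
    }
  }
  fail_rows(problems)

  sex <- canonicalize(df$sex, sex_levels)
  race <- canonicalize(df$race, race_levels)
  dx_group <- canonicalize(df$dx_group, dx_group_levels)
  age <- suppressWarnings(as.numeric(df$age_at_dx))

  for (i in seq_len(nrow(df))) {
    where <- paste0("row ", row_no[i], " (patient ", df$patient_id[i], "): ")
    if (is.na(sex[i])) {
      problems <- c(problems, paste0(where, "unknown sex '", df$sex[i], "'"))
    }
    if (is.na(race[i])) {
      problems <- c(problems, paste0(where, "unknown race '", df$race[i], "'"))
    }
    if (is.na(dx_group[i])) {
      problems <- c(problems, paste0(where, "unknown dx_group '", df$dx_group[i], "'"))
    }
    if (is.na(age[i]) || age[i] < 0) {
      problems <- c(problems, paste0(where, "invalid age_at_dx '", df$age_at_dx[i], "'"))
    }
    if (!is.na(censor[i]) && !is.na(dx[i]) && censor[i] < dx[i]) {
      problems <- c(problems, paste0(where, "censor_date precedes dx_date"))
    }
    if (!is.na(eot[i]) && !is.na(dx[i]) && eot[i] < dx[i]) {
      problems <- c(problems, paste0(where, "eot_date precedes dx_date"))
    }
    if (!is.na(eot[i]) && !is.na(censor[i]) && eot[i] > censor[i]) {
      problems <- c(problems, paste0(where, "eot_date after censor_date"))
    }
  }
  fail_rows(problems)

  tibble(
    patient_id = df$patient_id,
    cohort = df$cohort,
    dx_date = dx,
    eot_date = eot,
    censor_date = censor,
    sex = sex,
    race = race,
    dx_group = dx_group,
    age_at_dx = age
  )
}

empty_patients <- function() {
  tibble(
    patient_id = character(0), cohort = character(0),
    dx_date = as.Date(character(0)), eot_date = as.Date(character(0)),
    censor_date = as.Date(character(0)), sex = character(0),
    race = character(0), dx_group = character(0), age_at_dx = numeric(0)
  )
}

#' Read an assessment-event table
#'
#' One row per assessment: patient id, instrument (`SWA` or `PBA`, matched
#' case-insensitively) and ISO-8601 date.
#'
#' @param path path to a CSV file with columns `patient_id`, `instrument`,
#'   `date`.
#' @return a tibble of events.
#' @export
read_events <- function(path) {
  df <- read_csv_strict(path, event_columns)
  if (nrow(df) == 0L) {
    return(empty_events())
  }
  instrument <- canonicalize(df$instrument, instrument_levels)
  if (anyNA(instrument)) {
    bad <- unique(df$instrument[is.na(instrument)])
    stop("unknown instrument value(s): ", paste(bad, collapse = ", "),
         " (expected SWA or PBA)", call. = FALSE)
  }
  date <- parse_iso_date(df$date)
  if (anyNA(date)) {
    bad <- which(is.na(date))
    stop(paste(sprintf("row %d: unparseable date '%s'", bad + 1L, df$date[bad]),
               collapse = "\n"), call. = FALSE)
  }
  tibble(patient_id = df$patient_id, instrument = instrument, date = date)
}

empty_events <- function() {
  tibble(patient_id = character(0), instrument = character(0),
         date = as.Date(character(0)))
}

#' Attach assessment events to patient records
#'
#' Joins the event table onto the patient table as an `events` list-column.
#' Events dated before the patient's diagnosis or after the censor date
#' cannot fall in any assessable window; under the default policy they are
#' dropped with a warning. Same-day duplicates of the same instrument are
#' collapsed to one event, and each patient's events are sorted by date.
#'
#' @param patients a patient tibble from [read_patients()].
#' @param events an event tibble from [read_events()].
#' @param out_of_range `"drop"` (default) drops pre-diagnosis and
#'   post-censor events with a warning; `"error"` fails instead.
#' @return `patients` with an `events` list-column (each element a tibble
#'   with columns `instrument`, `date`).
#' @export
attach_events <- function(patients, events, out_of_range = c("drop", "error")) {
  out_of_range <- match.arg(out_of_range)
  orphan <- setdiff(events$patient_id, patients$patient_id)
  if (length(orphan)) {
    stop("event(s) reference unknown patient_id(s): ",
         paste(sort(orphan), collapse = ", "), call. = FALSE)
  }

  idx <- match(events$patient_id, patients$patient_id)
  pre_dx <- events$date < patients$dx_date[idx]
  post_censor <- events$date > patients$censor_date[idx]
  if (any(pre_dx) || any(post_censor)) {
    msg <- sprintf(
      "dropping %d pre-diagnosis and %d post-censor event(s) for patient(s): %s",
      sum(pre_dx), sum(post_censor),
      paste(sort(unique(events$patient_id[pre_dx | post_censor])), collapse = ", ")
    )
    if (out_of_range == "error") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
    events <- events[!(pre_dx | post_censor), , drop = FALSE]
  }

  events <- events[!duplicated(events[c("patient_id", "instrument", "date")]), , drop = FALSE]
  events <- events[order(events$patient_id, events$date, events$instrument), , drop = FALSE]

  split_idx <- split(seq_len(nrow(events)),
                     factor(events$patient_id, levels = patients$patient_id))
  patients$events <- lapply(split_idx, function(i) {
    tibble(instrument = events$instrument[i], date = events$date[i])
  })
  patients
}

#' Construct a single patient record
#'
#' Convenience constructor used throughout the test suite and the synthetic
#' generator: builds one validated patient row with its event history from
#' plain date vectors. Events outside `[dx_date, censor_date]` are dropped
#' silently (they can never satisfy a window requirement); same-day duplicates
#' per instrument are collapsed.
#'
#' @param patient_id,cohort identifiers (free strings).
#' @param dx_date,censor_date diagnosis and censor dates (`Date` or ISO string).
#' @param eot_date optional end-of-treatment date (`NULL`/`NA` when treatment
#'   is ongoing or unknown).
#' @param swa,pba `Date` vectors of assessment dates per instrument.
#' @param sex,race,dx_group,age_at_dx demographics.
#' @return a one-row patient tibble with an `events` list-column.
#' @export
patient_record <- function(patient_id = "P1", dx_date, censor_date,
                           eot_date = NULL, swa = NULL, pba = NULL,
                           cohort = "cohort", sex = "Female", race = "White",
                           dx_group = "Solid tumor", age_at_dx = 5) {
  as_date1 <- function(x) {
    if (is.null(x) || (length(x) == 1L && is.na(x))) return(as.Date(NA))
    if (inherits(x, "Date")) x else as.Date(x)
  }
  dx <- as_date1(dx_date)
  censor <- as_date1(censor_date)
  eot <- as_date1(eot_date)
  stopifnot(!is.na(dx), !is.na(censor), censor >= dx)
  if (!is.na(eot)) stopifnot(eot >= dx, eot <= censor)

  mk <- function(dates, instrument) {
    if (is.null(dates) || !length(dates)) return(empty_events()[c("instrument", "date")])
    dates <- if (inherits(dates, "Date")) dates else as.Date(dates)
    dates <- dates[!is.na(dates) & dates >= dx & dates <= censor]
    tibble(instrument = rep(instrument, length(dates)), date = dates)
  }
  ev <- rbind(mk(swa, "SWA"), mk(pba, "PBA"))
  ev <- ev[!duplicated(ev[c("instrument", "date")]), , drop = FALSE]
  ev <- ev[order(ev$date, ev$instrument), , drop = FALSE]

  out <- tibble(
    patient_id = patient_id, cohort = cohort, dx_date = dx,
    eot_date = eot, censor_date = censor,
    sex = canonicalize(sex, sex_levels),
    race = canonicalize(race, race_levels),
    dx_group = canonicalize(dx_group, dx_group_levels),
    age_at_dx = as.numeric(age_at_dx)
  )
  out$events <- list(as_tibble(ev))
  out
}

#' Write and read scored records
#'
#' `write_scores()` writes one row per patient with the three matrix levels
#' and the per-criterion audit flags (columns prefixed `crit_`, values
#' `met`/`unmet`/`not_assessable`); `read_scores()` reads such a file back and
#' re-validates the levels. The pair round-trips losslessly.
#'
#' @param scores a scored tibble from [score_cohort()].
#' @param path output/input CSV path.
#' @return `read_scores()` returns the scored tibble; `write_scores()` its
#'   input, invisibly.
#' @export
write_scores <- function(scores, path) {
  needed <- c("patient_id", "cohort", "swa_level", "pba_level", "combined_level")
  missing <- setdiff(needed, names(scores))
  if (length(missing)) {
    stop("scores are missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cols <- c(needed, grep("^crit_", names(scores), value = TRUE))
  readr::write_csv(scores[cols], path, progress = FALSE)
  invisible(scores)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  df <- read_csv_strict(path, c("patient_id", "cohort", "swa_level",
                                "pba_level", "combined_level"))
  for (col in c("swa_level", "pba_level", "combined_level")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    if (nrow(df) && (anyNA(v) || any(v < 1L | v > 5L))) {
      stop("column ", col, " must contain integer levels in 1..5", call. = FALSE)
    }
    df[[col]] <- v
  }
  as_tibble(df)
}
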