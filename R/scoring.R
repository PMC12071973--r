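#' Matrix scoring of assessment histories
#'
#' The five-level adherence matrix is evaluated per patient on three tracks:
#' the social-work-assessment (SWA) ladder, the provider-biopsychosocial-
#' assessment (PBA) ladder, and the combined ladder that joins the SWA and PBA
#' clauses of each level. Ladders are cumulative: the reported level is the
#' highest whose requirement set (restricted to assessable windows) is fully
#' met, and a level all of whose incremental requirements are non-assessable
#' is unattainable rather than vacuously granted — a newly diagnosed patient
#' cannot score 5 simply because no follow-up window has closed yet.
#'
#' Track ladders:
#' \describe{
#'   \item{SWA}{1 none; 2 any SWA after diagnosis; 3 initial SWA within one
#'     month of diagnosis; 4 = 3 + an SWA in the first post-treatment year
#'     window (12 +/- 3 months after EOT); 5 = 3 + every assessable annual
#'     anniversary window covered (at least two windows must be assessable).}
#'   \item{PBA}{1 none; 2 exactly one PBA; 3 at least two PBAs (initial plus
#'     follow-up); 4 = 3 + initial PBA during active treatment; 5 = the full
#'     schedule: initial within 4 weeks of diagnosis, every complete
#'     3-month treatment bin covered, end-of-treatment window, at least two
#'     PBAs in the post-treatment year, and every assessable annual window.}
#'   \item{combined}{1 no events at all; 2 any assessment of either
#'     instrument; 3 SWA clauses of level 3 plus at least one PBA; 4 SWA
#'     clauses of level 4 plus at least two PBAs; 5 both track ladders at
#'     level 5. A combined score above 2 therefore requires the SWA within
#'     one month of diagnosis.}
#' }
#'
#' A requirement window whose end postdates the censor date imposes nothing,
#' but still counts as met when an assessment already lies in its observed
#' part, so adding events never lowers a level.
#'
#' @param record a one-row patient tibble with an `events` list-column (from
#'   [attach_events()] or [patient_record()]).
#' @param rubric a rubric list from [read_rubric()].
#' @return `score_record()` returns a list with `swa_level`, `pba_level`,
#'   `combined_level` (integers in 1..5) and `criteria`, a named character
#'   vector of per-criterion audit statuses (`met`, `unmet`,
#'   `not_assessable`). The three `*_level()` helpers return the bare integer.
#' @examples
#' rec <- patient_record(
#'   dx_date = "2022-03-01", eot_date = "2022-12-01",
#'   censor_date = "2025-06-01",
#'   swa = as.Date(c("2022-03-10", "2023-12-01", "2024-12-05")),
#'   pba = as.Date(c("2022-03-20", "2022-06-01", "2022-09-01", "2022-11-20",
#'                   "2023-04-01", "2023-11-25", "2024-12-01"))
#' )
#' score_record(rec)[c("swa_level", "pba_level", "combined_level")]
#' @export
score_record <- function(record, rubric = default_rubric()) {
  stopifnot(nrow(record) == 1L)
  ev <- record$events[[1L]]
  if (is.null(ev)) {
    stop("record has no events attached; call attach_events() first",
         call. = FALSE)
  }
  score_one(
    dx = record$dx_date, eot = record$eot_date, censor = record$censor_date,
    S = ev$date[ev$instrument == "SWA"],
    P = ev$date[ev$instrument == "PBA"],
    rubric = rubric
  )
}

#' @rdname score_record
#' @export
swa_track_level <- function(record, rubric = default_rubric()) {
  score_record(record, rubric)$swa_level
}

#' @rdname score_record
#' @export
pba_track_level <- function(record, rubric = default_rubric()) {
  score_record(record, rubric)$pba_level
}

#' @rdname score_record
#' @export
combined_level <- function(record, rubric = default_rubric()) {
  score_record(record, rubric)$combined_level
}

# Core evaluator on bare anchors and per-instrument date vectors.
# S and P are the retained (post-dx, pre-censor, deduplicated) event dates.
score_one <- function(dx, eot, censor, S, P, rubric) {
  r <- rubric
  has_eot <- !is.na(eot)
  nS <- length(S)
  nP <- length(P)
  in_win <- function(d, s, e) any(d >= s & d <= e)
  mk <- function(met, assessable) {
    list(met = met, assessable = assessable,
         status = if (met) "met" else if (assessable) "unmet" else "not_assessable")
  }

  crit <- list()

  swa_init_end <- dx + r$swa$initial_window_days
  pba_init_end <- dx + r$pba$initial_window_days
  crit$swa_any <- mk(nS > 0L, TRUE)
  crit$swa_initial <- mk(nS > 0L && in_win(S, dx, swa_init_end),
                         swa_init_end <= censor)

  # annual anniversary windows following end of treatment
  ann <- r$annual$anniversary_months
  tol <- r$annual$tolerance_months
  K <- 0L
  ann_start <- ann_end <- as.Date(character(0))
  if (has_eot) {
    repeat {
      e_k <- add_months(eot, ann * (K + 1L) + tol)
      if (e_k > censor) break
      ann_start <- c(ann_start, add_months(eot, ann * (K + 1L) - tol))
      ann_end <- c(ann_end, e_k)
      K <- K + 1L
    }
  }
  covers_all <- function(d) {
    K >= 1L && all(vapply(seq_len(K),
                          function(k) in_win(d, ann_start[k], ann_end[k]),
                          logical(1)))
  }

  if (has_eot) {
    a1s <- add_months(eot, ann - tol)
    a1e <- add_months(eot, ann + tol)
    crit$swa_post_eot_year <- mk(in_win(S, a1s, a1e), a1e <= censor)
  } else {
    crit$swa_post_eot_year <- mk(FALSE, FALSE)
  }
  crit$swa_annual_lifetime <- mk(has_eot && K >= 2L && covers_all(S),
                                 has_eot && K >= 2L)

  crit$pba_any <- mk(nP > 0L, TRUE)
  crit$pba_followup <- mk(nP >= 2L, TRUE)

  # "initial assessment completed" during active treatment; without an EOT
  # date active treatment is still open, so the initial-contact month stands in
  init_end <- if (has_eot) eot else swa_init_end
  crit$pba_initial_treatment <- mk(nP > 0L && min(P) <= init_end, TRUE)
  crit$pba_initial_4wk <- mk(nP > 0L && in_win(P, dx, pba_init_end),
                             pba_init_end <= censor)

  if (has_eot) {
    bm <- r$pba$treatment_bin_months
    bins_met <- TRUE
    i <- 1L
    repeat {
      close <- add_months(dx, bm * i)
      if (close > eot) break
      if (!in_win(P, add_months(dx, bm * (i - 1L)), close - 1L)) {
        bins_met <- FALSE
        break
      }
      i <- i + 1L
    }
    crit$pba_q3_treatment <- mk(bins_met, TRUE)

    em <- r$pba$eot_window_months
    ee <- add_months(eot, em)
    crit$pba_eot_window <- mk(in_win(P, add_months(eot, -em), ee), ee <= censor)

    pe <- add_months(eot, r$pba$post_eot_year_window_months)
    crit$pba_twice_post_eot <- mk(sum(P > eot & P <= pe) >= r$pba$post_eot_year_min_events,
                                  pe <= censor)
  } else {
    crit$pba_q3_treatment <- mk(FALSE, FALSE)
    crit$pba_eot_window <- mk(FALSE, FALSE)
    crit$pba_twice_post_eot <- mk(FALSE, FALSE)
  }
  crit$pba_annual_lifetime <- mk(has_eot && K >= 1L && covers_all(P),
                                 has_eot && K >= 1L)

  swa_level <-
    if (nS == 0L) 1L
    else if (!crit$swa_initial$met) 2L
    else if (!crit$swa_post_eot_year$met) 3L
    else if (!crit$swa_annual_lifetime$met) 4L
    else 5L

  # non-assessable schedule components are excluded from the level-5 conjunction
  pass <- function(cr) cr$met || !cr$assessable
  pba_full <- crit$pba_initial_4wk$met &&
    pass(crit$pba_q3_treatment) &&
    pass(crit$pba_eot_window) &&
    pass(crit$pba_twice_post_eot) &&
    crit$pba_annual_lifetime$met
  pba_level <-
    if (nP == 0L) 1L
    else if (nP == 1L) 2L
    else if (!crit$pba_initial_treatment$met) 3L
    else if (!pba_full) 4L
    else 5L

  combined <- if (nS + nP == 0L) 1L else 2L
  if (combined == 2L && swa_level >= 3L && nP >= 1L) combined <- 3L
  if (combined == 3L && swa_level >= 4L && nP >= 2L) combined <- 4L
  if (combined == 4L && swa_level == 5L && pba_level == 5L) combined <- 5L

  list(
    swa_level = swa_level,
    pba_level = pba_level,
    combined_level = combined,
    criteria = vapply(crit, `[[`, character(1), "status")
  )
}

#' Score every patient in a cohort table
#'
#' @param patients a patient tibble with an `events` list-column.
#' @param rubric a rubric list from [read_rubric()].
#' @return a tibble with `patient_id`, `cohort`, the three levels, and one
#'   `crit_*` audit column per rubric criterion.
#' @export
score_cohort <- function(patients, rubric = default_rubric()) {
  if (!"events" %in% names(patients)) {
    stop("patients have no events attached; call attach_events() first",
         call. = FALSE)
  }
  scores <- lapply(seq_len(nrow(patients)),
                   function(i) score_record(patients[i, ], rubric))
  crit_names <- if (length(scores)) names(scores[[1L]]$criteria) else character(0)
  out <- tibble(
    patient_id = patients$patient_id,
    cohort = patients$cohort,
    swa_level = vapply(scores, `[[`, integer(1), "swa_level"),
    pba_level = vapply(scores, `[[`, integer(1), "pba_level"),
    combined_level = vapply(scores, `[[`, integer(1), "combined_level")
  )
  for (cn in crit_names) {
    out[[paste0("crit_", cn)]] <-
      vapply(scores, function(s) s$criteria[[cn]], character(1))
  }
  out
}
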