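#' Resolve the rubric's requirement windows for one patient
#'
#' Turns the rubric schedule into concrete calendar intervals anchored on the
#' patient's diagnosis and end-of-treatment dates. All intervals are inclusive
#' of both endpoints (the post-treatment-year interval excludes the EOT day
#' itself, so its `start` is the day after EOT). A window is *assessable* when
#' its end falls on or before the censor date; only assessable windows impose
#' requirements on the adherence level. Annual anniversary windows are
#' enumerated from k = 1 while assessable. EOT-anchored windows are tagged
#' not assessable (with `NA` dates) when the record has no end-of-treatment
#' date.
#'
#' @param record a one-row patient tibble (see [patient_record()]).
#' @param rubric a rubric list from [read_rubric()].
#' @return a tibble with columns `name`, `k` (bin or anniversary index, `NA`
#'   otherwise), `start`, `end`, `assessable`.
#' @export
resolve_windows <- function(record, rubric = default_rubric()) {
  stopifnot(nrow(record) == 1L)
  dx <- record$dx_date
  eot <- record$eot_date
  censor <- record$censor_date
  r <- rubric
  has_eot <- !is.na(eot)

  rows <- list()
  add <- function(name, k, start, end, assessable) {
    rows[[length(rows) + 1L]] <<- tibble(
      name = name, k = as.integer(k), start = start, end = end,
      assessable = assessable
    )
  }

  swa_end <- dx + r$swa$initial_window_days
  pba_end <- dx + r$pba$initial_window_days
  add("swa_initial", NA, dx, swa_end, swa_end <= censor)
  add("pba_initial", NA, dx, pba_end, pba_end <= censor)

  if (has_eot) {
    bm <- r$pba$treatment_bin_months
    i <- 1L
    repeat {
      close <- add_months(dx, bm * i)
      if (close > eot) break # trailing partial bin imposes nothing
      add("treatment_bin", i, add_months(dx, bm * (i - 1L)), close - 1L, TRUE)
      i <- i + 1L
    }

    em <- r$pba$eot_window_months
    ee <- add_months(eot, em)
    add("eot_window", NA, add_months(eot, -em), ee, ee <= censor)

    pe <- add_months(eot, r$pba$post_eot_year_window_months)
    add("post_eot_year", NA, eot + 1L, pe, pe <= censor)

    ann <- r$annual$anniversary_months
    tol <- r$annual$tolerance_months
    k <- 1L
    repeat {
      end_k <- add_months(eot, ann * k + tol)
      if (end_k > censor) {
        if (k == 1L) add("annual", 1L, add_months(eot, ann - tol), end_k, FALSE)
        break
      }
      add("annual", k, add_months(eot, ann * k - tol), end_k, TRUE)
      k <- k + 1L
    }
  } else {
    na_d <- as.Date(NA)
    add("eot_window", NA, na_d, na_d, FALSE)
    add("post_eot_year", NA, na_d, na_d, FALSE)
    add("annual", 1L, na_d, na_d, FALSE)
  }

  dplyr::bind_rows(rows)
}
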