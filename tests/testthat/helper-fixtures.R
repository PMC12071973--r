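# Fixture builders shared across test files. Everything is generated in code;
# no fixture files are stored.

write_temp_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

patients_header <- paste(
  "patient_id,cohort,dx_date,eot_date,censor_date,sex,race,dx_group,age_at_dx"
)

patients_csv <- function(rows = character(0)) {
  write_temp_csv(c(patients_header, rows))
}

events_csv <- function(rows = character(0)) {
  write_temp_csv(c("patient_id,instrument,date", rows))
}

# exhaustive lattice of small records at canonical offsets: 0-3 events per
# instrument, with/without EOT, several censor horizons, two diagnosis dates
# (one at a month end to exercise day-of-month clamping)
lattice_cases <- function() {
  subsets_upto3 <- function(pool) {
    out <- list(pool[0])
    n <- length(pool)
    for (k in seq_len(min(3L, n))) {
      idx <- utils::combn(n, k)
      for (j in seq_len(ncol(idx))) out[[length(out) + 1L]] <- pool[idx[, j]]
    }
    out
  }
  cases <- list()
  add_case <- function(dx, eot, censor, S, P) {
    cases[[length(cases) + 1L]] <<- list(dx = dx, eot = eot, censor = censor,
                                         S = S, P = P)
  }
  for (dx in list(as.Date("2020-03-01"), as.Date("2020-07-31"))) {
    swa_sub <- subsets_upto3(c(dx + 10, dx + 45))
    pba_sub <- subsets_upto3(c(dx + 14, dx + 100, dx + 200))
    for (censor in list(dx + 60, dx + 400)) {
      for (S in swa_sub) for (P in pba_sub) {
        add_case(dx, as.Date(NA), censor, S, P)
      }
    }
    for (dur in c(270L, 540L)) {
      eot <- dx + dur
      swa_sub <- subsets_upto3(c(dx + 10, dx + 45,
                                 oracle_am(eot, 12), oracle_am(eot, 24)))
      pba_sub <- subsets_upto3(c(dx + 14, dx + 100, dx + 200, eot + 10,
                                 oracle_am(eot, 4), oracle_am(eot, 12),
                                 oracle_am(eot, 24)))
      for (censor in list(oracle_am(eot, 2), oracle_am(eot, 16),
                          oracle_am(eot, 40))) {
        for (S in swa_sub) for (P in pba_sub) add_case(dx, eot, censor, S, P)
      }
    }
  }
  cases
}

compare_lattice <- function(cases) {
  mismatch <- 0L
  for (cs in cases) {
    e <- engine_levels(cs$dx, cs$eot, cs$censor, cs$S, cs$P)
    o <- oracle_levels(cs$dx, cs$eot, cs$censor, cs$S, cs$P)
    if (!identical(unname(e), unname(o))) mismatch <- mismatch + 1L
  }
  mismatch
}

# random record at arbitrary (non-lattice) offsets, for property tests
random_record <- function() {
  dx <- as.Date("2018-01-01") + sample.int(1500L, 1L)
  has_eot <- stats::runif(1) < 0.7
  if (has_eot) {
    eot <- dx + sample.int(900L, 1L)
    censor <- eot + sample.int(1100L, 1L)
  } else {
    eot <- as.Date(NA)
    censor <- dx + 29L + sample.int(1500L, 1L)
  }
  span <- as.integer(censor - dx)
  nS <- sample(0:3, 1L)
  nP <- sample(0:4, 1L)
  list(dx = dx, eot = eot, censor = censor,
       S = dx + sample.int(span + 1L, nS, replace = TRUE) - 1L,
       P = dx + sample.int(span + 1L, nP, replace = TRUE) - 1L)
}

random_levels <- function(rc) {
  engine_levels(rc$dx, rc$eot, rc$censor, rc$S, rc$P)
}
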