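# Independent literal-clause evaluator of the five-level adherence matrix.
# Written before and independently of the package engine: every level clause
# is checked directly against the event dates, and month arithmetic goes
# through lubridate::add_with_rollback rather than the package's own
# calendar code, so the two paths cross-validate each other.

# memoized: the lattice reuses a handful of anchors thousands of times, but
# every distinct (date, offset) pair is still computed by lubridate
.oracle_am_cache <- new.env(parent = emptyenv())
oracle_am <- function(d, m) {
  key <- paste0(as.integer(d), "_", m)
  v <- .oracle_am_cache[[key]]
  if (is.null(v)) {
    v <- lubridate::add_with_rollback(d, months(m))
    .oracle_am_cache[[key]] <- v
  }
  v
}

oracle_levels <- function(dx, eot, censor, S, P) {
  has_eot <- !is.na(eot)
  S <- unique(S[S >= dx & S <= censor])
  P <- unique(P[P >= dx & P <= censor])
  any_in <- function(d, a, b) any(d >= a & d <= b)

  # annual anniversary windows while the window end is observable
  ann_wins <- list()
  k <- 1
  if (has_eot) repeat {
    e <- oracle_am(eot, 12 * k + 3)
    if (e > censor) break
    ann_wins[[k]] <- c(oracle_am(eot, 12 * k - 3), e)
    k <- k + 1
  }
  K <- length(ann_wins)
  all_covered <- function(d) {
    K >= 1 && all(vapply(ann_wins, function(w) any_in(d, w[1], w[2]),
                         logical(1)))
  }

  # SWA clauses, level by level
  s2 <- length(S) > 0
  s3 <- s2 && any_in(S, dx, dx + 30)
  s4 <- s3 && has_eot && any_in(S, oracle_am(eot, 9), oracle_am(eot, 15))
  s5 <- s3 && K >= 2 && all_covered(S)
  swa <- if (!s2) 1L else if (!s3) 2L else if (!s4) 3L else if (!s5) 4L else 5L

  # PBA clauses
  p2 <- length(P) >= 1
  p3 <- length(P) >= 2
  treat_end <- if (has_eot) eot else dx + 30
  p4 <- p3 && min(P) <= treat_end
  full <- FALSE
  if (p4 && has_eot) {
    init4 <- any_in(P, dx, dx + 28)
    bins_ok <- TRUE
    i <- 1
    repeat {
      close <- oracle_am(dx, 3 * i)
      if (close > eot) break
      if (!any_in(P, oracle_am(dx, 3 * (i - 1)), close - 1)) {
        bins_ok <- FALSE
        break
      }
      i <- i + 1
    }
    ew_end <- oracle_am(eot, 2)
    eot_ok <- any_in(P, oracle_am(eot, -2), ew_end) || ew_end > censor
    py_end <- oracle_am(eot, 15)
    twice_ok <- sum(P > eot & P <= py_end) >= 2 || py_end > censor
    full <- init4 && bins_ok && eot_ok && twice_ok && all_covered(P)
  }
  pba <- if (!p2) 1L else if (!p3) 2L else if (!p4) 3L else if (!full) 4L else 5L

  comb <- if (length(S) + length(P) == 0) 1L
    else if (!(s3 && p2)) 2L
    else if (!(s4 && p3)) 3L
    else if (!(s5 && pba == 5L)) 4L
    else 5L

  c(swa = swa, pba = pba, combined = comb)
}

# engine levels on the same bare inputs (retained-event contract applied here)
engine_levels <- function(dx, eot, censor, S, P) {
  S <- unique(S[S >= dx & S <= censor])
  P <- unique(P[P >= dx & P <= censor])
  sc <- carematrix:::score_one(dx, eot, censor, S, P, default_rubric())
  c(swa = sc$swa_level, pba = sc$pba_level, combined = sc$combined_level)
}
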