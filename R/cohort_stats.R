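#' Summarize matrix scores for one cohort
#'
#' Mean, sample standard deviation (n - 1 denominator) and the 95% confidence
#' interval of the mean, `mean +/- t(0.975, n - 1) * sd / sqrt(n)`.
#' `summarize_from_stats()` computes the same interval from a printed
#' `(mean, sd, n)` summary triple, so published bounds can be reproduced
#' without the raw scores.
#'
#' @param scores integer matrix levels in 1..5.
#' @param cohort cohort label carried into the output.
#' @param mean,sd,n a summary triple (sample SD).
#' @param conf confidence level (default 0.95).
#' @return a one-row tibble: `cohort`, `n`, `mean`, `sd`, `ci_low`, `ci_high`.
#'   With `n = 1` the SD and interval are `NA` (with a warning).
#' @examples
#' summarize_from_stats(mean = 2.19, sd = 0.880, n = 150)
#' @export
summarize_scores <- function(scores, cohort = NA_character_, conf = 0.95) {
  if (length(scores) == 0L) {
    stop("cannot summarize an empty score vector", call. = FALSE)
  }
  if (anyNA(scores) || any(scores < 1 | scores > 5)) {
    stop("scores must be matrix levels in 1..5", call. = FALSE)
  }
  n <- length(scores)
  if (n == 1L) {
    warning("n = 1: standard deviation and confidence interval are undefined",
            call. = FALSE)
    return(tibble(cohort = cohort, n = 1L, mean = as.numeric(scores),
                  sd = NA_real_, ci_low = NA_real_, ci_high = NA_real_))
  }
  summarize_from_stats(mean(scores), stats::sd(scores), n, cohort, conf)
}

#' @rdname summarize_scores
#' @export
summarize_from_stats <- function(mean, sd, n, cohort = NA_character_,
                                 conf = 0.95) {
  stopifnot(n >= 2L, sd >= 0)
  half <- stats::qt(1 - (1 - conf) / 2, df = n - 1) * sd / sqrt(n)
  tibble(cohort = cohort, n = as.integer(n), mean = mean, sd = sd,
         ci_low = mean - half, ci_high = mean + half)
}

#' Compare two cohorts with a pooled one-tailed t-test
#'
#' Pooled-variance (Student) two-sample t-test with `df = n1 + n2 - 2`. The
#' statistic is computed as `(mean_b - mean_a) / SE`, so when the second
#' (later) cohort scores higher the statistic is positive and
#' `direction = "greater"` tests that hypothesis; `p(greater) + p(less) = 1`.
#' With zero pooled variance the test degenerates: equal means give `t = 0`,
#' `p = 0.5`; unequal means give `p = 0` and the result is flagged.
#'
#' @param scores_a,scores_b score vectors for the first and second cohort.
#' @param direction alternative hypothesis for the second cohort relative to
#'   the first: `"greater"` (default) or `"less"`.
#' @param alpha significance threshold (default 0.05, uncorrected).
#' @return a one-row tibble: `t_statistic`, `df`, `p_one_tailed`, `direction`,
#'   `significant`, `degenerate`, `mean_a`, `mean_b`.
#' @export
compare_cohorts <- function(scores_a, scores_b,
                            direction = c("greater", "less"), alpha = 0.05) {
  direction <- match.arg(direction)
  n1 <- length(scores_a)
  n2 <- length(scores_b)
  if (n1 < 2L || n2 < 2L) {
    stop("both cohorts need at least two scores", call. = FALSE)
  }
  df <- n1 + n2 - 2L
  m1 <- mean(scores_a)
  m2 <- mean(scores_b)
  sp2 <- ((n1 - 1) * stats::var(scores_a) + (n2 - 1) * stats::var(scores_b)) / df
  degenerate <- FALSE
  if (sp2 == 0) {
    if (m1 == m2) {
      t_stat <- 0
      p <- 0.5
    } else {
      degenerate <- TRUE
      t_stat <- sign(m2 - m1) * Inf
      p <- if ((direction == "greater") == (m2 > m1)) 0 else 1
    }
  } else {
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    t_stat <- (m2 - m1) / se
    p <- stats::pt(t_stat, df, lower.tail = (direction == "less"))
  }
  tibble(
    t_statistic = t_stat, df = df, p_one_tailed = p, direction = direction,
    significant = p < alpha, degenerate = degenerate,
    mean_a = m1, mean_b = m2
  )
}

age_bin_breaks <- c(0, 1, 3, 5, 8, 11, 15, 19)
age_bin_labels <- c("<1 year old", "1-2 years old", "3-4 years old",
                    "5-7 years old", "8-10 years old", "11-14 years old",
                    "15-18 years old", "19-25 years old")

#' Bin age at diagnosis into the reporting categories
#'
#' Ages are binned by completed years (floor) into the eight closed integer
#' ranges used in the demographic tables: <1, 1-2, 3-4, 5-7, 8-10, 11-14,
#' 15-18, 19-25. Ages above 25 fall into the top bin with a warning (the
#' table has no higher category).
#'
#' @param age_at_dx numeric ages in years (>= 0).
#' @return a factor with the eight bin labels.
#' @export
age_bin <- function(age_at_dx) {
  if (anyNA(age_at_dx) || any(age_at_dx < 0)) {
    stop("age_at_dx must be non-negative and non-missing", call. = FALSE)
  }
  if (any(age_at_dx > 25)) {
    warning("age(s) above 25 binned into '19-25 years old'", call. = FALSE)
  }
  yrs <- pmin(floor(age_at_dx), 25)
  idx <- findInterval(yrs, age_bin_breaks)
  factor(age_bin_labels[idx], levels = age_bin_labels)
}

demographic_dimensions <- function() {
  list(
    "Age at Diagnosis" = age_bin_labels,
    "Diagnosis Group" = dx_group_levels,
    "Racial Identity" = race_levels,
    "Sex" = sex_levels
  )
}

#' Demographic tables per cohort and pooled
#'
#' Counts and percentages over four dimensions (age at diagnosis, diagnosis
#' group, racial identity, sex). Per-cohort percentages are rounded to
#' integers (the table convention); pooled percentages to two decimals (the
#' running-text convention). Every category of each dimension appears, with
#' zero counts where absent, so counts per dimension always sum to cohort n.
#'
#' @param patients a patient tibble (events not required).
#' @return a long tibble: `dimension`, `category`, `cohort` (cohort labels
#'   plus `"pooled"`), `n`, `pct`.
#' @export
demographics_table <- function(patients) {
  if (nrow(patients) == 0L) {
    stop("no patients to tabulate", call. = FALSE)
  }
  values <- list(
    "Age at Diagnosis" = as.character(age_bin(patients$age_at_dx)),
    "Diagnosis Group" = patients$dx_group,
    "Racial Identity" = patients$race,
    "Sex" = patients$sex
  )
  dims <- demographic_dimensions()
  cohorts <- unique(patients$cohort)
  rows <- list()
  for (dim_name in names(dims)) {
    cats <- dims[[dim_name]]
    v <- factor(values[[dim_name]], levels = cats)
    for (co in cohorts) {
      cnt <- table(v[patients$cohort == co])
      n_co <- sum(cnt)
      rows[[length(rows) + 1L]] <- tibble(
        dimension = dim_name, category = cats, cohort = co,
        n = as.integer(cnt),
        pct = if (n_co > 0) round(100 * as.integer(cnt) / n_co) else NA_real_
      )
    }
    cnt <- table(v)
    rows[[length(rows) + 1L]] <- tibble(
      dimension = dim_name, category = cats, cohort = "pooled",
      n = as.integer(cnt),
      pct = round(100 * as.integer(cnt) / nrow(patients), 2)
    )
  }
  dplyr::bind_rows(rows)
}

#' Pool published per-cohort demographic counts
#'
#' Sums per-cohort counts within each dimension/category and attaches pooled
#' percentages rounded to two decimals. Intended for count tables such as
#' [reference_demographics()].
#'
#' @param counts a tibble with columns `dimension`, `category`, `cohort`, `n`.
#' @return a tibble `dimension`, `category`, `n`, `pct`.
#' @export
pooled_percentages <- function(counts) {
  stopifnot(all(c("dimension", "category", "n") %in% names(counts)))
  pooled <- dplyr::summarise(
    dplyr::group_by(counts, .data$dimension, .data$category),
    n = sum(.data$n), .groups = "drop_last"
  )
  pooled <- dplyr::mutate(pooled, pct = round(100 * .data$n / sum(.data$n), 2))
  dplyr::ungroup(pooled)
}

#' Published demographic counts of the two study cohorts
#'
#' The per-cohort demographic counts of the two diagnosis-era cohorts
#' (2017-2018, n = 68; 2022-2023, n = 82) that motivated the default
#' simulation scenario. These published counts serve two purposes: pooled
#' percentage summaries can be recomputed from them, and the synthetic
#' generator samples demographics from their empirical proportions.
#'
#' @return a tibble with columns `dimension`, `category`, `cohort`, `n`.
#' @export
reference_demographics <- function() {
  cached <- get0("ref_demographics", envir = .carematrix_cache)
  if (!is.null(cached)) return(cached)
  dims <- demographic_dimensions()
  counts <- list(
    "2017-2018" = list(
      "Age at Diagnosis" = c(3L, 9L, 11L, 13L, 7L, 12L, 9L, 4L),
      "Diagnosis Group" = c(1L, 22L, 14L, 31L),
      "Racial Identity" = c(54L, 0L, 5L, 5L, 0L, 0L, 4L),
      "Sex" = c(24L, 44L, 0L)
    ),
    "2022-2023" = list(
      "Age at Diagnosis" = c(9L, 11L, 8L, 7L, 12L, 16L, 19L, 0L),
      "Diagnosis Group" = c(1L, 20L, 34L, 27L),
      "Racial Identity" = c(70L, 0L, 4L, 6L, 0L, 0L, 2L),
      "Sex" = c(41L, 41L, 0L)
    )
  )
  rows <- list()
  for (co in names(counts)) {
    for (dim_name in names(dims)) {
      rows[[length(rows) + 1L]] <- tibble(
        dimension = dim_name, category = dims[[dim_name]], cohort = co,
        n = counts[[co]][[dim_name]]
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  assign("ref_demographics", out, envir = .carematrix_cache)
  out
}
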