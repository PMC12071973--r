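#' Load an adherence rubric
#'
#' The rubric fixes the temporal tolerances of the five-level matrix: the
#' initial-contact windows for each instrument, the quarterly treatment bins,
#' the end-of-treatment window, the first-year follow-up window, and the
#' annual anniversary windows. The default shipped rubric encodes the UI SFCH
#' modification of Standard 1.A; an alternative YAML file with the same schema
#' can be supplied to every scoring function.
#'
#' @param path path to a rubric YAML file.
#' @return a validated rubric list with elements `name`, `version`, `swa`,
#'   `pba`, `annual`.
#' @seealso [default_rubric()]
#' @export
read_rubric <- function(path) {
  if (!file.exists(path)) {
    stop("rubric file not found: ", path, call. = FALSE)
  }
  r <- yaml::read_yaml(path)
  required <- list(
    swa = "initial_window_days",
    pba = c("initial_window_days", "treatment_bin_months", "eot_window_months",
            "post_eot_year_window_months", "post_eot_year_min_events"),
    annual = c("anniversary_months", "tolerance_months")
  )
  for (section in names(required)) {
    if (is.null(r[[section]])) {
      stop("rubric is missing section '", section, "'", call. = FALSE)
    }
    missing <- setdiff(required[[section]], names(r[[section]]))
    if (length(missing)) {
      stop("rubric section '", section, "' is missing field(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    bad <- vapply(r[[section]][required[[section]]],
                  function(v) !is.numeric(v) || length(v) != 1L || v < 0,
                  logical(1))
    if (any(bad)) {
      stop("rubric fields must be single non-negative numbers: ",
           paste(required[[section]][bad], collapse = ", "), call. = FALSE)
    }
  }
  structure(r, class = c("carematrix_rubric", "list"))
}

#' @rdname read_rubric
#' @export
default_rubric <- function() {
  cached <- get0("rubric", envir = .carematrix_cache)
  if (!is.null(cached)) return(cached)
  path <- system.file("extdata", "rubric_uisfch_1a.yaml",
                      package = "carematrix", mustWork = TRUE)
  r <- read_rubric(path)
  assign("rubric", r, envir = .carematrix_cache)
  r
}

.carematrix_cache <- new.env(parent = emptyenv())
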