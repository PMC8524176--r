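#' @keywords internal
trial_table_columns <- function() {
  c("subject_id", "block", "trial_idx", "stimulus", "response", "correct",
    "confidence", "rt_ms", "soa_ms", "comprehension_passed")
}

empty_trial_table <- function() {
  data.frame(subject_id = character(), block = integer(),
             trial_idx = integer(), stimulus = character(),
             response = character(), correct = logical(),
             confidence = numeric(), rt_ms = numeric(), soa_ms = numeric(),
             comprehension_passed = logical(), stringsAsFactors = FALSE)
}

# Validate a trial table against the canonical schema; errors name the
# offending column. `require_all = FALSE` only checks the columns present.
validate_trial_table <- function(table, required = trial_table_columns()) {
  if (!is.data.frame(table)) stop("trial table must be a data frame", call. = FALSE)
  missing <- setdiff(required, names(table))
  if (length(missing))
    stop("trial table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(names(table), trial_table_columns())
  if (length(extra))
    stop("unknown column(s) in trial table: ", paste(extra, collapse = ", "),
         call. = FALSE)
  bad <- table$stimulus[!table$stimulus %in% c("S1", "S2")]
  if (length(bad))
    stop("column `stimulus` must be coded \"S1\"/\"S2\" (found \"", bad[1],
         "\")", call. = FALSE)
  if (any(!table$response %in% c("S1", "S2")))
    stop("column `response` must be coded \"S1\"/\"S2\"", call. = FALSE)
  invisible(table)
}

#' Write a trial table in the canonical delimited-text format
#'
#' Comma-separated with a header row; columns exactly `subject_id, block,
#' trial_idx, stimulus, response, correct, confidence, rt_ms, soa_ms,
#' comprehension_passed`; stimuli/responses coded `"S1"`/`"S2"`; logicals
#' written as `"true"`/`"false"`; indices 1-based.
#'
#' @param table A trial table data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(table, path) {
  validate_trial_table(table)
  out <- table[, trial_table_columns()]
  out$correct <- ifelse(out$correct, "true", "false")
  out$comprehension_passed <- ifelse(out$comprehension_passed, "true", "false")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trial table from the canonical delimited-text format
#'
#' @param path Path to a file written by [write_trial_table()] (or any file
#'   following the same schema).
#' @return A validated trial table data frame.
#' @export
read_trial_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing <- setdiff(trial_table_columns(), names(raw))
  if (length(missing))
    stop("file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  parse_bool <- function(x, col) {
    v <- tolower(x)
    if (any(!v %in% c("true", "false")))
      stop("column `", col, "` must be \"true\"/\"false\"", call. = FALSE)
    v == "true"
  }
  tab <- data.frame(
    subject_id = raw$subject_id,
    block = as.integer(raw$block),
    trial_idx = as.integer(raw$trial_idx),
    stimulus = raw$stimulus, response = raw$response,
    correct = parse_bool(raw$correct, "correct"),
    confidence = as.numeric(raw$confidence),
    rt_ms = as.numeric(raw$rt_ms),
    soa_ms = as.numeric(raw$soa_ms),
    comprehension_passed = parse_bool(raw$comprehension_passed,
                                      "comprehension_passed"),
    stringsAsFactors = FALSE)
  validate_trial_table(tab)
}

#' Read a cohort/design configuration file
#'
#' YAML or JSON (by extension) with two optional top-level maps:
#' \describe{
#'   \item{design}{fields of [experiment_design()]: `n_subjects`, `n_trials`,
#'     `n_blocks`, `soa_start_ms`, `step_factor`, `soa_min_ms`, `soa_max_ms`.}
#'   \item{cohort}{`sdlog`, `shift_sd`, and a `mean` map with fields of
#'     [observer_params()].}
#' }
#' Unknown keys raise an error naming the key. Missing keys take the package
#' defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `design` ([experiment_design()]) and
#'   `cohort` ([cohort_spec()]).
#' @export
read_cohort_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), c("design", "cohort"))
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  check_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad))
      stop("unknown key(s) in `", where, "`: ", paste(bad, collapse = ", "),
           call. = FALSE)
    x
  }
  dsn <- check_keys(cfg$design %||% list(),
                    names(formals(experiment_design)), "design")
  design <- do.call(experiment_design, dsn)
  coh <- check_keys(cfg$cohort %||% list(), c("mean", "sdlog", "shift_sd"),
                    "cohort")
  mean_pars <- do.call(observer_params,
                       check_keys(coh$mean %||% list(),
                                  names(formals(observer_params)),
                                  "cohort$mean"))
  spec <- cohort_spec(mean = mean_pars,
                      sdlog = coh$sdlog %||% 0.2,
                      shift_sd = coh$shift_sd %||% 0.05)
  list(design = design, cohort = spec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
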