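#' Drop the practice block
#'
#' Removes block 1; only the last five of the six blocks enter the analysis.
#' Idempotent: a table without block-1 rows is returned unchanged.
#'
#' @param table A trial table with a `block` column.
#' @return The table restricted to blocks > 1.
#' @export
filter_blocks <- function(table) {
  if (!"block" %in% names(table))
    stop("trial table is missing column(s): block", call. = FALSE)
  table[table$block != 1L, , drop = FALSE]
}

#' Drop trials with extreme response times
#'
#' Removes trials with RT strictly below 250 ms or strictly above 5000 ms;
#' trials at exactly the boundaries are retained.
#'
#' @param table A trial table with an `rt_ms` column.
#' @return The table without extreme-RT trials.
#' @export
filter_trials <- function(table) {
  if (!"rt_ms" %in% names(table))
    stop("trial table is missing column(s): rt_ms", call. = FALSE)
  table[table$rt_ms >= 250 & table$rt_ms <= 5000, , drop = FALSE]
}

exclusion_reason_levels <- function() {
  c("low_accuracy", "extreme_rt_fraction", "failed_comprehension",
    "too_few_errors_per_type", "too_few_confidence_levels")
}

#' Assess one participant against the exclusion rules
#'
#' Five rules: (1) accuracy below 60%; (2) RT outside \[250 ms, 5 s\] on more
#' than 25% of trials; (3) failed comprehension check; (4) fewer than two
#' errors of either type (S1 called S2, or S2 called S1); (5) fewer than two
#' distinct confidence levels within either response category. The RT-fraction
#' rule is evaluated on all trials; the accuracy, error-count and
#' confidence-level rules on the analysed blocks (block 1 removed) before RT
#' filtering, so that trial filtering cannot itself create an exclusion. Set
#' `accuracy_all_blocks = TRUE` to score accuracy on all six blocks instead.
#'
#' Rows with missing confidence are dropped with a warning before the checks.
#'
#' @param table A single participant's full (unfiltered) trial table.
#' @param accuracy_all_blocks Logical; score the accuracy rule on all blocks?
#' @return A list of class `exclusion_report` with fields `subject_id`,
#'   `included`, `reasons` (character subset of the five rule names),
#'   `n_trials_before`, `n_trials_after` (rows surviving block and RT
#'   filtering).
#' @export
assess_subject <- function(table, accuracy_all_blocks = FALSE) {
  validate_trial_table(table)
  if (length(unique(table$subject_id)) > 1)
    stop("`assess_subject` expects a single participant's table", call. = FALSE)
  if (anyNA(table$confidence)) {
    warning("dropping ", sum(is.na(table$confidence)),
            " row(s) with missing confidence")
    table <- table[!is.na(table$confidence), , drop = FALSE]
  }
  n_before <- nrow(table)
  reasons <- character()
  if (n_before == 0) {
    return(structure(list(subject_id = NA_character_, included = FALSE,
                          reasons = c("too_few_errors_per_type",
                                      "too_few_confidence_levels"),
                          n_trials_before = 0L, n_trials_after = 0L),
                     class = "exclusion_report"))
  }
  analyzed <- filter_blocks(table)
  acc_tab <- if (accuracy_all_blocks) table else analyzed
  if (mean(acc_tab$correct) < 0.60) reasons <- c(reasons, "low_accuracy")
  if (mean(table$rt_ms < 250 | table$rt_ms > 5000) > 0.25)
    reasons <- c(reasons, "extreme_rt_fraction")
  if (!table$comprehension_passed[1])
    reasons <- c(reasons, "failed_comprehension")
  err_s1 <- sum(analyzed$stimulus == "S1" & analyzed$response == "S2")
  err_s2 <- sum(analyzed$stimulus == "S2" & analyzed$response == "S1")
  if (err_s1 < 2 || err_s2 < 2)
    reasons <- c(reasons, "too_few_errors_per_type")
  n_levels <- vapply(c("S1", "S2"), function(r) {
    length(unique(analyzed$confidence[analyzed$response == r]))
  }, integer(1))
  if (any(n_levels < 2))
    reasons <- c(reasons, "too_few_confidence_levels")
  structure(list(subject_id = table$subject_id[1],
                 included = length(reasons) == 0, reasons = reasons,
                 n_trials_before = n_before,
                 n_trials_after = nrow(filter_trials(analyzed))),
            class = "exclusion_report")
}

#' Apply all exclusion rules to a multi-participant table
#'
#' Assesses every participant with [assess_subject()]; the clean table
#' contains only included participants' block-filtered, RT-filtered rows.
#' Participant order is preserved. Idempotent on its own output.
#'
#' @param table A multi-participant trial table.
#' @param accuracy_all_blocks Passed to [assess_subject()].
#' @return A list with `clean` (the filtered trial table) and `reports` (a
#'   data frame with one row per input participant: `subject_id`, `included`,
#'   `reasons` as a `;`-joined string, `n_trials_before`, `n_trials_after`).
#' @export
apply_exclusions <- function(table, accuracy_all_blocks = FALSE) {
  validate_trial_table(table)
  ids <- unique(table$subject_id)
  reports <- lapply(ids, function(id) {
    assess_subject(table[table$subject_id == id, , drop = FALSE],
                   accuracy_all_blocks = accuracy_all_blocks)
  })
  rep_df <- data.frame(
    subject_id = ids,
    included = vapply(reports, `[[`, logical(1), "included"),
    reasons = vapply(reports, function(r) paste(r$reasons, collapse = ";"),
                     character(1)),
    n_trials_before = vapply(reports, `[[`, integer(1), "n_trials_before"),
    n_trials_after = vapply(reports, `[[`, integer(1), "n_trials_after"),
    stringsAsFactors = FALSE)
  keep <- ids[rep_df$included]
  clean <- table[table$subject_id %in% keep & !is.na(table$confidence), ,
                 drop = FALSE]
  clean <- filter_trials(filter_blocks(clean))
  rownames(clean) <- NULL
  list(clean = clean, reports = rep_df)
}

#' Per-participant descriptive statistics
#'
#' @param table A clean single-participant trial table (exclusions applied).
#' @return A one-row data frame: `accuracy`, `p_s1_response`, `response_bias`
#'   (`p_s1_response - 0.5`), `mean_confidence`,
#'   `conf_correct_minus_incorrect` (NA when the participant has no correct or
#'   no incorrect trials), `last_trial_soa_ms`.
#' @export
describe_subject <- function(table) {
  validate_trial_table(table)
  if (nrow(table) == 0) stop("empty trial table", call. = FALSE)
  p_s1 <- mean(table$response == "S1")
  conf_diff <- if (any(table$correct) && any(!table$correct)) {
    mean(table$confidence[table$correct]) -
      mean(table$confidence[!table$correct])
  } else NA_real_
  data.frame(
    accuracy = mean(table$correct), p_s1_response = p_s1,
    response_bias = p_s1 - 0.5, mean_confidence = mean(table$confidence),
    conf_correct_minus_incorrect = conf_diff,
    last_trial_soa_ms = table$soa_ms[which.max(table$trial_idx)])
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Exclusion report for", x$subject_id, "\n")
  cat("  included:", x$included, "\n")
  if (length(x$reasons)) cat("  reasons:", paste(x$reasons, collapse = ", "), "\n")
  cat("  trials before/after filtering:", x$n_trials_before, "/",
      x$n_trials_after, "\n")
  invisible(x)
}
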