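#' Per-participant summary statistics for the four hypotheses
#'
#' \describe{
#'   \item{h1}{Metacognitive bias asymmetry: mean confidence on S1-response
#'     trials minus mean confidence on S2-response trials.}
#'   \item{h2}{Metacognitive sensitivity asymmetry: `delta_auc` from
#'     [subject_asymmetry()].}
#'   \item{h3}{Bias-controlled asymmetry: [h3_statistic()].}
#'   \item{h4}{Response-time asymmetry: mean natural-log RT on S1-response
#'     trials minus mean log RT on S2-response trials (negative when S1
#'     responses are faster).}
#' }
#'
#' @param table A clean single-participant trial table meeting the inclusion
#'   rules.
#' @return A one-row data frame: `subject_id`, `h1`, `h2`, `h3`, `h4`.
#' @export
summarize_subject <- function(table) {
  validate_trial_table(table)
  s1 <- table[table$response == "S1", , drop = FALSE]
  s2 <- table[table$response == "S2", , drop = FALSE]
  if (nrow(s1) == 0 || nrow(s2) == 0)
    stop("inclusion rule violated: a response category is empty", call. = FALSE)
  asym <- subject_asymmetry(table)
  data.frame(
    subject_id = table$subject_id[1],
    h1 = mean(s1$confidence) - mean(s2$confidence),
    h2 = asym$delta_auc,
    h3 = as.numeric(h3_statistic(table)),
    h4 = mean(log(s1$rt_ms)) - mean(log(s2$rt_ms)),
    stringsAsFactors = FALSE)
}

# Registered test directions for the four hypotheses: higher confidence,
# higher metacognitive sensitivity, higher bias-controlled sensitivity for S1
# responses, and faster (lower log RT) S1 responses.
hypothesis_directions <- function() {
  c(h1 = "greater", h2 = "greater", h3 = "greater", h4 = "less")
}

#' Run the full per-experiment analysis
#'
#' Applies the exclusion rules, computes the four per-participant summaries,
#' and tests each hypothesis with a one-tailed t-test (registered directions:
#' h1/h2/h3 greater, h4 less) and a two-sided JZS Bayes factor. The verdict
#' for each hypothesis is keyed to the Bayes factor (`BF10 > 3` supports the
#' alternative, `BF01 > 3` the null, otherwise inconclusive), with the
#' frequentist result reported alongside and conflicts between the two
#' flagged.
#'
#' @param table A multi-participant trial table.
#' @param config Optional list: `rscale` (prior scale, default 0.65),
#'   `alpha` (default 0.05), `accuracy_all_blocks` (default FALSE).
#' @return An object of class `experiment_report`: `n_recruited`,
#'   `n_included`, `exclusion_counts` (per-rule tallies), `descriptives`
#'   (means of [describe_subject()] fields over included participants),
#'   `hypotheses` (one row per hypothesis: group mean, t, df, one-tailed p,
#'   Cohen's d, BF10, BF01, verdict, conflict flag), `summaries` (the
#'   per-participant table) and `exclusions` (the per-participant report).
#' @export
run_experiment_analysis <- function(table, config = list()) {
  rscale <- config$rscale %||% 0.65
  alpha <- config$alpha %||% 0.05
  if (nrow(table) == 0) stop("empty trial table", call. = FALSE)
  excl <- apply_exclusions(table,
                           accuracy_all_blocks =
                             config$accuracy_all_blocks %||% FALSE)
  clean <- excl$clean
  ids <- unique(clean$subject_id)
  if (length(ids) < 2)
    stop("fewer than 2 included participants", call. = FALSE)
  summaries <- do.call(rbind, lapply(ids, function(id)
    summarize_subject(clean[clean$subject_id == id, , drop = FALSE])))
  desc <- do.call(rbind, lapply(ids, function(id)
    describe_subject(clean[clean$subject_id == id, , drop = FALSE])))
  dirs <- hypothesis_directions()
  hyp <- do.call(rbind, lapply(names(dirs), function(h) {
    tt <- one_sample_t(summaries[[h]], dirs[[h]])
    bf <- jzs_bf_from_t(tt$t, tt$n, rscale = rscale)
    verdict <- if (bf$bf10 > 3) "alternative"
      else if (bf$bf01 > 3) "null" else "inconclusive"
    significant <- tt$p_one_tailed < alpha
    data.frame(hypothesis = h, direction = dirs[[h]], mean = tt$mean,
               t = tt$t, df = tt$df, p_one_tailed = tt$p_one_tailed,
               cohens_d = tt$cohens_d, bf10 = bf$bf10, bf01 = bf$bf01,
               verdict = verdict,
               conflict = (significant && verdict != "alternative") ||
                 (!significant && verdict == "alternative"),
               stringsAsFactors = FALSE)
  }))
  reason_counts <- vapply(exclusion_reason_levels(), function(r)
    sum(grepl(r, excl$reports$reasons, fixed = TRUE)), integer(1))
  structure(list(
    n_recruited = nrow(excl$reports), n_included = length(ids),
    rscale = rscale, exclusion_counts = reason_counts,
    descriptives = colMeans(desc, na.rm = TRUE), hypotheses = hyp,
    summaries = summaries, exclusions = excl$reports),
    class = "experiment_report")
}

#' Correlations between per-participant effect summaries
#'
#' Pearson correlations across participants between the confidence asymmetry
#' and the response-time asymmetry (`h1`, `h4`) and between the confidence
#' asymmetry and the bias-controlled sensitivity asymmetry (`h1`, `h3`).
#'
#' @param summaries A data frame of per-participant summaries with columns
#'   `h1`, `h3`, `h4` (>= 3 rows).
#' @return A data frame with one row per pair: `pair`, `r`, `n`, `note`
#'   (`"zero variance"` with `r = NA` when a member is constant).
#' @export
correlate_effects <- function(summaries) {
  stopifnot(is.data.frame(summaries))
  if (nrow(summaries) < 3)
    stop("need at least 3 participants", call. = FALSE)
  one <- function(a, b) {
    x <- summaries[[a]]; y <- summaries[[b]]
    ok <- stats::complete.cases(x, y)
    if (stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0) {
      data.frame(pair = paste0(a, "-", b), r = NA_real_, n = sum(ok),
                 note = "zero variance", stringsAsFactors = FALSE)
    } else {
      data.frame(pair = paste0(a, "-", b), r = stats::cor(x[ok], y[ok]),
                 n = sum(ok), note = "", stringsAsFactors = FALSE)
    }
  }
  rbind(one("h1", "h4"), one("h1", "h3"))
}

#' Render an experiment report as plain text
#'
#' @param report An `experiment_report` object.
#' @return A character vector of lines.
#' @export
report_text <- function(report) {
  stopifnot(inherits(report, "experiment_report"))
  d <- report$descriptives
  h <- report$hypotheses
  lines <- c(
    sprintf("Participants: %d recruited, %d included",
            report$n_recruited, report$n_included),
    sprintf("Exclusions: %s",
            paste(sprintf("%s=%d", names(report$exclusion_counts),
                          report$exclusion_counts), collapse = ", ")),
    sprintf("Mean accuracy %.3f; response bias %+.3f; mean confidence %.3f; mean last-trial SOA %.1f ms",
            d[["accuracy"]], d[["response_bias"]], d[["mean_confidence"]],
            d[["last_trial_soa_ms"]]),
    sprintf("Inference (JZS rscale %.3g; verdicts keyed to the Bayes factor):",
            report$rscale),
    vapply(seq_len(nrow(h)), function(i) {
      sprintf("  %s (%s): M = %+.4f, t(%d) = %.2f, p = %.4f, d = %.2f, BF10 = %.3g -> %s%s",
              h$hypothesis[i], h$direction[i], h$mean[i], h$df[i], h$t[i],
              h$p_one_tailed[i], h$cohens_d[i], h$bf10[i], h$verdict[i],
              if (h$conflict[i]) " [t-test and BF disagree]" else "")
    }, character(1)))
  lines
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(report_text(x), sep = "\n")
  invisible(x)
}

#' Serialize an experiment report to JSON
#'
#' Writes the report (counts, descriptives, per-hypothesis inference and
#' per-participant summaries) with all analysis inputs echoed.
#'
#' @param report An `experiment_report` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "experiment_report"))
  jsonlite::write_json(
    list(n_recruited = report$n_recruited, n_included = report$n_included,
         rscale = report$rscale,
         exclusion_counts = as.list(report$exclusion_counts),
         descriptives = as.list(report$descriptives),
         hypotheses = report$hypotheses, summaries = report$summaries,
         exclusions = report$exclusions),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
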