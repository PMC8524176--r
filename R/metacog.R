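#' Response-conditional type-2 ROC curve
#'
#' For a set of trials sharing one response, plots the empirical cumulative
#' distribution of confidence ratings (from high to low) for correct trials
#' (y) against the same cumulative distribution for incorrect trials (x).
#' Cumulation is "at or above" each distinct confidence value, so tied ratings
#' share a single point; the endpoints (0,0) and (1,1) close the curve. The
#' area under this curve (trapezoidal) is the type-2 sensitivity measure
#' auROC2 and equals the rank concordance
#' `P(conf_correct > conf_incorrect) + P(tie)/2`.
#'
#' @param confidences Numeric vector of confidence ratings in `[0, 1]`.
#' @param corrects Logical vector, same length: was the trial correct?
#' @param response Optional label (`"S1"`/`"S2"`) carried on the curve.
#' @return An object of class `rcroc_curve`: a list with `response`, `points`
#'   (data frame with columns `fpr`, `tpr`) and `auc`.
#' @export
#' @examples
#' cv <- rcroc_curve(c(1, 1, 0), c(TRUE, TRUE, FALSE))
#' cv$auc  # 1: perfect metacognition
rcroc_curve <- function(confidences, corrects, response = NA_character_) {
  stopifnot(length(confidences) == length(corrects), is.logical(corrects))
  if (anyNA(confidences) || anyNA(corrects))
    stop("missing values in confidence or correctness", call. = FALSE)
  n_c <- sum(corrects); n_i <- sum(!corrects)
  if (n_c == 0 || n_i == 0)
    stop("rc-ROC curve undefined: need at least one correct and one ",
         "incorrect trial", call. = FALSE)
  u <- sort(unique(confidences), decreasing = TRUE)
  idx <- match(confidences, u)
  cnt_c <- tabulate(idx[corrects], nbins = length(u))
  cnt_i <- tabulate(idx[!corrects], nbins = length(u))
  tpr <- cumsum(cnt_c) / n_c
  fpr <- cumsum(cnt_i) / n_i
  pts <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  structure(list(response = response, points = pts, auc = trapezoid_auc(pts)),
            class = "rcroc_curve")
}

trapezoid_auc <- function(pts) {
  sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
}

#' Area under a type-2 ROC curve
#'
#' Trapezoidal area of the curve's points; for curves built by
#' [rcroc_curve()] this equals the pairwise rank concordance of the underlying
#' confidence samples exactly.
#'
#' @param curve An `rcroc_curve` object.
#' @return The area, in `[0, 1]`.
#' @export
auroc2 <- function(curve) {
  stopifnot(inherits(curve, "rcroc_curve"))
  trapezoid_auc(curve$points)
}

#' Metacognitive asymmetry for one participant
#'
#' Splits a participant's trials by response, builds the response-conditional
#' type-2 ROC for each, and returns both areas and their difference
#' `delta_auc = auROC2(S1 responses) - auROC2(S2 responses)` — positive when
#' confidence discriminates correct from incorrect trials better following
#' "S1" responses.
#'
#' @param table A clean single-participant trial table. The participant must
#'   satisfy the inclusion rules: at least two errors within each response and
#'   at least two distinct confidence levels per response; violations raise an
#'   error naming the failed rule.
#' @return An object of class `asymmetry_summary`: `auc_s1`, `auc_s2`,
#'   `delta_auc`, and the two curves in `curves`.
#' @export
subject_asymmetry <- function(table) {
  validate_trial_table(table)
  curves <- lapply(c("S1", "S2"), function(resp) {
    sub <- table[table$response == resp, , drop = FALSE]
    if (sum(!sub$correct) < 2)
      stop("inclusion rule violated (too_few_errors_per_type): fewer than 2 ",
           "errors among ", resp, " responses", call. = FALSE)
    if (length(unique(sub$confidence)) < 2)
      stop("inclusion rule violated (too_few_confidence_levels): fewer than ",
           "2 distinct confidence levels among ", resp, " responses",
           call. = FALSE)
    rcroc_curve(sub$confidence, sub$correct, response = resp)
  })
  names(curves) <- c("S1", "S2")
  structure(list(auc_s1 = curves$S1$auc, auc_s2 = curves$S2$auc,
                 delta_auc = curves$S1$auc - curves$S2$auc, curves = curves),
            class = "asymmetry_summary")
}

#' Bin confidence ratings over a participant's dynamic range
#'
#' Assigns each rating to one of `n_bins` equal-width bins spanning the
#' participant's own \[min, max\] of ratings. Used for plotting only — auROC2
#' is always computed on the raw continuous ratings.
#'
#' @param confidences Non-empty numeric vector.
#' @param n_bins Number of bins (default 20).
#' @return Integer bin assignments in `1:n_bins`, with the bin `breaks` as an
#'   attribute. A zero-range input yields a single bin with a warning.
#' @export
bin_confidence <- function(confidences, n_bins = 20) {
  stopifnot(length(confidences) > 0, n_bins >= 1)
  lo <- min(confidences); hi <- max(confidences)
  if (lo == hi) {
    warning("zero range in confidence ratings: single-bin assignment")
    out <- rep(1L, length(confidences))
    attr(out, "breaks") <- c(lo, hi)
    return(out)
  }
  breaks <- seq(lo, hi, length.out = n_bins + 1)
  out <- findInterval(confidences, breaks, all.inside = TRUE)
  attr(out, "breaks") <- breaks
  out
}

#' Export one or more type-2 ROC curves as delimited text
#'
#' Writes columns `response`, `fpr`, `tpr` (CSV, header row).
#'
#' @param curves An `rcroc_curve` or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rcroc <- function(curves, path) {
  if (inherits(curves, "rcroc_curve")) curves <- list(curves)
  rows <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(response = cv$response, cv$points, stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plot a response-conditional type-2 ROC curve
#'
#' Draws the curve with the chance diagonal; multiple curves overlay.
#'
#' @param curves An `rcroc_curve` or list of them.
#' @param file Optional PNG path; when given, the plot is written there.
#' @param main Plot title.
#' @return `NULL`, invisibly.
#' @export
plot_rcroc <- function(curves, file = NULL, main = "Response-conditional type-2 ROC") {
  if (inherits(curves, "rcroc_curve")) curves <- list(curves)
  if (!is.null(file)) {
    grDevices::png(file, width = 600, height = 600)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 2, col = "grey",
                 xlab = "P(conf >= level | incorrect)",
                 ylab = "P(conf >= level | correct)", main = main)
  cols <- c(S1 = "firebrick", S2 = "steelblue")
  for (cv in curves) {
    col <- if (!is.na(cv$response) && cv$response %in% names(cols))
      cols[[cv$response]] else "black"
    graphics::lines(cv$points$fpr, cv$points$tpr, col = col, lwd = 2)
  }
  labs <- vapply(curves, function(cv)
    sprintf("%s (auROC2 = %.3f)", cv$response, cv$auc), character(1))
  graphics::legend("bottomright", legend = labs, lwd = 2,
                   col = vapply(curves, function(cv)
                     if (!is.na(cv$response) && cv$response %in% names(cols))
                       cols[[cv$response]] else "black", character(1)))
  invisible(NULL)
}

#' @export
print.rcroc_curve <- function(x, ...) {
  cat("Response-conditional type-2 ROC",
      if (!is.na(x$response)) paste0("(", x$response, " responses)"), "\n")
  cat("  points:", nrow(x$points), " auROC2:", round(x$auc, 4), "\n")
  invisible(x)
}

#' @export
print.asymmetry_summary <- function(x, ...) {
  cat("Metacognitive asymmetry\n")
  cat(sprintf("  auROC2 S1: %.4f  auROC2 S2: %.4f  delta: %+.4f\n",
              x$auc_s1, x$auc_s2, x$delta_auc))
  invisible(x)
}
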