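#' Fit an equal-variance signal detection model from response counts
#'
#' Evidence-axis convention: S2 evidence ~ Normal(0, 1), S1 evidence ~
#' Normal(d', 1), and the observer responds "S1" when evidence exceeds the
#' decision threshold `k`. A "hit" is an S1 response to an S1 stimulus, a
#' "false alarm" an S1 response to an S2 stimulus. When any count is zero the
#' log-linear correction is applied (0.5 added to every cell, 1 to every
#' denominator) and flagged in `correction_applied`.
#'
#' @param n_hit,n_miss Counts of S1-stimulus trials answered "S1" / "S2".
#' @param n_fa,n_cr Counts of S2-stimulus trials answered "S1" / "S2".
#' @return An object of class `sdt_fit`: `hit_rate`, `fa_rate`, `dprime`
#'   (`z(hit) - z(fa)`), `criterion_c` (`-(z(hit)+z(fa))/2`), `threshold_k`
#'   (`-z(fa)`, the cut on the evidence axis) and `correction_applied`.
#' @export
#' @examples
#' fit_sdt(69, 31, 31, 69)  # d' ~ 0.99, no bias
fit_sdt <- function(n_hit, n_miss, n_fa, n_cr) {
  counts <- c(n_hit, n_miss, n_fa, n_cr)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (n_hit + n_miss == 0 || n_fa + n_cr == 0)
    stop("cannot fit SDT model: a stimulus class has no trials", call. = FALSE)
  correct_rates <- any(counts == 0)
  if (correct_rates) {
    hit <- (n_hit + 0.5) / (n_hit + n_miss + 1)
    fa <- (n_fa + 0.5) / (n_fa + n_cr + 1)
  } else {
    hit <- n_hit / (n_hit + n_miss)
    fa <- n_fa / (n_fa + n_cr)
  }
  zh <- stats::qnorm(hit); zf <- stats::qnorm(fa)
  structure(list(hit_rate = hit, fa_rate = fa, dprime = zh - zf,
                 criterion_c = -(zh + zf) / 2, threshold_k = -zf,
                 correction_applied = correct_rates),
            class = "sdt_fit")
}

# SDT fit from a single-participant trial table.
fit_sdt_table <- function(table) {
  fit_sdt(sum(table$stimulus == "S1" & table$response == "S1"),
          sum(table$stimulus == "S1" & table$response == "S2"),
          sum(table$stimulus == "S2" & table$response == "S1"),
          sum(table$stimulus == "S2" & table$response == "S2"))
}

#' SDT-expected response-conditional type-2 ROC curve
#'
#' Builds the type-2 ROC that an equal-variance SDT observer with the fitted
#' sensitivity and response bias would produce, given the participant's own
#' empirical distribution of confidence in *incorrect* trials. Confidence is
#' assumed to increase with the distance of the evidence from the threshold,
#' so each cumulative proportion `p` of incorrect-trial confidences (at or
#' above a level) maps to an evidence threshold via the truncated incorrect-
#' side distribution, and the matching correct-side cumulative `q` follows
#' from the model:
#' for S1 responses (evidence `> k`),
#' `theta = qnorm(1 - p * (1 - pnorm(k)))` and
#' `q = (1 - pnorm(theta - d')) / (1 - pnorm(k - d'))`;
#' for S2 responses (evidence `<= k`, confidence increasing as evidence
#' decreases), `theta = qnorm(p * pnorm(k - d')) + d'` and
#' `q = pnorm(theta) / pnorm(k)`.
#'
#' This expected curve shares the observed incorrect-confidence distribution
#' and the observed bias and sensitivity, so comparing its area with the
#' empirical one isolates asymmetries that an equal-variance model cannot
#' produce (see [h3_statistic()]).
#'
#' @param fit An [fit_sdt()] object.
#' @param incorrect_confidences Confidence ratings of the incorrect trials
#'   with the given response. A single distinct value yields the degenerate
#'   diagonal curve (area 0.5).
#' @param response `"S1"` or `"S2"`.
#' @return An `rcroc_curve` object (points `(p, q)` plus endpoints).
#' @export
expected_rcroc <- function(fit, incorrect_confidences, response) {
  stopifnot(inherits(fit, "sdt_fit"), response %in% c("S1", "S2"))
  if (length(incorrect_confidences) == 0)
    stop("no incorrect-trial confidences supplied", call. = FALSE)
  d <- fit$dprime; k <- fit$threshold_k
  u <- sort(unique(incorrect_confidences), decreasing = TRUE)
  if (length(u) < 2) {
    pts <- data.frame(fpr = c(0, 1), tpr = c(0, 1))
    return(structure(list(response = response, points = pts, auc = 0.5),
                     class = "rcroc_curve"))
  }
  idx <- match(incorrect_confidences, u)
  p <- cumsum(tabulate(idx, nbins = length(u))) / length(incorrect_confidences)
  if (any(p <= 0 | p > 1))
    stop("cumulative incorrect proportion outside (0, 1]", call. = FALSE)
  if (response == "S1") {
    denom_i <- 1 - stats::pnorm(k)        # P(S2 evidence > k): false alarms
    denom_c <- 1 - stats::pnorm(k - d)    # P(S1 evidence > k): hits
    if (denom_i <= 0 || denom_c <= 0)
      stop("degenerate SDT fit: no probability mass on the S1 side",
           call. = FALSE)
    theta <- stats::qnorm(1 - p * denom_i)
    q <- (1 - stats::pnorm(theta - d)) / denom_c
  } else {
    denom_i <- stats::pnorm(k - d)        # P(S1 evidence <= k): misses
    denom_c <- stats::pnorm(k)            # P(S2 evidence <= k): correct rej.
    if (denom_i <= 0 || denom_c <= 0)
      stop("degenerate SDT fit: no probability mass on the S2 side",
           call. = FALSE)
    theta <- stats::qnorm(p * denom_i) + d
    q <- stats::pnorm(theta) / denom_c
  }
  pts <- data.frame(fpr = c(0, p), tpr = c(0, pmin(pmax(q, 0), 1)))
  structure(list(response = response, points = pts, auc = trapezoid_auc(pts)),
            class = "rcroc_curve")
}

#' Bias-controlled metacognitive asymmetry statistic
#'
#' The observed asymmetry `delta_auc` (from [subject_asymmetry()]) minus the
#' asymmetry expected under an equal-variance SDT model with the same
#' sensitivity, response bias and incorrect-trial confidence distributions
#' (from [expected_rcroc()] with [fit_sdt()] on the same trials). A response
#' bias alone moves both the observed and the expected asymmetry equally, so
#' this statistic is driven only by structure the equal-variance model cannot
#' absorb — notably unequal evidence variances.
#'
#' @param table A clean single-participant trial table meeting the inclusion
#'   rules.
#' @return The difference of the two asymmetries (numeric scalar), with the
#'   observed and expected components as attributes `observed` and `expected`.
#' @export
h3_statistic <- function(table) {
  obs <- subject_asymmetry(table)
  fit <- fit_sdt_table(table)
  exp_auc <- vapply(c("S1", "S2"), function(resp) {
    ic <- table$confidence[table$response == resp & !table$correct]
    expected_rcroc(fit, ic, resp)$auc
  }, numeric(1))
  expected_delta <- exp_auc[["S1"]] - exp_auc[["S2"]]
  out <- obs$delta_auc - expected_delta
  attr(out, "observed") <- obs$delta_auc
  attr(out, "expected") <- expected_delta
  out
}

#' Type-1 zROC points from signed confidence thresholds
#'
#' Builds a signed-confidence axis (S1 responses keep their confidence `+c`,
#' S2 responses map to `-c`) and sweeps every distinct signed value as a
#' threshold: hit rate `P(signed >= theta | S1 stimulus)` against false-alarm
#' rate `P(signed >= theta | S2 stimulus)`. Degenerate rates (0 or 1) are
#' dropped; the survivors are probit-transformed.
#'
#' @param table A single-participant trial table.
#' @return A data frame with columns `z_fa`, `z_hit` (at least 3 rows, else
#'   an error).
#' @export
zroc_points <- function(table) {
  validate_trial_table(table)
  signed <- ifelse(table$response == "S1", table$confidence,
                   -table$confidence)
  is_s1 <- table$stimulus == "S1"
  n1 <- sum(is_s1); n2 <- sum(!is_s1)
  if (n1 == 0 || n2 == 0)
    stop("need trials from both stimulus classes", call. = FALSE)
  u <- sort(unique(signed), decreasing = TRUE)
  idx <- match(signed, u)
  hit <- cumsum(tabulate(idx[is_s1], nbins = length(u))) / n1
  fa <- cumsum(tabulate(idx[!is_s1], nbins = length(u))) / n2
  keep <- hit > 0 & hit < 1 & fa > 0 & fa < 1
  if (sum(keep) < 3)
    stop("insufficient data: fewer than 3 usable zROC points", call. = FALSE)
  data.frame(z_fa = stats::qnorm(fa[keep]), z_hit = stats::qnorm(hit[keep]))
}

#' Slope of the zROC line
#'
#' Ordinary least squares of `z_hit` on `z_fa`. Under an equal-variance SDT
#' model the slope is exactly 1; a slope below 1 indicates a wider S1
#' (signal) evidence distribution, with slope ~ `sd(S2) / sd(S1)`. Group
#' inference is conventionally run on the natural log of the slope.
#'
#' @param points A data frame from [zroc_points()] (>= 3 rows).
#' @return An object of class `zroc_fit`: `slope`, `intercept`, `n_points`,
#'   `log_slope`.
#' @export
zroc_slope <- function(points) {
  stopifnot(is.data.frame(points), all(c("z_fa", "z_hit") %in% names(points)))
  if (nrow(points) < 3)
    stop("need at least 3 zROC points", call. = FALSE)
  if (stats::var(points$z_fa) == 0)
    stop("zero variance in z-transformed false-alarm rates", call. = FALSE)
  fit <- stats::lm(z_hit ~ z_fa, data = points)
  slope <- unname(stats::coef(fit)[2])
  structure(list(slope = slope, intercept = unname(stats::coef(fit)[1]),
                 n_points = nrow(points),
                 log_slope = if (slope > 0) log(slope) else NA_real_),
            class = "zroc_fit")
}

#' Export zROC points as delimited text
#'
#' @param points A data frame from [zroc_points()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_zroc <- function(points, path) {
  utils::write.csv(points, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.sdt_fit <- function(x, ...) {
  cat("Equal-variance SDT fit\n")
  cat(sprintf("  hit rate %.3f, FA rate %.3f%s\n", x$hit_rate, x$fa_rate,
              if (x$correction_applied) " (log-linear correction)" else ""))
  cat(sprintf("  d' = %.3f, c = %.3f, threshold k = %.3f\n",
              x$dprime, x$criterion_c, x$threshold_k))
  invisible(x)
}

#' @export
print.zroc_fit <- function(x, ...) {
  cat(sprintf("zROC fit: slope %.3f (log slope %.3f), intercept %.3f, %d points\n",
              x$slope, x$log_slope, x$intercept, x$n_points))
  invisible(x)
}
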