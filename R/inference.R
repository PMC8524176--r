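#' One-sample t-test with a directional alternative
#'
#' `t = mean / (sd / sqrt(n))` against zero, with the one-tailed p-value taken
#' from the requested tail and the standardized effect size
#' `Cohen's d = mean / sd`.
#'
#' @param values Numeric vector of per-participant summaries (n >= 2, nonzero
#'   variance).
#' @param direction `"greater"` (upper tail) or `"less"` (lower tail).
#' @return An object of class `t_test_result`: `t`, `df`, `p_one_tailed`,
#'   `cohens_d`, `direction`, `n`, `mean`.
#' @export
#' @examples
#' one_sample_t(c(0.1, 0.2, 0.3), "greater")
one_sample_t <- function(values, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop("need at least 2 values", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0) stop("zero variance in the summaries", call. = FALSE)
  m <- mean(values)
  t <- m / (s / sqrt(n))
  p <- stats::pt(t, df = n - 1, lower.tail = (direction == "less"))
  structure(list(t = t, df = n - 1, p_one_tailed = p, cohens_d = m / s,
                 direction = direction, n = n, mean = m),
            class = "t_test_result")
}

# Core JZS Bayes factor: t statistic with `df` degrees of freedom and
# effective sample size `neff` (the ncp is delta * sqrt(neff)). The Cauchy
# prior on the standardized effect is integrated after substituting
# delta = rscale * u, which keeps the quadrature well-conditioned for any
# prior scale (as rscale -> 0 the integrand collapses onto the null and the
# BF -> 1 continuously).
jzs_bf10_core <- function(t, df, neff, rscale, rel.tol = 1e-7) {
  if (!is.finite(t)) stop("`t` must be finite", call. = FALSE)
  den <- stats::dt(t, df)
  # beyond the reach of double-precision t densities the evidence is
  # overwhelming; report an infinite Bayes factor rather than 0/0
  if (den < 1e-280) return(list(bf10 = Inf, err = 0))
  # substituting delta = rscale * u gives the prior bulk unit width at u = 0
  # for every prior scale; the likelihood peaks at u0 with width t/u0
  integrand <- function(u) {
    suppressWarnings(stats::dt(t, df, ncp = u * rscale * sqrt(neff))) *
      stats::dcauchy(u)
  }
  # anchor the quadrature pieces at both features (and at geometric
  # waypoints when the peak is remote) so neither can be stepped over
  u0 <- t / (rscale * sqrt(neff))
  anchors <- if (abs(u0) > 20) u0 * 10^seq(-3, 0) else u0
  bounds <- c(-Inf, sort(unique(c(0, anchors))), Inf)
  val <- err <- 0
  for (i in seq_len(length(bounds) - 1)) {
    piece <- stats::integrate(integrand, bounds[i], bounds[i + 1],
                              rel.tol = rel.tol, subdivisions = 400L)
    val <- val + piece$value
    err <- err + piece$abs.error
  }
  list(bf10 = val / den, err = err / den)
}

#' JZS (Cauchy-prior) Bayes factor from a t statistic
#'
#' Default Bayes factor for the t-test with a Jeffreys–Zellner–Siow prior:
#' a Cauchy distribution with scale `rscale` on the standardized effect size,
#' symmetric around zero (so the sign of `t` is irrelevant), and the Jeffreys
#' prior on the variance. Computed by adaptive quadrature of
#' `BF10 = [integral of f_nct(t; df, delta * sqrt(neff)) dCauchy(delta; 0,
#' rscale)] / f_t(t; df)`, where `f_nct` is the noncentral-t density.
#'
#' @param t Observed t statistic.
#' @param n Sample size (one-sample), or group-1 size when `n2` is given.
#' @param n2 Optional second group size for an independent-samples design
#'   (then `df = n + n2 - 2` and `neff = n * n2 / (n + n2)`).
#' @param rscale Cauchy prior scale on the standardized effect (default 0.65).
#' @return An object of class `bf_result`: `bf10`, `bf01 = 1/bf10`, `rscale`,
#'   `integration_error` (quadrature error estimate, relative to the null
#'   density), plus `t`, `n`, `n2` echoed.
#' @export
#' @examples
#' jzs_bf_from_t(2.96, 134)$bf10  # ~ 6.5
jzs_bf_from_t <- function(t, n, n2 = NULL, rscale = 0.65) {
  if (n < 2) stop("`n` must be >= 2", call. = FALSE)
  if (rscale <= 0) stop("`rscale` must be > 0", call. = FALSE)
  if (is.null(n2)) {
    df <- n - 1; neff <- n
  } else {
    if (n2 < 2) stop("`n2` must be >= 2", call. = FALSE)
    df <- n + n2 - 2; neff <- n * n2 / (n + n2)
  }
  core <- jzs_bf10_core(t, df, neff, rscale)
  structure(list(bf10 = core$bf10, bf01 = 1 / core$bf10, rscale = rscale,
                 integration_error = core$err, t = t, n = n, n2 = n2),
            class = "bf_result")
}

#' Power of the one-tailed one-sample t-test
#'
#' `1 - F_nct(t_crit; df = n - 1, ncp = d * sqrt(n))`, where `t_crit` is the
#' upper-`alpha` quantile of the central t distribution. At `d = 0` the power
#' equals `alpha` exactly.
#'
#' @param n Sample size (>= 2).
#' @param d True standardized effect size.
#' @param alpha Significance level (default 0.05).
#' @return Power in `[0, 1]`.
#' @export
#' @examples
#' power_one_tailed(106, 0.32)  # ~ 0.95
power_one_tailed <- function(n, d, alpha = 0.05) {
  stopifnot(n >= 2, alpha > 0, alpha < 1)
  tcrit <- stats::qt(1 - alpha, df = n - 1)
  if (d == 0) return(alpha)
  suppressWarnings(
    stats::pt(tcrit, df = n - 1, ncp = d * sqrt(n), lower.tail = FALSE))
}

#' Smallest observed effect size significant in the one-tailed t-test
#'
#' The observed Cohen's d at which the one-tailed test sits exactly at the
#' significance threshold: `t_crit / sqrt(n)`.
#'
#' @param n Sample size (>= 2).
#' @param alpha Significance level (default 0.05).
#' @return The minimal significant observed d.
#' @export
#' @examples
#' min_detectable_d(106)  # ~ 0.16
min_detectable_d <- function(n, alpha = 0.05) {
  stopifnot(n >= 2, alpha > 0, alpha < 1)
  stats::qt(1 - alpha, df = n - 1) / sqrt(n)
}

#' Smallest observed effect size with a decisive Bayes factor
#'
#' Root of `BF10(t = d * sqrt(n)) = bf_threshold` in the observed d, found by
#' bracketed root search on `d` in `[min_detectable_d(n)/4, 1]` (the Bayes
#' threshold exceeds the significance threshold in this regime).
#'
#' @param n Sample size (>= 2).
#' @param rscale Cauchy prior scale (default 0.65).
#' @param bf_threshold Bayes-factor criterion (default 3).
#' @return The minimal observed d with `BF10 >= bf_threshold`.
#' @export
#' @examples
#' min_bf_decisive_d(106)  # ~ 0.26
min_bf_decisive_d <- function(n, rscale = 0.65, bf_threshold = 3) {
  stopifnot(n >= 2)
  f <- function(d) jzs_bf10_core(d * sqrt(n), n - 1, n, rscale)$bf10 -
    bf_threshold
  lo <- min_detectable_d(n) / 4; hi <- 1
  if (f(lo) > 0 || f(hi) < 0)
    stop("Bayes-factor threshold not bracketed on d in [",
         signif(lo, 3), ", 1]", call. = FALSE)
  stats::uniroot(f, c(lo, hi), tol = 1e-6)$root
}

#' Bayes-factor design simulation
#'
#' Simulates repeated experiments and scores how often the JZS Bayes factor
#' supports each hypothesis. Per repetition a true standardized effect is
#' drawn (0 under `"point_zero"`, or from `Cauchy(0, effect_scale)` under
#' `"cauchy"`), unit-variance normal summaries are sampled with that mean, a
#' t statistic is computed, and the two-sided JZS Bayes factor (scale
#' `rscale`) is evaluated.
#'
#' The default `design = "two_sample"` simulates an independent-samples
#' experiment with `n` participants per group (pooled t with `2n - 2` degrees
#' of freedom), the design used by standard Bayes-factor design-analysis
#' code; `"one_sample"` draws a single group of `n` summaries.
#'
#' @param n Participants (per group for the two-sample design); default 106.
#' @param rscale Cauchy prior scale of the analysis (default 0.65).
#' @param effect_model `"point_zero"` or `"cauchy"`.
#' @param effect_scale Scale of the true-effect Cauchy distribution (default
#'   0.65; only used when `effect_model = "cauchy"`).
#' @param n_reps Number of simulated experiments (>= 100; default 10000).
#' @param seed Integer seed.
#' @param design `"two_sample"` (default) or `"one_sample"`.
#' @return An object of class `design_sim_result` with fractions
#'   `prop_null_supported` (BF01 > 1), `prop_bf01_gt3`, `prop_alt_supported`
#'   (BF10 > 1), `prop_bf10_gt3`, and the inputs echoed.
#' @export
design_simulation <- function(n = 106, rscale = 0.65,
                              effect_model = c("point_zero", "cauchy"),
                              effect_scale = 0.65, n_reps = 10000,
                              seed = NULL,
                              design = c("two_sample", "one_sample")) {
  effect_model <- match.arg(effect_model)
  design <- match.arg(design)
  if (n_reps < 100) stop("`n_reps` must be >= 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  bf <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    delta <- if (effect_model == "cauchy")
      stats::rcauchy(1, 0, effect_scale) else 0
    if (design == "one_sample") {
      x <- stats::rnorm(n) + delta
      t <- mean(x) / (stats::sd(x) / sqrt(n))
      bf[r] <- jzs_bf10_core(t, n - 1, n, rscale, rel.tol = 1e-6)$bf10
    } else {
      x <- stats::rnorm(n) + delta
      y <- stats::rnorm(n)
      sp <- sqrt((stats::var(x) + stats::var(y)) / 2)
      t <- (mean(x) - mean(y)) / (sp * sqrt(2 / n))
      bf[r] <- jzs_bf10_core(t, 2 * n - 2, n / 2, rscale,
                             rel.tol = 1e-6)$bf10
    }
  }
  structure(list(
    n_reps = n_reps,
    prop_null_supported = mean(bf < 1),
    prop_bf01_gt3 = mean(bf < 1 / 3),
    prop_alt_supported = mean(bf > 1),
    prop_bf10_gt3 = mean(bf > 3),
    effect_model = if (effect_model == "cauchy")
      sprintf("cauchy(%.3g)", effect_scale) else "point_zero",
    n = n, rscale = rscale, design = design, seed = seed),
    class = "design_sim_result")
}

#' Robustness region of a Bayes-factor conclusion over prior scales
#'
#' Evaluates the JZS Bayes factor on a grid of prior scales and labels each
#' grid point `"alternative"` (BF10 > 3), `"null"` (BF01 > 3) or
#' `"inconclusive"`, with the contiguous regions summarised as intervals.
#'
#' @param t Observed t statistic.
#' @param n Sample size.
#' @param rscale_grid Ordered positive prior scales (default 50 log-spaced
#'   points between 0.01 and 2).
#' @return An object of class `robustness_region`: `rscale_grid`,
#'   `bf10_values`, per-point `labels`, and `regions` (data frame with
#'   `from`, `to`, `label`).
#' @export
robustness_region <- function(t, n,
                              rscale_grid = exp(seq(log(0.01), log(2),
                                                    length.out = 50))) {
  if (any(rscale_grid <= 0) || is.unsorted(rscale_grid))
    stop("`rscale_grid` must be positive and increasing", call. = FALSE)
  bf <- vapply(rscale_grid, function(r)
    jzs_bf10_core(t, n - 1, n, r)$bf10, numeric(1))
  labels <- ifelse(bf > 3, "alternative",
                   ifelse(bf < 1 / 3, "null", "inconclusive"))
  runs <- rle(labels)
  ends <- cumsum(runs$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  regions <- data.frame(from = rscale_grid[starts], to = rscale_grid[ends],
                        label = runs$values, stringsAsFactors = FALSE)
  structure(list(t = t, n = n, rscale_grid = rscale_grid, bf10_values = bf,
                 labels = labels, regions = regions),
            class = "robustness_region")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("One-sample t-test (one-tailed, %s): t(%d) = %.3f, p = %.4g, d = %.3f\n",
              x$direction, x$df, x$t, x$p_one_tailed, x$cohens_d))
  invisible(x)
}

#' @export
print.bf_result <- function(x, ...) {
  cat(sprintf("JZS Bayes factor (rscale %.3g): BF10 = %.4g, BF01 = %.4g\n",
              x$rscale, x$bf10, x$bf01))
  invisible(x)
}

#' @export
print.design_sim_result <- function(x, ...) {
  cat(sprintf("Bayes-factor design simulation (%s, n = %d per %s, rscale %.3g, %d reps)\n",
              x$effect_model, x$n,
              if (x$design == "two_sample") "group" else "sample",
              x$rscale, x$n_reps))
  cat(sprintf("  BF01 > 1: %.1f%%   BF01 > 3: %.1f%%\n",
              100 * x$prop_null_supported, 100 * x$prop_bf01_gt3))
  cat(sprintf("  BF10 > 1: %.1f%%   BF10 > 3: %.1f%%\n",
              100 * x$prop_alt_supported, 100 * x$prop_bf10_gt3))
  invisible(x)
}

#' @export
print.robustness_region <- function(x, ...) {
  cat(sprintf("Robustness region for t = %.3g, n = %d\n", x$t, x$n))
  print(x$regions, row.names = FALSE)
  invisible(x)
}
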