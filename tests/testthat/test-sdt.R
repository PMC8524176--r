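test_that("SDT fit matches the standard-normal quantile oracle", {
  chance <- fit_sdt(50, 50, 50, 50)
  expect_equal(chance$dprime, 0)
  expect_equal(chance$criterion_c, 0)
  expect_equal(chance$threshold_k, 0)
  expect_false(chance$correction_applied)

  f1 <- fit_sdt(69, 31, 31, 69)
  expect_equal(f1$dprime, qnorm(0.69) - qnorm(0.31), tolerance = 1e-12)
  expect_equal(f1$dprime, 0.9917, tolerance = 1e-4)
  expect_equal(f1$criterion_c, 0, tolerance = 1e-12)

  f2 <- fit_sdt(90, 10, 30, 70)
  expect_equal(f2$dprime, 1.8061, tolerance = 1e-4)
  expect_equal(f2$criterion_c, -0.3786, tolerance = 1e-4)
  expect_equal(f2$threshold_k, -qnorm(0.3), tolerance = 1e-12)
})

test_that("zero cells trigger the log-linear correction; empty classes error", {
  f <- fit_sdt(50, 0, 20, 30)
  expect_true(f$correction_applied)
  expect_equal(f$hit_rate, 50.5 / 51)
  expect_error(fit_sdt(0, 0, 10, 10), "stimulus class")
})

test_that("expected rc-ROC is symmetric for an unbiased fit and degenerate for one level", {
  fit <- fit_sdt(70, 30, 30, 70)  # c = 0, k = d'/2
  ic <- c(0.9, 0.7, 0.5, 0.3)
  e1 <- expected_rcroc(fit, ic, "S1")
  e2 <- expected_rcroc(fit, ic, "S2")
  expect_equal(e1$auc, e2$auc, tolerance = 1e-12)
  expect_equal(e1$points$tpr, e2$points$tpr, tolerance = 1e-12)
  single <- expected_rcroc(fit, rep(0.5, 5), "S1")
  expect_equal(single$points$fpr, c(0, 1))
  expect_equal(single$auc, 0.5)
})

test_that("expected correct-cumulatives match a large-sample Monte-Carlo of the model", {
  d <- 1; k <- 0.2
  fit <- fit_sdt(round(1e4 * (1 - pnorm(k - d))), round(1e4 * pnorm(k - d)),
                 round(1e4 * (1 - pnorm(k))), round(1e4 * pnorm(k)))
  expect_equal(fit$dprime, d, tolerance = 1e-3)
  expect_equal(fit$threshold_k, k, tolerance = 1e-3)
  # incorrect-confidence values whose at-or-above cumulatives are .25/.5/.75/1
  ic <- c(0.9, 0.7, 0.5, 0.3)
  for (resp in c("S1", "S2")) {
    ec <- expected_rcroc(fit, ic, resp)
    # Monte-Carlo oracle: equal-variance observer, confidence = |x - k|
    set.seed(1234)
    n <- 1e6
    x1 <- rnorm(n, d); x2 <- rnorm(n)
    if (resp == "S1") {
      inc <- x2[x2 > k]; corr <- x1[x1 > k]
      conf_inc <- inc - k; conf_corr <- corr - k
    } else {
      inc <- x1[x1 <= k]; corr <- x2[x2 <= k]
      conf_inc <- k - inc; conf_corr <- k - corr
    }
    for (j in 1:3) {
      p <- j / 4
      theta_conf <- quantile(conf_inc, 1 - p, names = FALSE)
      q_mc <- mean(conf_corr >= theta_conf)
      expect_equal(ec$points$tpr[1 + j], q_mc, tolerance = 0.005)
    }
    # whole-curve area against the empirical curve of the same model
    cv_mc <- rcroc_curve(c(conf_corr[1:5e5], conf_inc[1:2e5]),
                         rep(c(TRUE, FALSE), c(5e5, 2e5)))
    ec_full <- expected_rcroc(fit, conf_inc[1:2e5], resp)
    expect_equal(ec_full$auc, cv_mc$auc, tolerance = 0.005)
  }
})

test_that("bias-controlled statistic vanishes for matched equal-variance data", {
  p0 <- observer_params(metacog_noise_sd = 0, lapse_rate = 0)
  set.seed(41)
  h <- replicate(40, h3_statistic(as_trial_table(
    simulate_trials(p0, 8000, soa_ms = 40))))
  expect_lt(abs(mean(h)) / (sd(h) / sqrt(length(h))), 2.5)
})

test_that("response bias moves raw asymmetry but not the bias-controlled statistic", {
  pb <- observer_params(criterion_shift = 0.3, metacog_noise_sd = 0,
                        lapse_rate = 0)
  set.seed(42)
  res <- replicate(40, {
    tab <- as_trial_table(simulate_trials(pb, 2000, soa_ms = 40))
    c(subject_asymmetry(tab)$delta_auc, h3_statistic(tab))
  })
  z_raw <- mean(res[1, ]) / (sd(res[1, ]) / sqrt(ncol(res)))
  z_h3 <- mean(res[2, ]) / (sd(res[2, ]) / sqrt(ncol(res)))
  expect_gt(abs(z_raw), 3)   # bias alone creates raw asymmetry
  expect_lt(abs(z_h3), 2.5)  # the SDT-matched null absorbs it
})

test_that("unequal variance drives the bias-controlled statistic positive", {
  pu <- observer_params(sigma_s1 = 1.25, metacog_noise_sd = 0, lapse_rate = 0)
  set.seed(43)
  h <- replicate(30, h3_statistic(as_trial_table(
    simulate_trials(pu, 2000, soa_ms = 40))))
  expect_gt(mean(h) / (sd(h) / sqrt(length(h))), 3)
})

test_that("the bias-controlled statistic is invariant to monotone confidence transforms", {
  tab <- clean_subject(observer_params(sigma_s1 = 1.2, metacog_noise_sd = 0),
                       seed = 44)
  base <- h3_statistic(tab)
  warped <- tab; warped$confidence <- tab$confidence^2
  expect_equal(as.numeric(h3_statistic(warped)), as.numeric(base),
               tolerance = 1e-10)
})

test_that("zROC points drop degenerate rates and recover the variance ratio", {
  # equal variance: slope ~ 1
  p1 <- observer_params(sigma_s1 = 1, metacog_noise_sd = 0, lapse_rate = 0)
  t1 <- as_trial_table(simulate_trials(p1, 1e5, soa_ms = 40, seed = 45))
  s1 <- zroc_slope(zroc_points(t1))
  expect_equal(s1$slope, 1, tolerance = 0.03)
  # sigma ratio 1.25: slope ~ 1/1.25
  p2 <- observer_params(sigma_s1 = 1.25, metacog_noise_sd = 0, lapse_rate = 0)
  t2 <- as_trial_table(simulate_trials(p2, 1e5, soa_ms = 40, seed = 13))
  s2 <- zroc_slope(zroc_points(t2))
  expect_equal(s2$slope, 0.8, tolerance = 0.03)
  expect_equal(s2$log_slope, log(s2$slope), tolerance = 1e-12)
  # every z-point is finite (0/1 rates dropped by construction)
  pts <- zroc_points(t2)
  expect_true(all(is.finite(pts$z_fa)) && all(is.finite(pts$z_hit)))
})

test_that("zROC slope fitting matches exact lines and validates input", {
  exact <- data.frame(z_fa = c(-1, 0, 1), z_hit = c(-1, 0, 1))
  f <- zroc_slope(exact)
  expect_equal(f$slope, 1, tolerance = 1e-12)
  expect_equal(f$log_slope, 0, tolerance = 1e-12)
  shallow <- data.frame(z_fa = c(-1, 0, 1), z_hit = c(-0.8, 0, 0.8))
  expect_equal(zroc_slope(shallow)$slope, 0.8, tolerance = 1e-12)
  expect_error(zroc_slope(exact[1:2, ]), "3")
  expect_error(zroc_slope(data.frame(z_fa = c(0, 0, 0),
                                     z_hit = c(-1, 0, 1))), "variance")
})

test_that("equal-variance cohorts have log-slope centred on zero", {
  p <- observer_params(metacog_noise_sd = 0, lapse_rate = 0)
  set.seed(46)
  ls <- replicate(200, zroc_slope(zroc_points(as_trial_table(
    simulate_trials(p, 2000, soa_ms = 40))))$log_slope)
  expect_lt(abs(mean(ls)) / (sd(ls) / sqrt(length(ls))), 2)
})
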