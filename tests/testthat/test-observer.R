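test_that("psychometric link is zero at SOA 0, saturating, and increasing", {
  p <- observer_params(d_max = 2.5, tau_ms = 40)
  expect_equal(dprime_from_soa(p, 0), 0)
  expect_equal(dprime_from_soa(p, 1e6), 2.5, tolerance = 1e-9)
  expect_equal(dprime_from_soa(p, 40), 2.5 * (1 - exp(-1)), tolerance = 1e-12)
  soas <- seq(0, 300, by = 5)
  expect_true(all(diff(dprime_from_soa(p, soas)) > 0))
  expect_error(dprime_from_soa(p, -1), "soa_ms")
})

test_that("staircase follows the 1-up-2-down rule with multiplicative steps", {
  st <- staircase_state(soa_ms = 30, step_factor = 0.9)
  up <- staircase_update(st, correct = FALSE)
  expect_equal(up$soa_ms, 30 / 0.9)
  expect_equal(up$correct_streak, 0L)
  st$correct_streak <- 1L
  down <- staircase_update(st, correct = TRUE)
  expect_equal(down$soa_ms, 27)
  expect_equal(down$correct_streak, 0L)
  hold <- staircase_update(staircase_state(30), correct = TRUE)
  expect_equal(hold$soa_ms, 30)
  expect_equal(hold$correct_streak, 1L)
  # clamping
  low <- staircase_state(soa_ms = 1.05, correct_streak = 1)
  expect_equal(staircase_update(low, TRUE)$soa_ms, 1)
})

test_that("staircase long-run accuracy sits at the Levitt fixed point sqrt(0.5)", {
  p <- observer_params(lapse_rate = 0, comprehension_fail_prob = 0)
  des <- experiment_design(n_subjects = 1, n_trials = 1e5, n_blocks = 5)
  tab <- simulate_subject(p, des, seed = 14)
  expect_equal(mean(tab$correct), sqrt(0.5), tolerance = 0.02 / sqrt(0.5))
})

test_that("simulated sessions have the right structure and are deterministic", {
  p <- observer_params()
  tab <- simulate_subject(p, experiment_design(n_subjects = 1), seed = 42)
  expect_equal(nrow(tab), 96)
  expect_equal(as.vector(table(tab$block)), rep(16L, 6))
  expect_equal(tab$soa_ms[1], 30)
  expect_equal(sum(tab$stimulus == "S1"), 48)
  expect_true(all(tab$confidence >= 0 & tab$confidence <= 1))
  expect_true(all(tab$rt_ms > 0))
  expect_identical(tab, simulate_subject(p, experiment_design(n_subjects = 1),
                                         seed = 42))
})

test_that("equal-variance unbiased observer responds symmetrically", {
  p <- observer_params(sigma_s1 = 1, criterion_shift = 0,
                       metacog_noise_sd = 0, lapse_rate = 0)
  tr <- simulate_trials(p, 4e4, soa_ms = 40, seed = 8)
  p_s1_given_s1 <- mean(tr$response[tr$stimulus == "S1"] == "S1")
  p_s2_given_s2 <- mean(tr$response[tr$stimulus == "S2"] == "S2")
  expect_equal(p_s1_given_s1, p_s2_given_s2, tolerance = 0.02)
})

test_that("confidence is negatively coupled to log response time", {
  p <- observer_params(rt_conf_slope = 0.5, rt_noise_sd = 0.3, lapse_rate = 0)
  tr <- simulate_trials(p, 1e5, soa_ms = 40, seed = 15)
  r <- cor(tr$confidence, log(tr$rt_ms))
  expect_lt(r, -0.3)
})

test_that("a fully lapsing observer performs at chance", {
  p <- observer_params(lapse_rate = 1)
  tr <- simulate_trials(p, 2e4, soa_ms = 40, seed = 9)
  expect_equal(mean(tr$correct), 0.5, tolerance = 0.02)
})

test_that("cohort simulation is reproducible and subject-stable", {
  spec <- cohort_spec()
  d3 <- experiment_design(n_subjects = 3)
  d5 <- experiment_design(n_subjects = 5)
  t3 <- simulate_cohort(spec, d3, seed = 7)
  t5 <- simulate_cohort(spec, d5, seed = 7)
  expect_identical(t3, t5[t5$subject_id %in% unique(t3$subject_id), ])
  expect_identical(t3, simulate_cohort(spec, d3, seed = 7))
  empty <- simulate_cohort(spec, experiment_design(n_subjects = 0), seed = 7)
  expect_equal(nrow(empty), 0)
  expect_named(empty, names(t3))
})

test_that("homogeneous symmetric cohort shows no confidence asymmetry", {
  spec <- cohort_spec(observer_params(metacog_noise_sd = 0,
                                      comprehension_fail_prob = 0),
                      sdlog = 0.05, shift_sd = 0.01)
  tab <- simulate_cohort(spec, experiment_design(n_subjects = 40), seed = 31)
  clean <- apply_exclusions(tab)$clean
  dc <- vapply(split(clean, clean$subject_id), function(s)
    mean(s$confidence[s$response == "S1"]) -
      mean(s$confidence[s$response == "S2"]), numeric(1))
  expect_lt(abs(mean(dc)) / (sd(dc) / sqrt(length(dc))), 2)
})

test_that("staircase keeps late-block accuracy in the target band across sensitivities", {
  for (dm in c(1.5, 2.5, 3.5)) {
    spec <- cohort_spec(observer_params(d_max = dm), sdlog = 0.1)
    tab <- simulate_cohort(spec, experiment_design(n_subjects = 15),
                           seed = 100 + dm * 10)
    acc <- mean(filter_blocks(tab)$correct)
    expect_gte(acc, 0.65)
    expect_lte(acc, 0.80)
  }
})

test_that("parameter constructors validate their domains", {
  expect_error(observer_params(d_max = -1), "d_max")
  expect_error(observer_params(tau_ms = 0), "tau_ms")
  expect_error(observer_params(sigma_s1 = 0), "sigma_s1")
  expect_error(observer_params(lapse_rate = 1.5), "lapse_rate")
  expect_error(experiment_design(n_trials = 95), "divisible")
  expect_error(staircase_state(step_factor = 1), "step_factor")
  expect_error(cohort_spec(sdlog = 0), "dispersion")
})
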