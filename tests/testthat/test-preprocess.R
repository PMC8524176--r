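make_session <- function(seed = 5, params = observer_params()) {
  simulate_subject(params, experiment_design(n_subjects = 1), seed = seed)
}

test_that("block filter drops the practice block and is idempotent", {
  tab <- make_session()
  f <- filter_blocks(tab)
  expect_equal(nrow(f), 80)
  expect_false(any(f$block == 1))
  expect_identical(filter_blocks(f), f)
  only1 <- tab[tab$block == 1, ]
  expect_equal(nrow(filter_blocks(only1)), 0)
  expect_error(filter_blocks(tab[, setdiff(names(tab), "block")]), "block")
})

test_that("RT filter is strict outside [250, 5000] and keeps boundaries", {
  tab <- make_session()
  tab$rt_ms[1:4] <- c(6000, 249.99, 250, 5000)
  f <- filter_trials(tab)
  expect_false(1 %in% f$trial_idx)
  expect_false(2 %in% f$trial_idx)
  expect_true(all(c(3, 4) %in% f$trial_idx))
  ok <- make_session(seed = 6)
  expect_identical(filter_trials(ok), ok)
})

test_that("block and RT filters commute", {
  tab <- make_session(seed = 7)
  tab$rt_ms[seq(1, 96, by = 9)] <- 7000
  expect_identical(filter_trials(filter_blocks(tab)),
                   filter_blocks(filter_trials(tab)))
})

test_that("each exclusion rule fires on the pathology that triggers it", {
  # low accuracy: a fully lapsing observer guesses at ~50% (480 trials keep
  # the binomial noise well below the 60% cutoff)
  lapser <- simulate_subject(observer_params(lapse_rate = 1),
                             experiment_design(n_subjects = 1, n_trials = 480,
                                               n_blocks = 6), seed = 11)
  expect_true("low_accuracy" %in% assess_subject(lapser)$reasons)

  # extreme RT fraction on all trials: 26 of 96 is > 25%
  tab <- make_session(seed = 12)
  tab$rt_ms[] <- 800  # fix the baseline so the counts below are exact
  slow <- tab; slow$rt_ms[1:26] <- 6000
  expect_true("extreme_rt_fraction" %in% assess_subject(slow)$reasons)
  borderline <- tab; borderline$rt_ms[1:24] <- 6000  # exactly 25%: retained
  expect_false("extreme_rt_fraction" %in% assess_subject(borderline)$reasons)

  # comprehension
  fail <- tab; fail$comprehension_passed <- FALSE
  expect_true("failed_comprehension" %in% assess_subject(fail)$reasons)

  # too few errors of one type
  perfect <- tab; perfect$response <- perfect$stimulus
  perfect$correct <- TRUE
  expect_true("too_few_errors_per_type" %in% assess_subject(perfect)$reasons)

  # constant confidence within one response category
  flat <- tab; flat$confidence[flat$response == "S2"] <- 0.5
  expect_true("too_few_confidence_levels" %in% assess_subject(flat)$reasons)

  # a healthy session passes
  expect_true(assess_subject(tab)$included)
})

test_that("empty and missing-confidence tables are handled", {
  empty <- make_session()[0, ]
  rep <- assess_subject(empty)
  expect_false(rep$included)
  expect_equal(rep$n_trials_before, 0L)
  expect_equal(rep$n_trials_after, 0L)
  withna <- make_session(seed = 13)
  withna$confidence[5] <- NA
  expect_warning(assess_subject(withna), "missing confidence")
})

test_that("apply_exclusions keeps included subjects only and reconciles counts", {
  spec <- cohort_spec()
  tab <- simulate_cohort(spec, experiment_design(n_subjects = 3), seed = 17)
  # make the second subject a low-accuracy case
  ids <- unique(tab$subject_id)
  bad <- tab$subject_id == ids[2]
  tab$response[bad] <- ifelse(runif(sum(bad)) < 0.5, "S1", "S2")
  tab$correct[bad] <- tab$response[bad] == tab$stimulus[bad]
  res <- apply_exclusions(tab)
  expect_equal(nrow(res$reports), 3)
  expect_equal(sum(res$reports$included) + sum(!res$reports$included), 3)
  expect_false(ids[2] %in% res$clean$subject_id)
  expect_equal(unique(res$clean$subject_id),
               res$reports$subject_id[res$reports$included])
  # conservation: clean rows = sum of per-subject filtered rows
  expect_equal(nrow(res$clean),
               sum(res$reports$n_trials_after[res$reports$included]))
  # idempotence on its own output
  again <- apply_exclusions(res$clean)
  expect_identical(again$clean, res$clean)
})

test_that("a fully lapsing cohort is excluded wholesale for low accuracy", {
  spec <- cohort_spec(observer_params(lapse_rate = 1))
  tab <- simulate_cohort(spec, experiment_design(n_subjects = 8), seed = 19)
  res <- apply_exclusions(tab)
  expect_true(all(!res$reports$included))
  expect_true(all(grepl("low_accuracy", res$reports$reasons)))
})

test_that("subject descriptives compute the stated fields", {
  tab <- toy_table(stimulus = c("S1", "S1", "S2", "S2"),
                   response = c("S1", "S1", "S1", "S2"),
                   confidence = c(0.2, 0.2, 0.1, 0.3))
  d <- describe_subject(tab)
  expect_equal(d$accuracy, 0.75)
  expect_equal(d$p_s1_response, 0.75)
  expect_equal(d$response_bias, 0.25)
  expect_equal(d$mean_confidence, 0.2)
  # mean conf correct (0.2,0.2,0.3)=0.2333 minus incorrect (0.1)
  expect_equal(d$conf_correct_minus_incorrect, 0.7 / 3 - 0.1)
  all_correct <- toy_table(stimulus = c("S1", "S2"), response = c("S1", "S2"),
                           confidence = c(0.4, 0.6))
  expect_true(is.na(describe_subject(all_correct)$conf_correct_minus_incorrect))
  balanced <- toy_table(stimulus = c("S1", "S2"), response = c("S1", "S2"),
                        confidence = c(0.4, 0.6))
  expect_equal(describe_subject(balanced)$response_bias, 0)
})
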