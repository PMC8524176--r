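# Shared fixtures and independent oracles for the test suite.

# Rank-concordance oracle for the type-2 ROC area:
# P(conf_correct > conf_incorrect) + P(tie)/2 over all pairs.
concordance_auc <- function(conf_correct, conf_incorrect) {
  cmp <- outer(conf_correct, conf_incorrect, function(a, b)
    (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Wrap the output of simulate_trials() into a canonical trial table.
as_trial_table <- function(trials, subject_id = "t01", block = 2L,
                           comprehension = TRUE) {
  data.frame(subject_id = subject_id, block = block,
             trial_idx = seq_len(nrow(trials)),
             trials[, c("stimulus", "response", "correct", "confidence",
                        "rt_ms", "soa_ms")],
             comprehension_passed = comprehension, stringsAsFactors = FALSE)
}

# Hand-built table for exclusion / descriptive tests: `spec` rows of
# (stimulus, response, confidence, rt_ms).
toy_table <- function(stimulus, response, confidence, rt_ms = 800,
                      block = 2L, subject_id = "toy", comprehension = TRUE) {
  n <- length(stimulus)
  data.frame(subject_id = subject_id, block = rep_len(block, n),
             trial_idx = seq_len(n), stimulus = stimulus, response = response,
             correct = stimulus == response, confidence = confidence,
             rt_ms = rep_len(rt_ms, n), soa_ms = 30,
             comprehension_passed = comprehension, stringsAsFactors = FALSE)
}

# One clean simulated subject table (blocks and RT filtered), retrying until
# the inclusion rules hold.
clean_subject <- function(params, design = experiment_design(n_subjects = 1),
                          seed = 1) {
  set.seed(seed)
  repeat {
    tab <- simulate_subject(params, design, seed = sample.int(1e8, 1))
    cl <- filter_trials(filter_blocks(tab))
    ok <- tryCatch({subject_asymmetry(cl); TRUE}, error = function(e) FALSE)
    if (ok) return(cl)
  }
}
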