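#' Observer parameters for the generative signal-detection model
#'
#' Bundles the parameters of a simulated observer performing a masked
#' two-alternative discrimination task with confidence ratings. On each trial
#' the observer samples an internal evidence value `x` from a stimulus-specific
#' normal distribution: `x ~ N(d'(SOA), sigma_s1)` for S1 stimuli and
#' `x ~ N(0, 1)` for S2 stimuli, where sensitivity `d'` grows with stimulus
#' onset asynchrony (SOA) through a saturating exponential (see
#' [dprime_from_soa()]). The observer responds "S1" when `x` exceeds the
#' decision threshold `k = d'/2 + criterion_shift`, and rates confidence as an
#' increasing, bounded function of the distance `|x - k|`.
#'
#' Setting `sigma_s1 > 1` produces the unequal-variance regime in which the
#' wider (S1) evidence distribution yields higher metacognitive sensitivity
#' for S1 responses — the asymmetry the analysis pipeline measures.
#'
#' @param d_max Maximum sensitivity, in d' units; asymptote of the
#'   psychometric function. Must be >= 0.
#' @param tau_ms Time constant of the psychometric function, in ms (> 0).
#' @param sigma_s1 Standard deviation of the S1 evidence distribution; the S2
#'   distribution is fixed at SD 1. Must be > 0.
#' @param criterion_shift Additive shift of the decision threshold away from
#'   the unbiased midpoint `d'/2`, in evidence units. Positive values bias the
#'   observer toward "S2" responses.
#' @param conf_gain Scaling from `|x - k|` to raw confidence.
#' @param metacog_noise_sd SD of zero-mean Gaussian noise added to raw
#'   confidence before squashing; 0 gives noise-free metacognition.
#' @param rt_base_ms Median response time at confidence 0, in ms (> 0).
#' @param rt_conf_slope Decrease in log RT per unit of confidence; positive
#'   values make high-confidence responses faster.
#' @param rt_noise_sd SD of Gaussian noise on log RT.
#' @param lapse_rate Probability that the response and confidence are replaced
#'   by uniform random draws (attentional lapse). In `[0, 1)` for a task-doing
#'   observer; 1 is allowed and yields pure guessing.
#' @param comprehension_fail_prob Probability that the simulated participant
#'   fails the instructions comprehension check.
#' @param conf_shift_s1 Additive shift applied to the reported confidence of
#'   S1-response trials (clamped to `[0, 1]`). Default 0; used to inject a
#'   known confidence asymmetry for parameter-recovery studies.
#'
#' @return An object of class `observer_params`.
#' @seealso [simulate_subject()], [simulate_cohort()], [cohort_spec()]
#' @export
#' @examples
#' observer_params(sigma_s1 = 1.25)  # unequal-variance observer
observer_params <- function(d_max = 2.5, tau_ms = 40, sigma_s1 = 1,
                            criterion_shift = 0, conf_gain = 1,
                            metacog_noise_sd = 0.1, rt_base_ms = 800,
                            rt_conf_slope = 0.5, rt_noise_sd = 0.3,
                            lapse_rate = 0.02, comprehension_fail_prob = 0.02,
                            conf_shift_s1 = 0) {
  if (d_max < 0) stop("`d_max` must be >= 0", call. = FALSE)
  if (tau_ms <= 0) stop("`tau_ms` must be > 0", call. = FALSE)
  if (sigma_s1 <= 0) stop("`sigma_s1` must be > 0", call. = FALSE)
  if (rt_base_ms <= 0) stop("`rt_base_ms` must be > 0", call. = FALSE)
  if (lapse_rate < 0 || lapse_rate > 1)
    stop("`lapse_rate` must lie in [0, 1]", call. = FALSE)
  if (metacog_noise_sd < 0 || rt_noise_sd < 0)
    stop("noise SDs must be >= 0", call. = FALSE)
  if (comprehension_fail_prob < 0 || comprehension_fail_prob > 1)
    stop("`comprehension_fail_prob` must lie in [0, 1]", call. = FALSE)
  structure(
    list(d_max = d_max, tau_ms = tau_ms, sigma_s1 = sigma_s1,
         criterion_shift = criterion_shift, conf_gain = conf_gain,
         metacog_noise_sd = metacog_noise_sd, rt_base_ms = rt_base_ms,
         rt_conf_slope = rt_conf_slope, rt_noise_sd = rt_noise_sd,
         lapse_rate = lapse_rate,
         comprehension_fail_prob = comprehension_fail_prob,
         conf_shift_s1 = conf_shift_s1),
    class = "observer_params")
}

#' Experiment design: trial counts, blocks and staircase settings
#'
#' @param n_subjects Number of simulated participants.
#' @param n_trials Trials per participant (default 96); must be divisible by
#'   `n_blocks` and even, so stimulus classes can be balanced.
#' @param n_blocks Number of blocks (default 6); the first block is treated as
#'   practice by [filter_blocks()].
#' @param soa_start_ms Initial stimulus onset asynchrony in ms (default 30).
#' @param step_factor Multiplicative staircase step (default 0.9), in (0, 1).
#' @param soa_min_ms,soa_max_ms Clamps on the SOA, in ms.
#'
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(n_subjects = 106, n_trials = 96, n_blocks = 6,
                              soa_start_ms = 30, step_factor = 0.9,
                              soa_min_ms = 1, soa_max_ms = 1000) {
  if (n_subjects < 0) stop("`n_subjects` must be >= 0", call. = FALSE)
  if (n_trials %% n_blocks != 0)
    stop("`n_trials` must be divisible by `n_blocks`", call. = FALSE)
  if (n_trials %% 2 != 0)
    stop("`n_trials` must be even to balance S1/S2 stimuli", call. = FALSE)
  if (step_factor <= 0 || step_factor >= 1)
    stop("`step_factor` must lie in (0, 1)", call. = FALSE)
  if (soa_min_ms > soa_start_ms || soa_start_ms > soa_max_ms)
    stop("`soa_start_ms` must lie within [soa_min_ms, soa_max_ms]", call. = FALSE)
  structure(
    list(n_subjects = as.integer(n_subjects), n_trials = as.integer(n_trials),
         n_blocks = as.integer(n_blocks), soa_start_ms = soa_start_ms,
         step_factor = step_factor, soa_min_ms = soa_min_ms,
         soa_max_ms = soa_max_ms),
    class = "experiment_design")
}

#' Sensitivity as a function of stimulus onset asynchrony
#'
#' Saturating-exponential psychometric link
#' `d'(SOA) = d_max * (1 - exp(-SOA / tau_ms))`: zero at SOA 0, strictly
#' increasing, asymptoting at `d_max`. This link ties the adaptive staircase to
#' accuracy; its exact shape is a modelling convenience, not an empirical claim.
#'
#' @param params An [observer_params()] object.
#' @param soa_ms SOA in ms (vectorised); must be >= 0.
#' @return Sensitivity d' (same length as `soa_ms`).
#' @export
#' @examples
#' dprime_from_soa(observer_params(), 40)  # 2.5 * (1 - exp(-1))
dprime_from_soa <- function(params, soa_ms) {
  stopifnot(inherits(params, "observer_params"))
  if (any(soa_ms < 0)) stop("`soa_ms` must be >= 0", call. = FALSE)
  params$d_max * (1 - exp(-soa_ms / params$tau_ms))
}

#' Staircase state constructor
#'
#' State of the 1-up-2-down adaptive staircase that calibrates the SOA online:
#' after an error the SOA is divided by `step_factor` (the task gets easier),
#' and after two consecutive correct responses it is multiplied by
#' `step_factor` (harder). The procedure converges to the Levitt fixed point
#' `p^2 = 0.5`, i.e. about 70.7% correct.
#'
#' @param soa_ms Current SOA in ms.
#' @param correct_streak Consecutive-correct counter, 0 or 1.
#' @param step_factor Multiplicative step in (0, 1), default 0.9.
#' @param soa_min_ms,soa_max_ms Clamps on the SOA.
#' @return An object of class `staircase_state`.
#' @export
staircase_state <- function(soa_ms = 30, correct_streak = 0, step_factor = 0.9,
                            soa_min_ms = 1, soa_max_ms = 1000) {
  if (step_factor <= 0 || step_factor >= 1)
    stop("`step_factor` must lie in (0, 1)", call. = FALSE)
  if (!correct_streak %in% c(0, 1))
    stop("`correct_streak` must be 0 or 1", call. = FALSE)
  if (soa_ms < soa_min_ms || soa_ms > soa_max_ms)
    stop("`soa_ms` outside [soa_min_ms, soa_max_ms]", call. = FALSE)
  structure(list(soa_ms = soa_ms, correct_streak = as.integer(correct_streak),
                 step_factor = step_factor, soa_min_ms = soa_min_ms,
                 soa_max_ms = soa_max_ms),
            class = "staircase_state")
}

#' Advance the 1-up-2-down staircase by one trial
#'
#' @param state A [staircase_state()] object.
#' @param correct Logical; was the response on this trial correct?
#' @return The updated `staircase_state`.
#' @export
#' @examples
#' st <- staircase_state(soa_ms = 30)
#' staircase_update(st, correct = FALSE)$soa_ms  # 30 / 0.9
staircase_update <- function(state, correct) {
  stopifnot(inherits(state, "staircase_state"), is.logical(correct))
  if (!correct) {
    state$soa_ms <- state$soa_ms / state$step_factor
    state$correct_streak <- 0L
  } else if (state$correct_streak == 1L) {
    state$soa_ms <- state$soa_ms * state$step_factor
    state$correct_streak <- 0L
  } else {
    state$correct_streak <- 1L
  }
  state$soa_ms <- min(max(state$soa_ms, state$soa_min_ms), state$soa_max_ms)
  state
}

# Vectorised core of the trial generator. Draws all trials at the given
# (vectorised) SOA without staircase coupling; callers that need the staircase
# must call trial-by-trial. Uses the current RNG stream.
simulate_trials_core <- function(params, stimuli, soa_ms) {
  n <- length(stimuli)
  soa_ms <- rep_len(soa_ms, n)
  dp <- dprime_from_soa(params, soa_ms)
  is_s1 <- stimuli == "S1"
  k <- dp / 2 + params$criterion_shift
  x <- stats::rnorm(n, mean = ifelse(is_s1, dp, 0),
                    sd = ifelse(is_s1, params$sigma_s1, 1))
  response <- ifelse(x > k, "S1", "S2")
  u <- params$conf_gain * abs(x - k) +
    stats::rnorm(n, 0, params$metacog_noise_sd)
  confidence <- pmax(0, 1 - exp(-pmax(u, 0)))
  log_rt <- log(params$rt_base_ms) - params$rt_conf_slope * confidence +
    stats::rnorm(n, 0, params$rt_noise_sd)
  # lapses replace the response and confidence with uniform draws; the RT was
  # already generated from the pre-lapse confidence
  if (params$lapse_rate > 0) {
    lapse <- stats::runif(n) < params$lapse_rate
    if (any(lapse)) {
      nl <- sum(lapse)
      response[lapse] <- ifelse(stats::runif(nl) < 0.5, "S1", "S2")
      confidence[lapse] <- stats::runif(nl)
    }
  }
  if (params$conf_shift_s1 != 0) {
    s1r <- response == "S1"
    confidence[s1r] <- pmin(1, pmax(0, confidence[s1r] + params$conf_shift_s1))
  }
  data.frame(stimulus = stimuli, response = response,
             correct = response == stimuli, confidence = confidence,
             rt_ms = exp(log_rt), soa_ms = soa_ms,
             stringsAsFactors = FALSE)
}

#' Simulate one trial of the discrimination task
#'
#' Draws the evidence, response, confidence and response time for a single
#' trial at a fixed SOA. Mainly useful for inspection; [simulate_subject()]
#' runs whole sessions with the staircase, and [simulate_trials()] draws many
#' independent trials at once.
#'
#' @param params An [observer_params()] object.
#' @param stimulus `"S1"` or `"S2"`.
#' @param soa_ms SOA for this trial, in ms.
#' @return A one-row data frame with columns `stimulus`, `response`,
#'   `correct`, `confidence`, `rt_ms`, `soa_ms`.
#' @export
simulate_trial <- function(params, stimulus, soa_ms) {
  stopifnot(stimulus %in% c("S1", "S2"))
  simulate_trials_core(params, stimulus, soa_ms)
}

#' Simulate many independent trials at fixed SOA
#'
#' Vectorised fixed-difficulty generator (no staircase): useful for
#' large-sample checks of the evidence model, e.g. zROC slope recovery.
#' Stimuli are a balanced random permutation unless supplied.
#'
#' @param params An [observer_params()] object.
#' @param n_trials Number of trials.
#' @param soa_ms Fixed SOA in ms (scalar or length `n_trials`).
#' @param stimuli Optional character vector of `"S1"`/`"S2"`; defaults to a
#'   random permutation of a half/half split.
#' @param seed Optional integer seed.
#' @return A data frame as in [simulate_trial()], one row per trial.
#' @export
simulate_trials <- function(params, n_trials, soa_ms, stimuli = NULL,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(stimuli)) {
    stimuli <- sample(rep(c("S1", "S2"), length.out = n_trials))
  }
  stopifnot(length(stimuli) == n_trials, all(stimuli %in% c("S1", "S2")))
  simulate_trials_core(params, stimuli, soa_ms)
}

#' Simulate a full session for one participant
#'
#' Runs `n_trials` trials in `n_blocks` blocks with the SOA evolved by the
#' 1-up-2-down staircase from `soa_start_ms`. The stimulus sequence is a
#' random permutation of a balanced half-S1/half-S2 split; the
#' comprehension-check outcome is drawn once per participant.
#'
#' @param params An [observer_params()] object.
#' @param design An [experiment_design()] object.
#' @param subject_id Identifier stored in the `subject_id` column.
#' @param seed Optional integer seed; identical seeds give identical tables.
#' @return A trial table (data frame) with the canonical columns
#'   `subject_id`, `block`, `trial_idx`, `stimulus`, `response`, `correct`,
#'   `confidence`, `rt_ms`, `soa_ms`, `comprehension_passed`.
#' @export
#' @examples
#' tab <- simulate_subject(observer_params(), experiment_design(), seed = 1)
#' table(tab$block)
simulate_subject <- function(params, design = experiment_design(),
                             subject_id = "s001", seed = NULL) {
  stopifnot(inherits(params, "observer_params"),
            inherits(design, "experiment_design"))
  if (!is.null(seed)) set.seed(seed)
  n <- design$n_trials
  comprehension <- stats::runif(1) >= params$comprehension_fail_prob
  stimuli <- sample(rep(c("S1", "S2"), length.out = n))
  st <- staircase_state(soa_ms = design$soa_start_ms,
                        step_factor = design$step_factor,
                        soa_min_ms = design$soa_min_ms,
                        soa_max_ms = design$soa_max_ms)
  response <- character(n); correct <- logical(n)
  confidence <- numeric(n); rt_ms <- numeric(n); soa <- numeric(n)
  # scalar inline of simulate_trials_core: the staircase couples trial i+1's
  # SOA to trial i's outcome, so trials cannot be drawn in one vectorised call
  soa_now <- st$soa_ms; streak <- 0L
  step <- design$step_factor
  for (i in seq_len(n)) {
    soa[i] <- soa_now
    dp <- params$d_max * (1 - exp(-soa_now / params$tau_ms))
    s1 <- stimuli[i] == "S1"
    k <- dp / 2 + params$criterion_shift
    x <- stats::rnorm(1, if (s1) dp else 0, if (s1) params$sigma_s1 else 1)
    resp <- if (x > k) "S1" else "S2"
    u <- params$conf_gain * abs(x - k) +
      stats::rnorm(1, 0, params$metacog_noise_sd)
    conf <- max(0, 1 - exp(-max(u, 0)))
    log_rt <- log(params$rt_base_ms) - params$rt_conf_slope * conf +
      stats::rnorm(1, 0, params$rt_noise_sd)
    if (params$lapse_rate > 0 && stats::runif(1) < params$lapse_rate) {
      resp <- if (stats::runif(1) < 0.5) "S1" else "S2"
      conf <- stats::runif(1)
    }
    if (params$conf_shift_s1 != 0 && resp == "S1")
      conf <- min(1, max(0, conf + params$conf_shift_s1))
    response[i] <- resp
    correct[i] <- resp == stimuli[i]
    confidence[i] <- conf
    rt_ms[i] <- exp(log_rt)
    # 1-up-2-down update, clamped
    if (!correct[i]) {
      soa_now <- soa_now / step; streak <- 0L
    } else if (streak == 1L) {
      soa_now <- soa_now * step; streak <- 0L
    } else streak <- 1L
    soa_now <- min(max(soa_now, design$soa_min_ms), design$soa_max_ms)
  }
  data.frame(
    subject_id = subject_id,
    block = rep(seq_len(design$n_blocks), each = n / design$n_blocks),
    trial_idx = seq_len(n),
    stimulus = stimuli, response = response, correct = correct,
    confidence = confidence, rt_ms = rt_ms, soa_ms = soa,
    comprehension_passed = comprehension,
    stringsAsFactors = FALSE)
}

#' Population-level cohort specification
#'
#' Describes the distribution of observer parameters across participants.
#' Positive-mean parameters (`d_max`, `tau_ms`, `sigma_s1`, `conf_gain`,
#' `metacog_noise_sd`, `rt_base_ms`, `rt_conf_slope`, `rt_noise_sd`) are drawn
#' from mean-preserving log-normal distributions with log-scale SD `sdlog`
#' (positivity plus right skew, as is typical of behavioural parameters);
#' parameters whose population mean is 0 are held at 0. The sign-free additive
#' parameters `criterion_shift` and `conf_shift_s1` are drawn from
#' `Normal(mean, shift_sd)`. The probability parameters (`lapse_rate`,
#' `comprehension_fail_prob`) are shared by all participants.
#'
#' @param mean An [observer_params()] object of population means.
#' @param sdlog Log-scale SD of the log-normal between-subject dispersion;
#'   must be > 0.
#' @param shift_sd SD of the normal dispersion on the additive parameters;
#'   must be >= 0.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(mean = observer_params(), sdlog = 0.2,
                        shift_sd = 0.05) {
  stopifnot(inherits(mean, "observer_params"))
  if (!is.numeric(sdlog) || sdlog <= 0)
    stop("`sdlog` dispersion must be > 0", call. = FALSE)
  if (shift_sd < 0) stop("`shift_sd` must be >= 0", call. = FALSE)
  structure(list(mean = mean, sdlog = sdlog, shift_sd = shift_sd),
            class = "cohort_spec")
}

# Draw one participant's observer parameters from a cohort specification.
draw_observer <- function(spec) {
  m <- spec$mean; s <- spec$sdlog
  ln <- function(mu) {
    if (mu == 0) return(0)
    stats::rlnorm(1, meanlog = log(mu) - s^2 / 2, sdlog = s)
  }
  observer_params(
    d_max = ln(m$d_max), tau_ms = ln(m$tau_ms), sigma_s1 = ln(m$sigma_s1),
    criterion_shift = stats::rnorm(1, m$criterion_shift, spec$shift_sd),
    conf_gain = ln(m$conf_gain), metacog_noise_sd = ln(m$metacog_noise_sd),
    rt_base_ms = ln(m$rt_base_ms), rt_conf_slope = ln(m$rt_conf_slope),
    rt_noise_sd = ln(m$rt_noise_sd), lapse_rate = m$lapse_rate,
    comprehension_fail_prob = m$comprehension_fail_prob,
    conf_shift_s1 = stats::rnorm(1, m$conf_shift_s1, spec$shift_sd))
}

# Deterministic per-subject child seed so subject i's data do not depend on
# the cohort size (kept below .Machine$integer.max).
child_seed <- function(seed, i) {
  as.integer((as.double(seed) %% 2147483563 * 40014 + i * 40692) %% 2147483563)
}

#' Simulate a cohort of participants
#'
#' Draws per-participant observer parameters from `spec` and simulates each
#' participant's session. Each participant uses a deterministic child seed
#' derived from `seed` and their index, so participant `i`'s table is
#' invariant to the cohort size.
#'
#' @param spec A [cohort_spec()] object.
#' @param design An [experiment_design()] object; `design$n_subjects`
#'   participants are simulated.
#' @param seed Integer root seed.
#' @return A trial table with all participants' rows concatenated (empty, with
#'   the canonical columns, when `n_subjects` is 0).
#' @export
#' @examples
#' tab <- simulate_cohort(cohort_spec(), experiment_design(n_subjects = 3), seed = 7)
#' length(unique(tab$subject_id))
simulate_cohort <- function(spec, design = experiment_design(), seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(design, "experiment_design"))
  n <- design$n_subjects
  if (n == 0) return(empty_trial_table())
  ids <- sprintf("s%03d", seq_len(n))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(child_seed(seed, i))
    pars <- draw_observer(spec)
    out[[i]] <- simulate_subject(pars, design, subject_id = ids[i])
  }
  do.call(rbind, out)
}
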