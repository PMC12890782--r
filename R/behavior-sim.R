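#' One step of the adaptive presentation-time staircase
#'
#' The task holds overall accuracy near a target by adapting how long the
#' flanker stimulus stays on screen: if cumulative accuracy *exceeds* the
#' target the presentation time is reduced by one step, otherwise (including
#' exact ties) it is increased, clipped to the configured bounds.
#'
#' @param cumulative_accuracy proportion correct over trials so far.
#' @param current_ms current presentation time (ms).
#' @param step_ms step size (ms).
#' @param floor_ms,ceiling_ms presentation-time bounds (ms).
#' @param target accuracy target; the comparison is strict (`>`).
#' @return new presentation time in ms.
#' @export
staircase_update <- function(cumulative_accuracy, current_ms, step_ms = 50,
                             floor_ms = 50, ceiling_ms = 1000, target = 0.60) {
  stopifnot(current_ms >= floor_ms, current_ms <= ceiling_ms)
  new_ms <- if (cumulative_accuracy > target) current_ms - step_ms else current_ms + step_ms
  min(max(new_ms, floor_ms), ceiling_ms)
}

#' Probability of a correct response for a simulated observer
#'
#' Logistic psychometric function of presentation time, floored at the guess
#' rate. The incongruent asymptote varies with age and group on the logit
#' scale; the congruent asymptote is fixed.
#'
#' @param t_ms presentation time(s) in ms.
#' @param condition "congruent" or "incongruent".
#' @param age,group participant descriptors.
#' @param observer observer parameter list ([default_observer()]).
#' @return vector of probabilities.
#' @export
observer_p_correct <- function(t_ms, condition, age, group, observer = default_observer()) {
  o <- observer
  if (condition == "congruent") {
    asym <- o$cong_asym; t50 <- o$cong_t50_ms; sl <- o$cong_slope_ms
  } else {
    asym <- plogis(o$incong_asym_logit + o$incong_asym_age_slope * (age - 12) +
                     o$incong_group_offset[[group]])
    t50 <- o$incong_t50_ms; sl <- o$incong_slope_ms
  }
  o$guess + (asym - o$guess) * plogis((t_ms - t50) / sl)
}

#' Simulate one Flanker session under the staircase
#'
#' Runs practice then test trials; conditions are a shuffled balanced mix of
#' congruent and incongruent. After every trial the presentation time is
#' updated from the running cumulative accuracy ([staircase_update()]).
#' Practice trials warm the staircase up (if `practice_warmup`); the
#' cumulative accuracy then resets so test-trial tracking starts clean.
#' Reaction times are log-normal with age, condition, group, subject and
#' (optionally) latent-dynamics contributions: `lambda_mean` above the
#' observer's reference slows responses with weight `mediation_gain`, which
#' is what makes the eigenvalues a true mediator of age/group effects on
#' performance in the synthetic cohort.
#'
#' @param age,group participant descriptors.
#' @param config a [generator_config()].
#' @param seed integer seed for this session.
#' @param lambda_mean participant's mean true first-eigenvalue (for the
#'   mediation pathway); `NULL` disables it.
#' @param subject_rt_offset subject-level log-RT offset (drawn internally if
#'   `NULL`).
#' @return event table (data.frame) with one row per trial: `trial_index`,
#'   `phase`, `onset_s`, `condition`, `correct`, `rt_s`,
#'   `presentation_time_ms`, `response_onset_s`. Onsets are strictly
#'   increasing; `response_onset_s = onset_s + rt_s`.
#' @export
simulate_behavior_session <- function(age, group, config = generator_config(),
                                      seed = config$seed, lambda_mean = NULL,
                                      subject_rt_offset = NULL) {
  o <- config$observer; sc <- config$staircase
  set.seed(seed)
  # warn if the staircase target is out of the observer's reach
  overall <- function(t) mean(c(observer_p_correct(t, "congruent", age, group, o),
                                observer_p_correct(t, "incongruent", age, group, o)))
  if (overall(sc$floor_ms) > sc$target || overall(sc$ceiling_ms) < sc$target)
    warning("observer's psychometric range does not span the staircase target; ",
            "presentation time will pin at a bound")
  if (is.null(subject_rt_offset)) subject_rt_offset <- rnorm(1, 0, o$rt_subject_sd)
  med <- if (!is.null(lambda_mean)) config$mediation_gain * (lambda_mean - o$lambda_ref) else 0

  n_prac <- config$n_practice_trials; n_test <- config$n_test_trials
  n_all <- n_prac + n_test
  condition <- sample(rep(c("congruent", "incongruent"), length.out = n_all))
  phase <- rep(c("practice", "test"), c(n_prac, n_test))
  pt <- numeric(n_all); correct <- integer(n_all); rt <- numeric(n_all)
  cur <- sc$start_ms; n_ok <- 0L; n_seen <- 0L
  for (i in seq_len(n_all)) {
    if (i == n_prac + 1L) { n_ok <- 0L; n_seen <- 0L }  # reset after practice
    pt[i] <- cur
    p <- observer_p_correct(cur, condition[i], age, group, o)
    correct[i] <- rbinom(1, 1, p)
    mu <- log(o$rt_base_s) + o$rt_age_slope * (age - 12) +
      (condition[i] == "incongruent") * o$rt_incong +
      o$rt_group_offset[[group]] + med + subject_rt_offset
    rt[i] <- min(exp(mu + rnorm(1, 0, o$rt_trial_sd)), 2.4)
    run_staircase <- phase[i] == "test" || isTRUE(sc$practice_warmup)
    n_seen <- n_seen + 1L; n_ok <- n_ok + correct[i]
    if (run_staircase)
      cur <- staircase_update(n_ok / n_seen, cur, sc$step_ms, sc$floor_ms,
                              sc$ceiling_ms, sc$target)
  }
  onset <- 5 + cumsum(c(0, head(rt, -1) + config$iti_s + runif(n_all - 1, 0, 0.5)))
  data.frame(trial_index = seq_len(n_all), phase = phase, onset_s = onset,
             condition = condition, correct = correct, rt_s = rt,
             presentation_time_ms = pt, response_onset_s = onset + rt,
             stringsAsFactors = FALSE)
}
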