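#' Generator configuration for the synthetic longitudinal cohort
#'
#' Returns the full set of parameters that define the simulated study:
#' cohort composition, task structure, latent dynamics, sensor model and
#' behavioural observer. Defaults emulate a three-group longitudinal design
#' (never-institutionalized NIG, foster-care FCG, care-as-usual CAUG) assessed
#' at ages 12, 16 and 21, performing an adaptive Flanker task while 56-channel
#' EEG is recorded at 500 Hz.
#'
#' @param n_per_group named integer vector of participants per group
#'   (default `c(NIG = 60, FCG = 52, CAUG = 51)`, total 163).
#' @param ages assessment ages in years.
#' @param n_channels number of EEG channels.
#' @param sample_rate acquisition rate in Hz (continuous mode).
#' @param analysis_rate rate of the analysis grid in Hz (post-downsampling).
#' @param n_test_trials,n_practice_trials Flanker trial counts.
#' @param eigen_base baseline eigenvalue trajectory: either a length-2 numeric
#'   (constant \eqn{\lambda_1,\lambda_2}) or a `function(times)` returning a
#'   2-row matrix over `times` (seconds relative to flanker onset).
#' @param eigen_age_slope additive change in both eigenvalues per year of age.
#' @param eigen_group_offset named additive offset per group.
#' @param subject_sd SD of the subject-level random eigenvalue offset.
#' @param innovation_cov 2x2 innovation covariance Q of the latent AR process.
#' @param x0_sd SD of the latent initial condition.
#' @param rotation_angle rotation (degrees) applied to the dynamics matrix;
#'   0 keeps \eqn{A_t} diagonal, non-zero values produce complex eigenvalue
#'   pairs with equal moduli.
#' @param sensor_noise_sd per-channel white sensor noise SD.
#' @param erp_templates per-condition latent ERP templates; see
#'   [default_erp_templates()].
#' @param observer behavioural observer parameters; see [default_observer()].
#' @param staircase staircase parameters: `start_ms`, `step_ms`, `floor_ms`,
#'   `ceiling_ms`, `target`, `practice_warmup`.
#' @param mediation_gain weight of a participant's mean true \eqn{\lambda_1}
#'   on log reaction time; >0 makes eigenvalues a genuine mediator of
#'   age/group effects on performance.
#' @param iti_s minimum interval (s) between a response and the next flanker
#'   onset; must be >= 2.5 so epochs never cross trials.
#' @param seed integer root seed; all randomness derives from it.
#' @return a list of class `resdyn_generator_config`.
#' @export
generator_config <- function(n_per_group = c(NIG = 60, FCG = 52, CAUG = 51),
                             ages = c(12, 16, 21),
                             n_channels = 56,
                             sample_rate = 500,
                             analysis_rate = 40,
                             n_test_trials = 160,
                             n_practice_trials = 20,
                             eigen_base = c(0.75, 0.55),
                             eigen_age_slope = -0.010,
                             eigen_group_offset = c(NIG = 0, FCG = 0.05, CAUG = 0.06),
                             subject_sd = 0.04,
                             innovation_cov = diag(1.5, 2),
                             x0_sd = 2,
                             rotation_angle = 0,
                             sensor_noise_sd = 0.2,
                             erp_templates = default_erp_templates(),
                             observer = default_observer(),
                             staircase = list(start_ms = 400, step_ms = 50,
                                              floor_ms = 50, ceiling_ms = 1000,
                                              target = 0.60, practice_warmup = TRUE),
                             mediation_gain = 4,
                             iti_s = 2.5,
                             seed = 1L) {
  groups <- c("NIG", "FCG", "CAUG")
  if (is.null(names(n_per_group)) || !setequal(names(n_per_group), groups))
    stop("n_per_group must be named with groups ", paste(groups, collapse = ", "))
  if (any(n_per_group <= 0) || any(n_per_group != round(n_per_group)))
    stop("configuration error: n_per_group must be positive integers")
  if (!setequal(names(eigen_group_offset), groups))
    stop("eigen_group_offset must be named with the declared groups")
  if (!isTRUE(all.equal(innovation_cov, t(innovation_cov))) ||
      inherits(try(chol(innovation_cov), silent = TRUE), "try-error"))
    stop("configuration error: innovation_cov must be symmetric positive-definite")
  if (iti_s < 2.5)
    stop("iti_s must be >= 2.5 s so flanker- and response-aligned epochs never cross trials")
  eigen_age_slope <- rep_len(eigen_age_slope, 2L)
  cfg <- list(n_per_group = n_per_group[groups], ages = sort(ages),
              n_channels = n_channels, sample_rate = sample_rate,
              analysis_rate = analysis_rate,
              n_test_trials = n_test_trials,
              n_practice_trials = n_practice_trials,
              eigen_base = eigen_base, eigen_age_slope = eigen_age_slope,
              eigen_group_offset = eigen_group_offset[groups],
              subject_sd = subject_sd, innovation_cov = innovation_cov,
              x0_sd = x0_sd, rotation_angle = rotation_angle,
              sensor_noise_sd = sensor_noise_sd,
              erp_templates = erp_templates, observer = observer,
              staircase = staircase, mediation_gain = mediation_gain,
              iti_s = iti_s, seed = as.integer(seed))
  class(cfg) <- "resdyn_generator_config"
  cfg
}

#' Default latent-space ERP templates
#'
#' Each of the four condition cells (congruent/incongruent x correct/error)
#' is a sum of Gaussian bumps in the 2D latent space. Bumps are anchored
#' either to the flanker stimulus or to the response, so both stimulus-locked
#' and response-locked ERPs carry structure. Amplitudes differ across cells
#' (larger stimulus response for incongruent trials; a strong response-locked
#' deflection on component 2 for errors, an error-monitoring analogue).
#'
#' @return named list with one bump table per cell; each bump has fields
#'   `dim` (latent component 1 or 2), `amp`, `center_s`, `width_s`,
#'   `align` ("flanker" or "response").
#' @export
default_erp_templates <- function() {
  bump <- function(dim, amp, center_s, width_s, align = "flanker")
    list(dim = dim, amp = amp, center_s = center_s, width_s = width_s, align = align)
  base1 <- function(a) list(bump(1, a, 0.15, 0.06), bump(1, -0.45 * a, 0.35, 0.12))
  list(
    congruent_correct   = c(base1(3.0), list(bump(2, 1.0, 0.25, 0.10),
                                             bump(2, 1.2, 0.08, 0.07, "response"))),
    congruent_error     = c(base1(3.0), list(bump(2, 1.0, 0.25, 0.10),
                                             bump(2, 4.0, 0.08, 0.07, "response"))),
    incongruent_correct = c(base1(3.8), list(bump(2, 1.4, 0.25, 0.10),
                                             bump(2, 1.2, 0.08, 0.07, "response"))),
    incongruent_error   = c(base1(3.8), list(bump(2, 1.4, 0.25, 0.10),
                                             bump(2, 4.0, 0.08, 0.07, "response")))
  )
}

#' Default behavioural observer
#'
#' Logistic psychometric functions of presentation time (per condition) and a
#' log-normal reaction-time model. The congruent asymptote is fixed and high;
#' the incongruent asymptote depends on age and group on the logit scale, so
#' the adaptive staircase equalises *overall* accuracy near its target while
#' condition-specific accuracy retains age and group structure.
#'
#' @return list of observer parameters.
#' @export
default_observer <- function() {
  list(guess = 0.5,
       cong_asym = 0.97, cong_t50_ms = 150, cong_slope_ms = 80,
       incong_asym_logit = qlogis(0.60), incong_asym_age_slope = 0.10,
       incong_group_offset = c(NIG = 0.25, FCG = -0.45, CAUG = -0.60),
       incong_t50_ms = 300, incong_slope_ms = 100,
       rt_base_s = 0.55, rt_age_slope = -0.015, rt_incong = 0.08,
       rt_group_offset = c(NIG = 0, FCG = 0.02, CAUG = 0.03),
       rt_subject_sd = 0.06, rt_trial_sd = 0.25,
       lambda_ref = 0.65)
}

# Deterministic child seeds: one substream per unit of work, derived from the
# root seed without touching the caller's RNG state.
child_seeds <- function(root, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(root)
  sample.int(.Machine$integer.max - 1L, n)
}
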