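#' Ground-truth eigenvalue trajectories for one participant-visit
#'
#' The generator's model of how the persistence of neural perturbations
#' varies over trial time and across the cohort:
#' \deqn{\lambda_d(t) = clip(base_d(t) + slope_d (age - 12) + group_d + subject_d,\ 0,\ 0.98)}
#' with a negative age slope (dynamics speed up across adolescence) and
#' positive offsets for ever-institutionalized groups. After clipping the two
#' trajectories are ordered so \eqn{\lambda_1 \ge \lambda_2} pointwise.
#'
#' @param times numeric vector of times (s, relative to flanker onset).
#' @param age age in years.
#' @param group group label.
#' @param subject_offset length-2 subject-level additive offset.
#' @param config a [generator_config()].
#' @return 2 x length(times) matrix, row 1 = \eqn{\lambda_1(t)}.
#' @export
eigenvalue_profile <- function(times, age, group, subject_offset = c(0, 0),
                               config = generator_config()) {
  base <- config$eigen_base
  b <- if (is.function(base)) {
    m <- base(times)
    stopifnot(is.matrix(m), nrow(m) == 2, ncol(m) == length(times))
    m
  } else matrix(rep(base, length(times)), nrow = 2)
  eff <- config$eigen_age_slope * (age - 12) +
    config$eigen_group_offset[[group]] + subject_offset
  lam <- pmin(pmax(b + eff, 0), 0.98)
  apply(lam, 2, sort, decreasing = TRUE)
}
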