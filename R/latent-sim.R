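#' Evaluate a condition's ERP template on a latent time grid
#'
#' Sums the template's Gaussian bumps; flanker-anchored bumps are placed at
#' their `center_s` relative to flanker onset, response-anchored bumps at
#' `center_s` relative to the response (i.e. shifted by `rt_s`).
#'
#' @param template bump list for one condition cell.
#' @param times time grid (s, relative to flanker onset).
#' @param rt_s reaction time of the trial (s); needed for response-anchored bumps.
#' @return 2 x length(times) matrix.
#' @export
template_series <- function(template, times, rt_s = 0) {
  out <- matrix(0, 2, length(times))
  for (b in template) {
    center <- b$center_s + if (identical(b$align, "response")) rt_s else 0
    out[b$dim, ] <- out[b$dim, ] + b$amp * exp(-0.5 * ((times - center) / b$width_s)^2)
  }
  out
}

# rotation matrix, angle in degrees
rot2 <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

#' Simulate latent 2D series for a batch of trials
#'
#' Runs the generative AR(1) recursion \eqn{x_{t+1} = A_t x_t + \epsilon_t}
#' with \eqn{A_t = R\,diag(\lambda_1(t), \lambda_2(t))} (R a rotation by
#' `rotation_angle`; at 0 degrees \eqn{A_t} is diagonal with the profile as
#' its eigenvalues, at non-zero angles the dynamics spiral and the
#' eigenvalues form a complex pair), \eqn{\epsilon_t \sim N(0, Q)}, and
#' \eqn{x_1 \sim N(0, \sigma_0^2 I)}; the condition template is added on top.
#' All trials in the batch share the profile and time grid (templates may
#' differ per trial through `rt_s`).
#'
#' @param profile 2 x T eigenvalue trajectories (from [eigenvalue_profile()]).
#' @param times time grid (s) matching `profile`.
#' @param templates list (length n) of per-trial bump lists, or a single bump
#'   list reused for all trials; `NULL` for zero template.
#' @param rt_s per-trial reaction times (recycled).
#' @param n number of trials.
#' @param Q 2x2 innovation covariance.
#' @param x0_sd initial-condition SD.
#' @param rotation_angle degrees.
#' @return array n x 2 x T of latent series (template + residual), with the
#'   pure residual component in attribute `"residual"`.
#' @export
simulate_trial_latent <- function(profile, times, templates = NULL, rt_s = 0,
                                  n = 1, Q = diag(1.5, 2), x0_sd = 2,
                                  rotation_angle = 0) {
  Tn <- ncol(profile)
  stopifnot(length(times) == Tn)
  if (any(profile >= 1)) stop("unstable profile: spectral radius must be < 1")
  R <- rot2(rotation_angle)
  zero_q <- all(Q == 0)
  Lq <- if (zero_q) NULL else t(chol(Q))
  X <- array(0, c(n, 2, Tn))
  x <- matrix(rnorm(2 * n, 0, x0_sd), n, 2)
  X[, , 1] <- x
  for (t in seq_len(Tn - 1)) {
    A <- R %*% diag(profile[, t], 2)
    eps <- if (zero_q) matrix(0, n, 2) else matrix(rnorm(2 * n), n, 2) %*% t(Lq)
    x <- x %*% t(A) + eps
    X[, , t + 1] <- x
  }
  resid <- X
  rt_s <- rep_len(rt_s, n)
  if (!is.null(templates)) {
    # `templates` is a single bump list if its first element is a bump
    is_bump_list <- is.list(templates[[1]]) && !is.null(templates[[1]]$amp)
    for (i in seq_len(n)) {
      tpl <- if (is_bump_list) templates else templates[[i]]
      X[i, , ] <- X[i, , ] + template_series(tpl, times, rt_s[i])
    }
  }
  attr(X, "residual") <- resid
  X
}
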