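#' Time grid of AR-window centers
#'
#' A 200 ms window at 40 Hz spans 8 samples (7 consecutive transition pairs
#' per trial) and slides by one sample (25 ms); the reported time stamp of a
#' window is the midpoint of its samples.
#'
#' @param sfreq analysis rate (Hz).
#' @param tmin,tmax epoch window (s).
#' @param window_ms,step_ms moving-window parameters (ms).
#' @return numeric vector of window-center times (s).
#' @export
ar_window_centers <- function(sfreq = 40, tmin = -1, tmax = 1,
                              window_ms = 200, step_ms = 25) {
  times <- epoch_time_grid(sfreq, tmin, tmax)
  win <- round(window_ms / 1000 * sfreq)
  step <- max(1L, round(step_ms / 1000 * sfreq))
  starts <- seq(1L, length(times) - win + 1L, by = step)
  (times[starts] + times[starts + win - 1L]) / 2
}

#' Moving-window AR(1) fit to pooled residual trials
#'
#' Within each window, pools the consecutive-sample transition pairs
#' \eqn{(x_t, x_{t+1})} of every trial (all condition cells together; pairs
#' never straddle a window edge) and solves the intercept-free least-squares
#' problem \eqn{\hat A = (\sum x_{t+1} x_t')(\sum x_t x_t')^{-1}}. Residuals
#' are mean-zero by construction so no intercept is fit; the pooled mean is
#' checked before fitting. Windows whose second-moment matrix is
#' ill-conditioned (condition number > 1e10) or that hold fewer than
#' `min_pairs` pairs are marked missing rather than extrapolated.
#'
#' @param resid residual set from [residuals_latent()] (or any list with
#'   `data` trials x 2 x T and `times`).
#' @param window_ms,step_ms moving-window parameters (ms).
#' @param min_pairs minimum pooled pairs per window.
#' @return data.frame, one row per window: `t_center`, `a11,a12,a21,a22`,
#'   `n_pairs`, `ok`, plus innovation covariance entries `q11,q12,q22`.
#' @export
fit_window_ar <- function(resid, window_ms = 200, step_ms = 25, min_pairs = 50) {
  X <- resid$data; times <- resid$times
  n <- dim(X)[1]; Tn <- dim(X)[3]
  sfreq <- 1 / mean(diff(times))
  win <- round(window_ms / 1000 * sfreq)
  step <- max(1L, round(step_ms / 1000 * sfreq))
  stopifnot(win >= 2, Tn >= win)
  mu <- c(mean(X[, 1, ]), mean(X[, 2, ]))
  if (any(abs(mu) > 0.5)) stop("pooled residual mean is far from zero; were residuals computed?")
  starts <- seq(1L, Tn - win + 1L, by = step)
  out <- data.frame(t_center = (times[starts] + times[starts + win - 1L]) / 2,
                    a11 = NA_real_, a12 = NA_real_, a21 = NA_real_, a22 = NA_real_,
                    q11 = NA_real_, q12 = NA_real_, q22 = NA_real_,
                    n_pairs = 0L, ok = FALSE)
  for (w in seq_along(starts)) {
    cols <- starts[w]:(starts[w] + win - 2L)
    X0 <- cbind(as.vector(X[, 1, cols]), as.vector(X[, 2, cols]))
    X1 <- cbind(as.vector(X[, 1, cols + 1L]), as.vector(X[, 2, cols + 1L]))
    np <- nrow(X0)
    out$n_pairs[w] <- np
    if (np < min_pairs) next
    S00 <- crossprod(X0); S01 <- crossprod(X0, X1)
    if (kappa(S00, exact = TRUE) > 1e10) next
    A <- t(solve(S00, S01))
    E <- X1 - X0 %*% t(A)
    Q <- crossprod(E) / np
    out[w, c("a11", "a12", "a21", "a22")] <- c(A[1, 1], A[1, 2], A[2, 1], A[2, 2])
    out[w, c("q11", "q12", "q22")] <- c(Q[1, 1], Q[1, 2], Q[2, 2])
    out$ok[w] <- TRUE
  }
  out
}

#' Normal-equations oracle for one pooled AR(1) window
#'
#' Independent reference fit: accumulates the normal equations pair by pair
#' and inverts the 2x2 second-moment matrix in closed form. Agrees with
#' [fit_window_ar()] to near machine precision on every window; kept as a
#' cross-check path, not a replacement.
#'
#' @param X0,X1 n x 2 matrices of paired states (x_t and x_{t+1}).
#' @return 2x2 coefficient matrix, or NULL if the system is singular.
#' @export
ar_oracle <- function(X0, X1) {
  s00 <- 0; s01 <- 0; s11 <- 0
  b11 <- 0; b12 <- 0; b21 <- 0; b22 <- 0
  for (i in seq_len(nrow(X0))) {
    x <- X0[i, ]; y <- X1[i, ]
    s00 <- s00 + x[1] * x[1]; s01 <- s01 + x[1] * x[2]; s11 <- s11 + x[2] * x[2]
    b11 <- b11 + y[1] * x[1]; b12 <- b12 + y[1] * x[2]
    b21 <- b21 + y[2] * x[1]; b22 <- b22 + y[2] * x[2]
  }
  det <- s00 * s11 - s01 * s01
  if (!is.finite(det) || abs(det) < 1e-12 * max(s00, s11, 1)) return(NULL)
  inv <- matrix(c(s11, -s01, -s01, s00), 2, 2) / det
  B <- matrix(c(b11, b12, b21, b22), 2, 2, byrow = TRUE)   # rows: outputs
  B %*% inv
}

#' Eigenvalue-modulus time series from windowed AR fits
#'
#' Extracts the eigenvalues of each window's coefficient matrix and reports
#' their moduli sorted descending: \eqn{\lambda_1(t) \ge \lambda_2(t)}.
#' Complex-conjugate pairs have equal moduli (\eqn{\sqrt{\det A}}), so the
#' series stays real-valued. Missing windows propagate as NA.
#'
#' @param fits data.frame from [fit_window_ar()].
#' @return data.frame: `t_center`, `lambda1`, `lambda2`, `ok`.
#' @export
eigen_series <- function(fits) {
  lam <- t(vapply(seq_len(nrow(fits)), function(w) {
    if (!fits$ok[w]) return(c(NA_real_, NA_real_))
    A <- matrix(c(fits$a11[w], fits$a21[w], fits$a12[w], fits$a22[w]), 2, 2)
    sort(Mod(eigen(A, only.values = TRUE)$values), decreasing = TRUE)
  }, numeric(2)))
  data.frame(t_center = fits$t_center, lambda1 = lam[, 1], lambda2 = lam[, 2],
             ok = fits$ok)
}
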