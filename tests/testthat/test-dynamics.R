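test_that("window centers implement 200 ms / 8-sample windows at 25 ms steps", {
  ctr <- ar_window_centers()
  expect_length(ctr, 73)                       # 80 - 8 + 1 windows
  expect_equal(ctr[1], (-1 + -1 + 7 / 40) / 2) # midpoint of samples 1..8
  expect_equal(diff(ctr)[1], 1 / 40)
})

test_that("noiseless linear decay is fit exactly in every window", {
  Tn <- 80; n <- 10
  set.seed(2)
  X <- array(0, c(n, 2, Tn))
  X[, , 1] <- rnorm(2 * n)
  for (t in 2:Tn) X[, , t] <- 0.5 * X[, , t - 1]
  res <- list(data = X, times = seq(-1, 0.975, by = 1 / 40))
  fits <- fit_window_ar(res, min_pairs = 10)
  expect_true(all(fits$ok))
  expect_equal(fits$a11, rep(0.5, 73), tolerance = 1e-9)
  expect_equal(fits$a22, rep(0.5, 73), tolerance = 1e-9)
  expect_equal(fits$a12, rep(0, 73), tolerance = 1e-9)
  es <- eigen_series(fits)
  expect_equal(es$lambda1, rep(0.5, 73), tolerance = 1e-9)
})

test_that("stationary AR(1) moduli are recovered within 0.05 at 500 trials", {
  set.seed(31)
  tr <- ar_trials(500, 0.9, 0.3, q = 0.1)
  es <- eigen_series(fit_window_ar(tr))
  expect_lt(abs(median(es$lambda1) - 0.9), 0.05)
  expect_lt(abs(median(es$lambda2) - 0.3), 0.05)
  # lag-covariance oracle on the pooled sample: A = C1 C0^{-1}
  X <- tr$data
  X0 <- cbind(as.vector(X[, 1, 1:79]), as.vector(X[, 2, 1:79]))
  X1 <- cbind(as.vector(X[, 1, 2:80]), as.vector(X[, 2, 2:80]))
  A <- t(solve(crossprod(X0), crossprod(X0, X1)))
  expect_equal(sort(Mod(eigen(A)$values), decreasing = TRUE), c(0.9, 0.3),
               tolerance = 0.03)
})

test_that("white-noise residuals give near-zero moduli", {
  set.seed(5)
  tr <- ar_trials(500, 0, 0, q = 1)
  es <- eigen_series(fit_window_ar(tr))
  expect_lt(max(es$lambda1, na.rm = TRUE), 0.1)
})

test_that("OLS fit equals the normal-equations oracle on every window", {
  set.seed(8)
  tr <- ar_trials(40, 0.7, 0.4, q = 0.2)
  X <- tr$data
  fits <- fit_window_ar(tr, min_pairs = 10)
  for (w in seq_len(nrow(fits))) {
    s <- w  # step is one sample, so window w starts at sample w
    cols <- s:(s + 6)
    X0 <- cbind(as.vector(X[, 1, cols]), as.vector(X[, 2, cols]))
    X1 <- cbind(as.vector(X[, 1, cols + 1]), as.vector(X[, 2, cols + 1]))
    A_o <- ar_oracle(X0, X1)
    A_f <- matrix(c(fits$a11[w], fits$a21[w], fits$a12[w], fits$a22[w]), 2, 2)
    expect_lt(max(abs(A_o - A_f)), 1e-8)
  }
})

test_that("an exactly determined system is interpolated; degenerate pairs flagged", {
  # two trials spanning R^2 with a single transition each
  X0 <- rbind(c(1, 0), c(0, 1))
  X1 <- rbind(c(0.3, 0.1), c(-0.2, 0.8))
  A <- ar_oracle(X0, X1)
  expect_equal(A %*% t(X0), t(X1), tolerance = 1e-12)
  # pairs all on one line -> singular on both paths
  X0d <- rbind(c(1, 1), c(2, 2), c(3, 3))
  X1d <- X0d * 0.5
  expect_null(ar_oracle(X0d, X1d))
  X0z <- rbind(c(1, 1), c(-1, -1), c(0.5, 0.5), c(-0.5, -0.5))  # mean-zero line
  Xarr <- array(0, c(4, 2, 80))
  for (t in 1:80) Xarr[, , t] <- X0z * 0.99^t
  resd <- list(data = Xarr, times = seq(-1, 0.975, by = 1 / 40))
  fitsd <- fit_window_ar(resd, min_pairs = 1)
  expect_false(any(fitsd$ok))
})

test_that("eigen extraction: diagonal, rotation, nilpotent cases", {
  f <- function(A) {
    fits <- data.frame(t_center = 0, a11 = A[1, 1], a12 = A[1, 2],
                       a21 = A[2, 1], a22 = A[2, 2], q11 = 0, q12 = 0,
                       q22 = 0, n_pairs = 100L, ok = TRUE)
    unlist(eigen_series(fits)[1, c("lambda1", "lambda2")], use.names = FALSE)
  }
  expect_equal(f(diag(c(0.9, 0.3))), c(0.9, 0.3))
  th <- pi / 4
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_equal(f(0.8 * R), c(0.8, 0.8), tolerance = 1e-12)
  expect_equal(f(matrix(c(0, 0, 1, 0), 2, 2)), c(0, 0))
})

test_that("rescaling residuals leaves the fitted dynamics unchanged", {
  set.seed(12)
  tr <- ar_trials(60, 0.6, 0.2, q = 0.3)
  f1 <- fit_window_ar(tr)
  tr2 <- tr; tr2$data <- tr2$data * 37.5
  f2 <- fit_window_ar(tr2)
  expect_equal(f1[c("a11", "a12", "a21", "a22")],
               f2[c("a11", "a12", "a21", "a22")], tolerance = 1e-9)
})

test_that("recovery error shrinks with trial count; small-sample bias is downward", {
  set.seed(17)
  lam_grid <- c(0.2, 0.5, 0.8)
  med_err <- matrix(NA, 3, 3, dimnames = list(lam_grid, c(50, 150, 500)))
  for (i in seq_along(lam_grid)) for (j in seq_along(c(50, 150, 500))) {
    n <- c(50, 150, 500)[j]
    errs <- vapply(1:3, function(k) {
      tr <- ar_trials(n, lam_grid[i], max(lam_grid[i] - 0.2, 0.05), q = 0.2)
      es <- eigen_series(fit_window_ar(tr))
      abs(median(es$lambda1, na.rm = TRUE) - lam_grid[i])
    }, numeric(1))
    med_err[i, j] <- median(errs)
  }
  expect_true(all(med_err[, "500"] <= 0.05))
  expect_true(all(med_err[, "500"] <= med_err[, "50"] + 0.01))
})

test_that("a dip in the true profile is localized within 50 ms at 500 trials", {
  set.seed(23)
  t <- seq(-1, 0.975, by = 1 / 40)
  prof <- rbind(0.8 - 0.5 * exp(-((t - 0.2) / 0.12)^2), rep(0.3, length(t)))
  X <- simulate_trial_latent(prof, t, n = 500, Q = diag(0.3, 2), x0_sd = 1)
  res <- list(data = attr(X, "residual"), times = t)
  es <- eigen_series(fit_window_ar(res))
  t_min <- es$t_center[which.min(es$lambda1)]
  expect_lt(abs(t_min - 0.2), 0.05 + 1e-9)
})
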