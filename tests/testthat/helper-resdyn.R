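# Shared fixtures and independent oracles for the suite. Heavy shared
# computations (the default-cohort analysis bundle) are memoised for the
# session so several test files can reuse them.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .cache)) assign(key, force(expr), .cache)
  get(key, .cache)
}

# A small but fully-featured cohort shared across files.
small_cohort <- function() memo("small_cohort", {
  build_cohort(generator_config(n_per_group = c(NIG = 2, FCG = 2, CAUG = 2),
                                seed = 42))
})

# Full default-condition analysis bundle (the study-scale run).
default_bundle <- function() memo("default_bundle", {
  run_all(pipeline_config(generator = generator_config(seed = 20240901),
                          n_boot = 1000),
          progress = FALSE)
})

# Noise-free generator settings: tiny innovation variance, zero sensor
# noise, fixed initial state - epochs become (almost) pure mixed templates.
noiseless_config <- function(...) {
  generator_config(innovation_cov = diag(1e-10, 2), x0_sd = 0,
                   sensor_noise_sd = 0, subject_sd = 0, ...)
}

# Brute-force Benjamini-Hochberg: largest k with p_(k) <= k * alpha / m,
# rejecting exactly the k smallest p-values. Returns the rejection set,
# used as the independent oracle for p.adjust-based masks.
bh_brute_force <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  k_max <- 0L
  for (k in seq_len(m)) if (p[ord[k]] <= k * alpha / m) k_max <- k
  rej <- logical(m)
  if (k_max > 0) rej[ord[seq_len(k_max)]] <- TRUE
  rej
}

# Principal angles between the column spaces of two matrices (radians).
principal_angles <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  s <- svd(crossprod(qa, qb))$d
  acos(pmin(pmax(s, -1), 1))
}

# Simulate a batch of stationary 2D AR(1) residual trials with constant
# diagonal dynamics (independent generative path used by dynamics tests).
ar_trials <- function(n_trials, l1, l2, q = 0.1, Tn = 80, noise_sd = 0) {
  X <- array(0, c(n_trials, 2, Tn))
  X[, 1, 1] <- rnorm(n_trials, 0, sqrt(q / (1 - l1^2)))
  X[, 2, 1] <- rnorm(n_trials, 0, sqrt(q / (1 - l2^2)))
  for (t in 2:Tn) {
    X[, 1, t] <- l1 * X[, 1, t - 1] + rnorm(n_trials, 0, sqrt(q))
    X[, 2, t] <- l2 * X[, 2, t - 1] + rnorm(n_trials, 0, sqrt(q))
  }
  if (noise_sd > 0) X <- X + array(rnorm(length(X), 0, noise_sd), dim(X))
  list(data = X, times = seq(-1, 0.975, by = 1 / 40))
}
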