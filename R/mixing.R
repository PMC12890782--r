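#' Random orthonormal channel-mixing matrix
#'
#' Draws an n_channels x 2 matrix with orthonormal columns (QR of a Gaussian
#' matrix), the forward model mapping the 2D latent space onto the sensor
#' array. Column signs are fixed so the largest-magnitude weight in each
#' column is positive.
#'
#' @param n_channels number of channels.
#' @param seed integer seed.
#' @return n_channels x 2 matrix with orthonormal columns.
#' @export
make_mixing <- function(n_channels, seed = 1L) {
  set.seed(seed)
  M <- qr.Q(qr(matrix(rnorm(n_channels * 2), n_channels, 2)))
  for (k in 1:2) if (M[which.max(abs(M[, k])), k] < 0) M[, k] <- -M[, k]
  M
}

#' Render latent trials into a continuous multichannel recording
#'
#' Places each trial's channel-space signal (`mixing %*% latent`) into a
#' continuous recording at the event onsets, on a baseline of white sensor
#' noise. Trial windows must not overlap (the task's inter-trial interval
#' guarantees this for well-formed event tables).
#'
#' @param latent_trials list of 2 x T latent matrices (one per trial, at
#'   `sample_rate`).
#' @param trial_starts_s start time (s) of each trial's first latent sample.
#' @param mixing channels x 2 weight matrix (full column rank).
#' @param sensor_noise_sd white noise SD per channel.
#' @param sample_rate Hz.
#' @param duration_s total recording length (s).
#' @param channel_names optional channel names.
#' @return a [raw_recording()].
#' @export
mix_to_channels <- function(latent_trials, trial_starts_s, mixing,
                            sensor_noise_sd, sample_rate, duration_s,
                            channel_names = NULL) {
  stopifnot(qr(mixing)$rank == 2, length(latent_trials) == length(trial_starts_s))
  n_ch <- nrow(mixing)
  n_samp <- round(duration_s * sample_rate)
  dat <- matrix(rnorm(n_ch * n_samp, 0, sensor_noise_sd), n_ch, n_samp)
  prev_end <- -Inf
  ord <- order(trial_starts_s)
  for (i in ord) {
    s0 <- round(trial_starts_s[i] * sample_rate)  # 0-based
    len <- ncol(latent_trials[[i]])
    if (s0 < prev_end) stop("overlapping trial windows: enforce the inter-trial interval")
    if (s0 < 0 || s0 + len > n_samp) stop("trial window outside the recording")
    idx <- (s0 + 1):(s0 + len)
    dat[, idx] <- dat[, idx] + mixing %*% latent_trials[[i]]
    prev_end <- s0 + len
  }
  raw_recording(dat, sample_rate, channel_names)
}
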