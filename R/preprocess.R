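#' Continuous multichannel recording container
#'
#' @param data channels x samples numeric matrix (arbitrary units).
#' @param sfreq sampling rate in Hz.
#' @param channel_names optional character vector.
#' @return object of class `resdyn_raw`.
#' @export
raw_recording <- function(data, sfreq, channel_names = NULL) {
  stopifnot(is.matrix(data), sfreq > 0)
  if (anyNA(data)) stop("recording contains NaN/NA samples")
  if (is.null(channel_names)) channel_names <- sprintf("ch%02d", seq_len(nrow(data)))
  stopifnot(length(channel_names) == nrow(data))
  structure(list(data = data, sfreq = sfreq, channel_names = channel_names),
            class = "resdyn_raw")
}

#' @export
print.resdyn_raw <- function(x, ...) {
  cat("Recording:", nrow(x$data), "channels x", ncol(x$data), "samples @",
      x$sfreq, "Hz\n")
  invisible(x)
}

# 2nd-order IIR notch (standard biquad design), quality factor Q
iir_notch <- function(f0, fs, Q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  list(b = c(1, -2 * cos(w0), 1) / (1 + alpha),
       a = c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha)))
}

#' Filter chain: notch, high-pass, low-pass
#'
#' Applies, in order: a 50 Hz notch (2nd-order IIR, Q = 30), a 1 Hz
#' high-pass (4th-order Butterworth) and a 20 Hz low-pass (2nd-order
#' Butterworth). All filters are run zero-phase (forward-backward,
#' [signal::filtfilt()]) so ERP latencies are not shifted; the effective
#' order therefore doubles.
#'
#' @param raw a [raw_recording()].
#' @param notch_hz,hp_hz,lp_hz corner/center frequencies (Hz).
#' @param notch_q notch quality factor.
#' @return filtered [raw_recording()] at the same rate.
#' @export
filter_chain <- function(raw, notch_hz = 50, hp_hz = 1, lp_hz = 20, notch_q = 30) {
  stopifnot(inherits(raw, "resdyn_raw"))
  corners <- c(notch = notch_hz, highpass = hp_hz, lowpass = lp_hz)
  for (nm in names(corners))
    if (raw$sfreq < 2 * corners[[nm]])
      stop("sampling rate ", raw$sfreq, " Hz is below twice the ", nm,
           " corner (", corners[[nm]], " Hz)")
  nf <- iir_notch(notch_hz, raw$sfreq, notch_q)
  hp <- signal::butter(4, hp_hz / (raw$sfreq / 2), "high")
  lp <- signal::butter(2, lp_hz / (raw$sfreq / 2), "low")
  out <- raw$data
  for (ch in seq_len(nrow(out))) {
    x <- signal::filtfilt(filt = nf$b, a = nf$a, x = out[ch, ])
    x <- signal::filtfilt(hp, x)
    out[ch, ] <- signal::filtfilt(lp, x)
  }
  raw_recording(out, raw$sfreq, raw$channel_names)
}

#' Eye-blink removal hook
#'
#' Placeholder stage where ICA-based ocular artifact removal would run on
#' real recordings; the synthetic data contain no blinks, so this is the
#' identity.
#'
#' @param raw a [raw_recording()].
#' @return `raw`, unchanged.
#' @export
remove_blinks <- function(raw) raw

#' Downsample a recording by rational resampling
#'
#' Polyphase rational resampling to `target_hz` (e.g. 500 -> 40 Hz is the
#' rational factor 2/25). Duration is preserved to within one sample.
#'
#' @param raw a [raw_recording()].
#' @param target_hz target rate (Hz), must not exceed the current rate.
#' @return resampled [raw_recording()].
#' @export
downsample <- function(raw, target_hz = 40) {
  stopifnot(inherits(raw, "resdyn_raw"))
  if (target_hz > raw$sfreq) stop("target rate exceeds the sampling rate")
  if (target_hz == raw$sfreq) return(raw)
  g <- gcd(round(target_hz * 1000), round(raw$sfreq * 1000))
  p <- round(target_hz * 1000) / g; q <- round(raw$sfreq * 1000) / g
  n_out <- floor(ncol(raw$data) * p / q)
  out <- matrix(0, nrow(raw$data), n_out)
  for (ch in seq_len(nrow(out))) {
    y <- signal::resample(raw$data[ch, ], p, q)
    out[ch, ] <- y[seq_len(n_out)]
  }
  raw_recording(out, target_hz, raw$channel_names)
}

gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)

#' Epoched data container
#'
#' @param data trials x channels x time array.
#' @param times seconds relative to the alignment event.
#' @param alignment "flanker" or "response".
#' @param info per-trial data.frame (condition, correct, rt_s, ...).
#' @param sfreq sampling rate (Hz).
#' @param channel_names character vector.
#' @return object of class `resdyn_epochs`.
#' @export
epoch_set <- function(data, times, alignment, info, sfreq, channel_names) {
  stopifnot(length(dim(data)) == 3, dim(data)[3] == length(times),
            dim(data)[1] == nrow(info), alignment %in% c("flanker", "response"))
  structure(list(data = data, times = times, alignment = alignment,
                 info = info, sfreq = sfreq, channel_names = channel_names),
            class = "resdyn_epochs")
}

#' @export
print.resdyn_epochs <- function(x, ...) {
  cat("Epochs (", x$alignment, "-aligned): ", dim(x$data)[1], " trials x ",
      dim(x$data)[2], " channels x ", dim(x$data)[3], " samples @ ",
      x$sfreq, " Hz\n", sep = "")
  invisible(x)
}

#' Segment a recording around task events
#'
#' Cuts half-open `[tmin, tmax)` windows around each event: at 40 Hz and the
#' default window this is exactly 80 samples, with the event at sample index
#' `-tmin * sfreq` (0-based). Events whose window would cross a recording
#' edge are dropped and counted in attribute `"n_dropped"`.
#'
#' @param raw a [raw_recording()] (already downsampled to the analysis rate).
#' @param events event table; flanker alignment uses `onset_s`, response
#'   alignment uses `response_onset_s`.
#' @param alignment "flanker" or "response".
#' @param tmin,tmax epoch window in seconds (half-open).
#' @return a [epoch_set()]; attribute `"n_dropped"` counts excluded events.
#' @export
epoch <- function(raw, events, alignment = c("flanker", "response"),
                  tmin = -1, tmax = 1) {
  alignment <- match.arg(alignment)
  stopifnot(inherits(raw, "resdyn_raw"))
  onset <- if (alignment == "flanker") events$onset_s else events$response_onset_s
  fs <- raw$sfreq
  n_t <- round((tmax - tmin) * fs)
  s0 <- round(onset * fs) + round(tmin * fs)         # 0-based first sample
  ok <- s0 >= 0 & (s0 + n_t) <= ncol(raw$data)
  if (!any(ok)) stop("no epochable events inside the recording")
  keep <- which(ok)
  dat <- array(0, c(length(keep), nrow(raw$data), n_t))
  for (k in seq_along(keep))
    dat[k, , ] <- raw$data[, (s0[keep[k]] + 1):(s0[keep[k]] + n_t)]
  times <- tmin + (seq_len(n_t) - 1) / fs
  info <- events[keep, , drop = FALSE]
  if (!is.null(info$condition) && !is.null(info$correct))
    info$cell <- paste0(info$condition, "_",
                        ifelse(info$correct == 1, "correct", "error"))
  out <- epoch_set(dat, times, alignment, info, fs, raw$channel_names)
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Z-transform channels within a participant-visit
#'
#' Standardizes each channel to mean 0, SD 1 using moments pooled over *all*
#' epoched samples of the visit (every trial of every supplied alignment),
#' and applies the same affine map to each alignment — so the two alignments
#' stay on a common scale.
#'
#' @param ... one or more [epoch_set()] objects from the same visit.
#' @return list of the same epoch sets, z-scored (single input returns a
#'   list of length one).
#' @export
zscore_channels <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && !inherits(sets[[1]], "resdyn_epochs")) sets <- sets[[1]]
  n_ch <- dim(sets[[1]]$data)[2]
  mu <- numeric(n_ch); s2 <- numeric(n_ch); n_tot <- 0
  for (es in sets) {
    for (ch in seq_len(n_ch)) {
      v <- es$data[, ch, ]
      mu[ch] <- mu[ch] + sum(v); s2[ch] <- s2[ch] + sum(v^2)
    }
    n_tot <- n_tot + dim(es$data)[1] * dim(es$data)[3]
  }
  mu <- mu / n_tot
  sdv <- sqrt(pmax((s2 - n_tot * mu^2) / (n_tot - 1), 0))
  bad <- which(sdv < 1e-12)
  if (length(bad))
    stop("zero-variance channel(s): ",
         paste(sets[[1]]$channel_names[bad], collapse = ", "))
  lapply(sets, function(es) {
    for (ch in seq_len(n_ch)) es$data[, ch, ] <- (es$data[, ch, ] - mu[ch]) / sdv[ch]
    es
  })
}
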