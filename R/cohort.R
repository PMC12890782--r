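#' Build the synthetic longitudinal cohort
#'
#' Creates the full study skeleton: participant roster (three groups),
#' per-visit behavioural sessions run under the adaptive staircase (event
#' tables are realized eagerly, they are cheap), subject-level ground-truth
#' parameters, and deterministic per-visit seeds from which the EEG of any
#' visit can be (re)generated on demand with [simulate_visit_epochs()] or
#' [simulate_visit_recording()]. Keeping the EEG lazy means a 163 x 3-visit
#' cohort never has to be held in memory at once.
#'
#' @param config a [generator_config()].
#' @return object of class `resdyn_cohort`: list with `config`, `participants`
#'   (pid, group, eigenvalue and RT subject offsets), `visits` (pid, group,
#'   age, seeds), `events` (named list of event tables, key `"pid@age"`),
#'   and `mixing` (channel weight matrix).
#' @export
build_cohort <- function(config = generator_config()) {
  groups <- rep(names(config$n_per_group), config$n_per_group)
  n <- length(groups)
  pid <- sprintf("P%03d", seq_len(n))
  seeds <- child_seeds(config$seed, 3L + 2L * n * length(config$ages) + n)
  mixing <- make_mixing(config$n_channels, seeds[1])
  set.seed(seeds[2])
  subj_eig <- rnorm(n, 0, config$subject_sd)           # persists across visits
  set.seed(seeds[3])
  subj_rt <- rnorm(n, 0, config$observer$rt_subject_sd)
  participants <- data.frame(pid = pid, group = groups,
                             eig_offset = subj_eig, rt_offset = subj_rt,
                             stringsAsFactors = FALSE)
  visits <- expand.grid(pid = pid, age = config$ages, stringsAsFactors = FALSE)
  visits <- visits[order(visits$pid, visits$age), ]
  visits$group <- participants$group[match(visits$pid, pid)]
  nv <- nrow(visits)
  visits$behavior_seed <- seeds[3 + seq_len(nv)]
  visits$eeg_seed <- seeds[3 + nv + seq_len(nv)]
  rownames(visits) <- NULL

  events <- vector("list", nv)
  names(events) <- paste0(visits$pid, "@", visits$age)
  epoch_times <- epoch_time_grid(config$analysis_rate)
  for (i in seq_len(nv)) {
    p <- match(visits$pid[i], pid)
    lam <- eigenvalue_profile(epoch_times, visits$age[i], visits$group[i],
                              rep(subj_eig[p], 2), config)
    events[[i]] <- simulate_behavior_session(
      visits$age[i], visits$group[i], config, seed = visits$behavior_seed[i],
      lambda_mean = mean(lam[1, ]), subject_rt_offset = subj_rt[p])
  }
  structure(list(config = config, participants = participants, visits = visits,
                 events = events, mixing = mixing),
            class = "resdyn_cohort")
}

#' @export
print.resdyn_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$participants), "participants (",
      paste(names(x$config$n_per_group), x$config$n_per_group,
            sep = "=", collapse = ", "),
      ") x ages", paste(x$config$ages, collapse = "/"), "\n")
  invisible(x)
}

# The fixed 2 s epoch grid: 80 samples at 40 Hz, half-open [-1, 1).
epoch_time_grid <- function(sfreq = 40, tmin = -1, tmax = 1)
  seq(tmin, tmax - 1 / sfreq, by = 1 / sfreq)

#' Ground-truth eigenvalue trajectories for a visit
#'
#' @param cohort a [build_cohort()] object.
#' @param pid participant id.
#' @param age visit age.
#' @param times time grid (s relative to flanker onset); defaults to the
#'   AR-window center grid the dynamics module reports on.
#' @return 2 x length(times) matrix of true moduli.
#' @export
true_lambda <- function(cohort, pid, age, times = ar_window_centers()) {
  p <- match(pid, cohort$participants$pid)
  if (is.na(p)) stop("unknown participant id: ", pid)
  eigenvalue_profile(times, age, cohort$participants$group[p],
                     rep(cohort$participants$eig_offset[p], 2), cohort$config)
}

# Internal: simulate the latent content of every test trial of a visit.
# Returns list(lat = n x 2 x Lmax array with template, resid = pure residual,
# r_idx = response sample offsets, keep = per-trial series length).
visit_latents <- function(cohort, pid, age) {
  cfg <- cohort$config
  v <- cohort$visits[cohort$visits$pid == pid & cohort$visits$age == age, ]
  if (nrow(v) != 1) stop("unknown visit ", pid, "@", age)
  ev <- cohort$events[[paste0(pid, "@", age)]]
  ev <- ev[ev$phase == "test", ]
  fs <- cfg$analysis_rate
  r_idx <- round(ev$rt_s * fs)                       # response sample offset
  len <- pmax(80L, r_idx + 80L)                      # spans [-1, rt+1)
  Lmax <- max(len)
  times <- -1 + (seq_len(Lmax) - 1) / fs
  p <- match(pid, cohort$participants$pid)
  lam <- eigenvalue_profile(times, age, v$group,
                            rep(cohort$participants$eig_offset[p], 2), cfg)
  cell <- paste0(ev$condition, "_", ifelse(ev$correct == 1, "correct", "error"))
  set.seed(v$eeg_seed)
  X <- simulate_trial_latent(lam, times,
                             templates = lapply(cell, function(cl) cfg$erp_templates[[cl]]),
                             rt_s = r_idx / fs, n = nrow(ev),
                             Q = cfg$innovation_cov, x0_sd = cfg$x0_sd,
                             rotation_angle = cfg$rotation_angle)
  list(lat = X, resid = attr(X, "residual"), r_idx = r_idx, len = len,
       times = times, events = ev, cell = cell)
}

#' Generate the epoched EEG of one visit directly on the analysis grid
#'
#' Fast path for cohort-scale analyses: latent AR trials (with condition
#' templates) are mixed into channel space and cut into the flanker-aligned
#' and response-aligned 80-sample epochs, with white sensor noise added per
#' channel. Deterministic given the cohort (per-visit seeds).
#'
#' @param cohort a [build_cohort()] object.
#' @param pid,age visit key.
#' @param keep_truth if `TRUE`, attach the noise-free latent residual epochs
#'   as attribute `"latent_residual"` (flanker alignment) for recovery tests.
#' @return list with elements `flanker` and `response`, each an epoch set as
#'   produced by [epoch()] (trials x channels x 80 array, times, labels).
#' @export
simulate_visit_epochs <- function(cohort, pid, age, keep_truth = FALSE) {
  cfg <- cohort$config
  vl <- visit_latents(cohort, pid, age)
  n <- dim(vl$lat)[1]; n_ch <- cfg$n_channels
  cut_align <- function(offsets) {
    lat <- array(0, c(n, 2, 80))
    for (i in seq_len(n)) lat[i, , ] <- vl$lat[i, , offsets[i] + (1:80)]
    chm <- cohort$mixing %*% rbind(as.vector(lat[, 1, ]), as.vector(lat[, 2, ]))
    dat <- array(0, c(n, n_ch, 80))
    for (c2 in seq_len(n_ch)) dat[, c2, ] <- matrix(chm[c2, ], n, 80)
    dat + array(rnorm(n * n_ch * 80, 0, cfg$sensor_noise_sd), c(n, n_ch, 80))
  }
  info <- data.frame(trial_index = vl$events$trial_index,
                     condition = vl$events$condition,
                     correct = vl$events$correct, rt_s = vl$events$rt_s,
                     cell = vl$cell, stringsAsFactors = FALSE)
  times <- epoch_time_grid(cfg$analysis_rate)
  ch_names <- sprintf("ch%02d", seq_len(n_ch))
  out <- list(
    flanker = epoch_set(cut_align(rep(0L, n)), times, "flanker", info,
                        cfg$analysis_rate, ch_names),
    response = epoch_set(cut_align(vl$r_idx), times, "response", info,
                         cfg$analysis_rate, ch_names))
  if (keep_truth) {
    lat_res <- array(0, c(n, 2, 80))
    for (d in 1:2) lat_res[, d, ] <- vl$resid[, d, 1:80]
    attr(out, "latent_residual") <- lat_res
  }
  out
}

#' Generate a continuous multichannel recording for one visit
#'
#' Full-rate path: the 40 Hz latent trials are band-limited-interpolated to
#' the acquisition rate, mixed into channel space and placed into a
#' continuous recording ([mix_to_channels()]) so the complete preprocessing
#' chain (filters, downsampling, epoching) can be exercised. Intended for
#' small cohorts; the epochs-mode path is the cohort-scale default.
#'
#' @inheritParams simulate_visit_epochs
#' @return list(recording = [raw_recording()], events = event table of the
#'   visit with practice rows retained).
#' @export
simulate_visit_recording <- function(cohort, pid, age) {
  cfg <- cohort$config
  vl <- visit_latents(cohort, pid, age)
  fs_hi <- cfg$sample_rate; fs_lo <- cfg$analysis_rate
  up <- fs_hi / fs_lo
  n <- dim(vl$lat)[1]
  lat_hi <- vector("list", n)
  for (i in seq_len(n)) {
    L <- vl$len[i]
    t_lo <- vl$times[seq_len(L)]
    t_hi <- seq(t_lo[1], t_lo[L], by = 1 / fs_hi)
    lat_hi[[i]] <- rbind(approx(t_lo, vl$lat[i, 1, seq_len(L)], t_hi)$y,
                         approx(t_lo, vl$lat[i, 2, seq_len(L)], t_hi)$y)
  }
  ev <- vl$events
  starts <- ev$onset_s - 1                           # trial span starts at flanker - 1 s
  duration <- max(ev$onset_s + ev$rt_s) + 2
  rec <- mix_to_channels(lat_hi, starts, cohort$mixing, cfg$sensor_noise_sd,
                         fs_hi, duration,
                         channel_names = sprintf("ch%02d", seq_len(cfg$n_channels)))
  list(recording = rec, events = cohort$events[[paste0(pid, "@", age)]])
}

#' @importFrom stats approx
NULL
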