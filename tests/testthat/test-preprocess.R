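tone_recording <- function(freq, fs = 500, dur = 10, n_ch = 2) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  raw_recording(matrix(rep(sin(2 * pi * freq * t), each = n_ch), n_ch), fs)
}

test_that("filter chain attenuates 50 Hz, kills DC, passes 10 Hz", {
  fs <- 500; core <- 1001:4000   # discard 2 s of edges
  y50 <- filter_chain(tone_recording(50))$data[1, ]
  expect_lt(sqrt(mean(y50[core]^2)) / sqrt(0.5), 0.05)
  ydc <- filter_chain(raw_recording(matrix(1, 2, 5000), fs))$data[1, ]
  expect_lt(max(abs(ydc[core])), 1e-2)
  y10 <- filter_chain(tone_recording(10))$data[1, ]
  gain <- sqrt(mean(y10[core]^2)) / sqrt(0.5)
  expect_gt(gain, 0.9); expect_lt(gain, 1.1)
})

test_that("filter chain refuses too-low sampling rates, naming the corner", {
  expect_error(filter_chain(tone_recording(10, fs = 30)), "notch")
})

test_that("filter chain is linear", {
  set.seed(5)
  x <- matrix(rnorm(2 * 2000), 2, 2000)
  y <- matrix(rnorm(2 * 2000), 2, 2000)
  fs <- 500
  fx <- filter_chain(raw_recording(x, fs))$data
  fy <- filter_chain(raw_recording(y, fs))$data
  fxy <- filter_chain(raw_recording(2 * x - 3 * y, fs))$data
  expect_equal(fxy, 2 * fx - 3 * fy, tolerance = 1e-6)
})

test_that("downsampling 500 -> 40 Hz keeps duration and tone amplitude", {
  d <- downsample(tone_recording(5), 40)
  expect_equal(d$sfreq, 40)
  expect_equal(ncol(d$data), 400)                  # 10 s x 40 Hz
  core <- 41:360
  expect_equal(sqrt(mean(d$data[1, core]^2)) / sqrt(0.5), 1, tolerance = 0.1)
  # idempotence at the target rate
  expect_identical(downsample(d, 40), d)
  expect_error(downsample(d, 80), "exceeds")
})

test_that("epoching does 0-based half-open index arithmetic", {
  fs <- 40
  # channel value = 0-based sample index, so epochs reveal which samples were cut
  rec <- raw_recording(matrix(0:799, 1, 800, byrow = TRUE), fs)
  ev <- data.frame(onset_s = c(10.0, 0.5), response_onset_s = c(10.4, 0.9),
                   condition = "congruent", correct = 1L)
  es <- epoch(rec, ev, "flanker")
  expect_equal(dim(es$data), c(1, 1, 80))          # event at 0.5 s dropped
  expect_equal(attr(es, "n_dropped"), 1L)
  expect_equal(as.vector(es$data[1, 1, ]), 360:439)
  expect_equal(es$times[1], -1)
  expect_equal(es$times[80], 0.975)
  er <- epoch(rec, ev, "response")
  expect_equal(as.vector(er$data[1, 1, ]), 376:455)
})

test_that("epoch rows stay aligned with the event table over random schedules", {
  set.seed(21)
  fs <- 40
  for (rep in 1:5) {
    n_ev <- sample(3:8, 1)
    onsets <- sort(5 + cumsum(runif(n_ev, 2.5, 4)))
    rec_len <- ceiling((max(onsets) + 3) * fs)
    # encode the event id at its own onset sample
    x <- matrix(0, 1, rec_len)
    x[1, round(onsets * fs) + 1] <- seq_len(n_ev) * 100
    ev <- data.frame(onset_s = onsets, response_onset_s = onsets + 0.4,
                     condition = "congruent", correct = 1L)
    es <- epoch(raw_recording(x, fs), ev, "flanker")
    for (i in seq_len(n_ev))
      expect_equal(es$data[i, 1, 41], i * 100)     # time 0 sample carries the id
  }
})

test_that("z-scoring standardizes pooled channels and is affine-invariant", {
  co <- small_cohort()
  ep <- simulate_visit_epochs(co, "P001", 12)
  z <- zscore_channels(ep$flanker, ep$response)
  pooled <- c(z[[1]]$data[, 3, ], z[[2]]$data[, 3, ])
  expect_equal(mean(pooled), 0, tolerance = 1e-10)
  expect_equal(sd(pooled), 1, tolerance = 1e-10)
  # affine transform of a channel changes nothing after z-scoring
  ep2 <- ep
  ep2$flanker$data[, 3, ] <- 5 * ep2$flanker$data[, 3, ] + 2
  ep2$response$data[, 3, ] <- 5 * ep2$response$data[, 3, ] + 2
  z2 <- zscore_channels(ep2$flanker, ep2$response)
  expect_equal(z2[[1]]$data[, 3, ], z[[1]]$data[, 3, ], tolerance = 1e-8)
  # channels on different scales end with equal variance
  expect_equal(var(c(z2[[1]]$data[, 1, ], z2[[2]]$data[, 1, ])),
               var(c(z2[[1]]$data[, 3, ], z2[[2]]$data[, 3, ])), tolerance = 1e-9)
})

test_that("zero-variance channels are reported by name", {
  ep <- simulate_visit_epochs(small_cohort(), "P002", 12)
  ep$flanker$data[, 2, ] <- 7
  ep$response$data[, 2, ] <- 7
  expect_error(zscore_channels(ep$flanker, ep$response), "ch02")
})

test_that("the continuous path reproduces the analysis-grid template content", {
  cfg <- noiseless_config(n_per_group = c(NIG = 1, FCG = 1, CAUG = 1),
                          ages = 12, n_test_trials = 30, n_practice_trials = 5,
                          seed = 13)
  co <- build_cohort(cfg)
  vr <- simulate_visit_recording(co, "P001", 12)
  d <- downsample(filter_chain(vr$recording), 40)
  ev <- vr$events[vr$events$phase == "test", ]
  epf <- epoch(d, ev, "flanker")
  direct <- simulate_visit_epochs(co, "P001", 12)
  # compare trial-wise channel signals where the template lives (post-stimulus);
  # the 1 Hz high-pass strips some near-DC content of the wider bumps, so the
  # two paths agree strongly but not perfectly
  sel <- epf$times > 0 & epf$times < 0.6
  a <- as.vector(epf$data[, , sel])
  b <- as.vector(direct$flanker$data[, , sel])
  expect_gt(cor(a, b), 0.9)
})
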