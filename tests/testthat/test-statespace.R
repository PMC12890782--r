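make_epochs <- function(dat, conds, corr, alignment = "flanker", sfreq = 40) {
  info <- data.frame(condition = conds, correct = corr,
                     cell = paste0(conds, "_", ifelse(corr == 1, "correct", "error")))
  epoch_set(dat, seq(-1, 1 - 1 / sfreq, by = 1 / sfreq), alignment, info, sfreq,
            sprintf("ch%02d", seq_len(dim(dat)[2])))
}

test_that("cell ERPs average trials and flag scarce cells", {
  set.seed(1)
  dat <- array(rnorm(4 * 3 * 80), c(4, 3, 80))
  dat[2, , ] <- dat[1, , ]                       # two identical trials
  ep <- make_epochs(dat, c("congruent", "congruent", "incongruent", "incongruent"),
                    c(1, 1, 1, 0))
  erps <- condition_erps(list(flanker = ep, response = ep), min_trials = 2)
  expect_equal(erps$erp$flanker$congruent_correct, dat[1, , ])
  expect_equal(erps$counts["congruent_correct", "flanker"], 2L)
  # single-trial cells: ERP equals the trial but the cell is unusable
  expect_equal(erps$erp$flanker$incongruent_error, dat[4, , ])
  expect_false(erps$usable["incongruent_error", "flanker"])
  expect_false(erps$usable["congruent_error", "flanker"])   # zero trials
})

test_that("a participant with no usable cells is excluded with an error", {
  dat <- array(rnorm(2 * 2 * 80), c(2, 2, 80))
  ep <- make_epochs(dat, c("congruent", "incongruent"), c(1, 1))
  expect_error(condition_erps(list(flanker = ep, response = ep), min_trials = 6),
               "excluded")
})

test_that("grand matrix has the documented block structure and symmetry", {
  co <- small_cohort()
  erps <- lapply(seq_len(nrow(co$visits))[1:6], function(i) {
    e <- simulate_visit_epochs(co, co$visits$pid[i], co$visits$age[i])
    z <- zscore_channels(e$flanker, e$response)
    condition_erps(list(flanker = z[[1]], response = z[[2]]))
  })
  G <- build_grand_matrix(erps)
  expect_equal(dim(G), c(56, 2 * 4 * 80))        # alignment x condition x time
  bi <- attr(G, "block_index")
  expect_equal(unique(bi$alignment), c("flanker", "response"))
  # permuting participants leaves the average unchanged
  G2 <- build_grand_matrix(erps[c(4, 2, 6, 1, 3, 5)])
  expect_equal(G, G2, ignore_attr = TRUE)
  # single participant, single usable cell -> matrix is that ERP block
  one <- erps[[1]]
  one$usable[] <- FALSE; one$usable["congruent_correct", "flanker"] <- TRUE
  G1 <- build_grand_matrix(list(one))
  expect_equal(unname(G1), unname(one$erp$flanker$congruent_correct),
               ignore_attr = TRUE)
})

test_that("PCA space: orthonormal weights, normalized variance, rank checks", {
  # grand matrix built from exactly two orthogonal channel patterns
  p1 <- c(1, 0, 0, 0); p2 <- c(0, 1, 0, 0)
  G <- outer(p1, sin(seq(0, 6, length.out = 100))) +
       outer(p2, cos(seq(0, 9, length.out = 100)))
  rownames(G) <- paste0("ch", 1:4)
  sp <- pca_space(G)
  expect_equal(sum(sp$explained_var[1:2]), 1, tolerance = 1e-12)
  expect_equal(sum(sp$explained_var), 1, tolerance = 1e-12)
  expect_equal(crossprod(sp$weights), diag(1, 2), tolerance = 1e-12)
  expect_error(pca_space(outer(p1, sin(1:50))), "rank")
})

test_that("projection is the fixed rigid map and is linear", {
  co <- small_cohort()
  e <- simulate_visit_epochs(co, "P003", 16)
  z <- zscore_channels(e$flanker, e$response)
  erps <- condition_erps(list(flanker = z[[1]], response = z[[2]]))
  sp <- pca_space(build_grand_matrix(list(erps)))
  # epoch equal to weight column 1 broadcast over time -> latent (1, 0)
  dat <- array(0, c(1, 56, 80))
  dat[1, , ] <- matrix(sp$weights[, 1], 56, 80)
  ep1 <- make_epochs(dat, "congruent", 1)
  lat <- project_trials(ep1, sp)
  expect_equal(as.vector(lat$data[1, 1, ]), rep(1, 80), tolerance = 1e-10)
  expect_equal(as.vector(lat$data[1, 2, ]), rep(0, 80), tolerance = 1e-10)
  # linearity
  la <- project_trials(z[[1]], sp)$data
  zb <- z[[1]]; zb$data <- 3 * zb$data
  expect_equal(project_trials(zb, sp)$data, 3 * la, tolerance = 1e-10)
  # channel mismatch is an error
  bad <- z[[1]]; bad$channel_names <- rev(bad$channel_names)
  expect_error(project_trials(bad, sp), "mismatch")
})

test_that("residuals subtract cell means: zero-mean, hand arithmetic", {
  a <- matrix(rnorm(2 * 80), 2, 80); b <- matrix(rnorm(2 * 80), 2, 80)
  dat <- array(0, c(2, 2, 80)); dat[1, , ] <- a; dat[2, , ] <- b
  lat <- list(data = dat, times = seq(-1, 0.975, 1 / 40), alignment = "flanker",
              info = data.frame(cell = c("congruent_correct", "congruent_correct")))
  res <- residuals_latent(lat, min_trials = 2)
  expect_equal(res$data[1, , ], (a - b) / 2, tolerance = 1e-12)
  expect_equal(res$data[2, , ], (b - a) / 2, tolerance = 1e-12)
  # single-trial cell with min_trials = 1 -> residual identically zero
  lat1 <- lat; lat1$data <- dat[1, , , drop = FALSE]
  lat1$info <- lat$info[1, , drop = FALSE]
  res1 <- residuals_latent(lat1, min_trials = 1)
  expect_true(all(abs(res1$data) < 1e-12))
  # cohort data: per-cell means vanish at every component and time
  co <- small_cohort()
  e <- simulate_visit_epochs(co, "P005", 21)
  z <- zscore_channels(e$flanker, e$response)
  erps <- condition_erps(list(flanker = z[[1]], response = z[[2]]))
  sp <- pca_space(build_grand_matrix(list(erps)))
  rr <- residuals_latent(project_trials(z[[1]], sp))
  for (cl in unique(rr$info$cell)) {
    idx <- rr$info$cell == cl
    cm <- apply(rr$data[idx, , , drop = FALSE], c(2, 3), mean)
    expect_lt(max(abs(cm)), 1e-10)
  }
})

test_that("condition means in channel vs latent space are equivalent", {
  co <- small_cohort()
  e <- simulate_visit_epochs(co, "P002", 16)
  z <- zscore_channels(e$flanker, e$response)
  erps <- condition_erps(list(flanker = z[[1]], response = z[[2]]))
  sp <- pca_space(build_grand_matrix(list(erps)))
  lat <- project_trials(z[[1]], sp)
  for (cl in CELLS_usable <- names(which(erps$usable[, "flanker"]))) {
    chan_mean_proj <- crossprod(sp$weights, erps$erp$flanker[[cl]])
    idx <- lat$info$cell == cl
    lat_mean <- apply(lat$data[idx, , , drop = FALSE], c(2, 3), mean)
    expect_equal(chan_mean_proj, lat_mean, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("flipping a weight column's sign leaves AR moduli unchanged", {
  co <- small_cohort()
  e <- simulate_visit_epochs(co, "P004", 12)
  z <- zscore_channels(e$flanker, e$response)
  erps <- condition_erps(list(flanker = z[[1]], response = z[[2]]))
  sp <- pca_space(build_grand_matrix(list(erps)))
  sp2 <- sp; sp2$weights[, 2] <- -sp2$weights[, 2]
  es1 <- eigen_series(fit_window_ar(residuals_latent(project_trials(z[[1]], sp))))
  es2 <- eigen_series(fit_window_ar(residuals_latent(project_trials(z[[1]], sp2))))
  expect_equal(es1$lambda1, es2$lambda1, tolerance = 1e-9)
  expect_equal(es1$lambda2, es2$lambda2, tolerance = 1e-9)
})
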