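test_that("BH rejection set equals exhaustive brute force for m <= 12", {
  set.seed(9)
  alpha <- 0.05
  # worked example: all four survive because p_(4) = 0.041 <= 0.05
  p_ex <- c(0.001, 0.008, 0.039, 0.041)
  expect_true(all(p.adjust(p_ex, "BH") < alpha))
  expect_true(all(bh_brute_force(p_ex, alpha)))
  for (rep in 1:200) {
    m <- sample(1:12, 1)
    p <- round(runif(m)^sample(1:3, 1), 3)
    expect_identical(p.adjust(p, "BH") <= alpha, bh_brute_force(p, alpha))
  }
  expect_equal(sum(p.adjust(rep(1, 10), "BH") < alpha), 0)
})

test_that("cluster extraction is plain run-length logic", {
  t <- 1:6 / 10
  cl <- find_clusters(c(FALSE, TRUE, TRUE, TRUE, FALSE, TRUE), t)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$t_start[cl$longest], 0.2)
  expect_equal(cl$t_end[cl$longest], 0.4)
  expect_equal(cl$n_points, c(3L, 1L))
  expect_equal(nrow(find_clusters(rep(FALSE, 6), t)), 0)
  all_on <- find_clusters(rep(TRUE, 6), t)
  expect_equal(all_on$n_points, 6L)
  # averaging a constant series over any cluster returns the constant
  et <- data.frame(pid = "P1", group = "NIG", age = 12, alignment = "flanker",
                   t_center = t, lambda1 = 0.7, lambda2 = 0.7)
  ca <- cluster_average(et, "flanker", 0.2, 0.4)
  expect_equal(ca$lambda1, 0.7)
})

test_that("mixed model recovers a known group effect and the grand mean", {
  set.seed(14)
  n <- 60
  d <- expand.grid(pid = sprintf("S%02d", 1:(3 * n)), age = c(12, 16, 21))
  d$group <- factor(rep(rep(c("NIG", "FCG", "CAUG"), each = n), 3),
                    levels = c("NIG", "FCG", "CAUG"))
  d$age_f <- factor(d$age)
  subj <- rnorm(3 * n, 0, 0.03)
  d$lambda <- 0.7 + 0.1 * (d$group != "NIG") - 0.008 * (d$age - 12) +
    subj[match(d$pid, unique(d$pid))] + rnorm(nrow(d), 0, 0.02)
  f <- fit_lme(lambda ~ group * age_f + (1 + age_f | pid), d)
  fe <- lme4::fixef(f$fit)
  expect_lt(abs(fe[["groupFCG"]] - 0.1), 0.03)
  expect_true(f$anova["group", "Pr(>F)"] < 0.001)
  f0 <- fit_lme(lambda ~ 1 + (1 | pid), d)
  expect_equal(unname(lme4::fixef(f0$fit)[1]), mean(d$lambda), tolerance = 0.01)
})

test_that("timewise tests apply BH within effect x alignment and honor alpha", {
  set.seed(3)
  pid <- sprintf("S%02d", 1:30)
  grid <- expand.grid(pid = pid, age = c(12, 16, 21), alignment = "flanker",
                      t_center = (1:6) / 10, stringsAsFactors = FALSE)
  grid$group <- rep(c("NIG", "FCG", "CAUG"), 10)[match(grid$pid, pid)]
  # group effect present only at late time points
  grid$lambda1 <- 0.6 + 0.2 * (grid$group != "NIG") * (grid$t_center > 0.35) +
    rnorm(nrow(grid), 0, 0.05)
  tw <- timewise_test(grid, "lambda1", "group_age")
  expect_true(all(tw$p_fdr >= tw$p_raw))
  expect_identical(tw$significant, tw$p_fdr < 0.05)
  g <- tw[tw$effect == "group", ]
  g <- g[order(g$t_center), ]
  expect_identical(g$significant, g$t_center > 0.35)
  # permuting group labels destroys the effect
  hits <- vapply(1:5, function(k) {
    gp <- grid
    perm <- setNames(sample(grid$group[match(pid, grid$pid)]), pid)
    gp$group <- perm[gp$pid]
    sum(timewise_test(gp, "lambda1", "group_age")$significant &
          timewise_test(gp, "lambda1", "group_age")$effect == "group")
  }, numeric(1))
  expect_lt(mean(hits > 0), 0.5)
})

test_that("post hoc contrasts are Bonferroni-scaled Wald tests", {
  set.seed(6)
  d <- expand.grid(pid = sprintf("S%02d", 1:45), age = c(12, 16, 21))
  d$group <- factor(rep(c("NIG", "FCG", "CAUG"), 15)[match(d$pid, unique(d$pid))],
                    levels = c("NIG", "FCG", "CAUG"))
  d$age_f <- factor(d$age)
  d$lambda <- 0.7 + 0.08 * (d$group != "NIG") + rnorm(nrow(d), 0, 0.08)
  f <- fit_lme(lambda ~ group * age_f + (1 + age_f | pid), d)
  ph <- posthoc_contrasts(f, "group")
  expect_equal(nrow(ph), 3)
  raw <- as.data.frame(summary(emmeans::contrast(
    emmeans::emmeans(f$fit, "group"), method = "pairwise", adjust = "none")))
  expect_equal(ph$p.value, pmin(raw$p.value * 3, 1), tolerance = 1e-8)
  expect_true(all(ph$p.value <= 1))
  expect_error(posthoc_contrasts(f, "sex"), "not in the fitted model")
})

test_that("mediation: identities, degenerate chain, known indirect effect", {
  set.seed(44)
  # random data: c = c' + ab holds exactly
  x <- rnorm(80); m <- rnorm(80); y <- rnorm(80)
  md <- mediate(x, m, y, n_boot = 200, seed = 1)
  expect_equal(md$estimates[["c"]],
               md$estimates[["cprime"]] + md$estimates[["ab"]], tolerance = 1e-12)
  # deterministic chain y = m = x: full mediation
  xx <- seq(-1, 1, length.out = 20)
  md2 <- mediate(xx, xx, xx, n_boot = 50, seed = 1)
  expect_equal(md2$estimates[["cprime"]], 0)
  expect_equal(md2$estimates[["ab"]], md2$estimates[["c"]], tolerance = 1e-12)
  # a = 0.5, b = 0.4 with noise: ab near 0.2 and inside its CI
  x <- rnorm(500); m <- 0.5 * x + rnorm(500, 0, 0.5)
  y <- 0.4 * m + 0.1 * x + rnorm(500, 0, 0.5)
  md3 <- mediate(x, m, y, n_boot = 1000, seed = 7)
  expect_equal(md3$estimates[["ab"]], 0.2, tolerance = 0.05)
  expect_true(md3$ci["ab", 1] <= 0.2 && 0.2 <= md3$ci["ab", 2])
  # determinism and input validation
  md4 <- mediate(x, m, y, n_boot = 1000, seed = 7)
  expect_identical(md3$ci, md4$ci)
  expect_error(mediate(x[1:5], m[1:5], y[1:5]), "at least 10")
  expect_error(mediate(rep(1, 20), m[1:20], y[1:20]), "zero variance")
})
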