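#' Fit a mixed-effects model with graceful random-structure fallback
#'
#' REML fit via lmerTest (Satterthwaite degrees of freedom for F-tests). If
#' the requested random structure fails to converge, progressively simpler
#' structures from `fallbacks` are tried (the documented order is
#' interaction slopes -> slopes -> intercept-only); the structure actually
#' used is recorded. Singular fits (variance components estimated at zero)
#' are accepted — with three visits per participant, maximal slope
#' structures are routinely singular.
#'
#' @param formula full lmer formula (fixed + random terms).
#' @param data model data.
#' @param fallbacks character vector of replacement random-effects terms,
#'   e.g. `c("(1 + age_f | pid)", "(1 | pid)")`, tried in order.
#' @return list: `fit` (lmerModLmerTest), `anova` (type III table with
#'   Satterthwaite df), `formula_used`, `note`.
#' @export
fit_lme <- function(formula, data, fallbacks = c("(1 | pid)")) {
  fixed_part <- deparse1(lme4::nobars(formula))
  tries <- c(deparse1(formula),
             paste(fixed_part, "+", fallbacks))
  note <- NULL
  for (ft in unique(tries)) {
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lmerTest::lmer(as.formula(ft), data = data, REML = TRUE,
                       control = lme4::lmerControl(calc.derivs = FALSE,
                                                   check.conv.singular = "ignore")))),
      error = function(e) e)
    if (!inherits(fit, "error")) {
      conv <- fit@optinfo$conv$opt
      if (is.null(conv) || conv == 0) {
        if (ft != tries[1]) note <- paste("random structure simplified to", ft)
        an <- suppressMessages(anova(fit, type = 3, ddf = "Satterthwaite"))
        return(list(fit = fit, anova = an, formula_used = ft, note = note))
      }
    }
  }
  stop("mixed model failed to converge even with intercept-only random effects")
}

#' Model formulas of the study design
#'
#' The three mixed-model structures used throughout: the behavioural model
#' (Group x Condition x Age with maximal within-participant random slopes),
#' the eigenvalue model (Group x Age with a random age slope), and the
#' eigenvalue-BIS coupling model (BIS main effect plus its interactions with
#' Group and Age; note the latter has no Group main effect by design). Age
#' enters as a 3-level factor; the reference group is NIG.
#'
#' @param response name of the response column.
#' @return an lmer formula.
#' @export
behavior_formula <- function(response)
  as.formula(paste(response, "~ group * condition * age_f",
                   "+ (1 + condition * age_f | pid)"))

#' @rdname behavior_formula
#' @export
eigen_formula <- function(response)
  as.formula(paste(response, "~ group * age_f + (1 + age_f | pid)"))

#' @rdname behavior_formula
#' @export
eigen_bis_formula <- function(response)
  as.formula(paste(response, "~ bis + age_f + group:age_f + bis:age_f",
                   "+ bis:group + bis:group:age_f + (1 + age_f | pid)"))

#' Time-resolved mixed-model tests with FDR correction
#'
#' Fits a mixed model at every time point of the eigenvalue series and
#' corrects the per-effect p-values for multiple comparisons over time with
#' Benjamini-Hochberg, separately within each effect x alignment family.
#' Time points with more than `max_missing` missing values are excluded.
#'
#' @param eigen_table long table: pid, group, age, alignment, t_center and the
#'   response column (plus `bis` for `model = "bis"`).
#' @param response "lambda1" or "lambda2".
#' @param model "group_age" (eigenvalue ~ Group*Age, random intercept + age
#'   slope) or "bis" (the BIS-coupling model).
#' @param alpha significance level applied to adjusted p-values.
#' @param max_missing maximum tolerated fraction of missing responses per
#'   time point.
#' @return data.frame: alignment, effect, t_center, F, df1, df2, p_raw,
#'   p_fdr, significant.
#' @export
timewise_test <- function(eigen_table, response = "lambda1",
                          model = c("group_age", "bis"), alpha = 0.05,
                          max_missing = 0.2) {
  model <- match.arg(model)
  fml <- if (model == "group_age") eigen_formula(response) else eigen_bis_formula(response)
  out <- list()
  for (al in unique(eigen_table$alignment)) {
    d_al <- eigen_table[eigen_table$alignment == al, ]
    d_al$age_f <- factor(d_al$age)
    d_al$group <- factor(d_al$group, levels = c("NIG", "FCG", "CAUG"))
    for (tc in sort(unique(d_al$t_center))) {
      d <- d_al[d_al$t_center == tc, ]
      if (mean(is.na(d[[response]])) > max_missing) next
      d <- d[!is.na(d[[response]]), ]
      f <- fit_lme(fml, d)
      an <- f$anova
      out[[length(out) + 1L]] <- data.frame(
        alignment = al, effect = rownames(an), t_center = tc,
        F = an[, "F value"], df1 = an[, "NumDF"], df2 = an[, "DenDF"],
        p_raw = an[, "Pr(>F)"], stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$p_fdr <- NA_real_
  for (al in unique(res$alignment)) for (ef in unique(res$effect)) {
    idx <- res$alignment == al & res$effect == ef
    res$p_fdr[idx] <- p.adjust(res$p_raw[idx], method = "BH")
  }
  res$significant <- res$p_fdr < alpha
  res
}

#' Contiguous significant-time clusters and within-cluster averages
#'
#' Finds maximal runs of contiguous significant time points, sorts them by
#' length (longest flagged), and averages a per-participant eigenvalue series
#' within a chosen cluster.
#'
#' @param mask logical vector over the time grid.
#' @param times the time grid (s).
#' @return data.frame of clusters (`t_start`, `t_end`, `n_points`,
#'   `longest`), zero rows if the mask is empty.
#' @export
find_clusters <- function(mask, times) {
  stopifnot(length(mask) == length(times))
  r <- rle(as.logical(mask) & !is.na(mask))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (!length(keep))
    return(data.frame(t_start = numeric(0), t_end = numeric(0),
                      n_points = integer(0), longest = logical(0)))
  cl <- data.frame(t_start = times[starts[keep]], t_end = times[ends[keep]],
                   n_points = r$lengths[keep])
  cl <- cl[order(-cl$n_points, cl$t_start), ]
  cl$longest <- seq_len(nrow(cl)) == 1L
  rownames(cl) <- NULL
  cl
}

#' @rdname find_clusters
#' @param eigen_table long eigenvalue table (pid, age, group, alignment,
#'   t_center, lambda1, lambda2).
#' @param alignment alignment to average within.
#' @param t_start,t_end cluster window (inclusive).
#' @return for `cluster_average`: per participant-visit means of lambda1 and
#'   lambda2 over the cluster's time points.
#' @export
cluster_average <- function(eigen_table, alignment, t_start, t_end) {
  d <- eigen_table[eigen_table$alignment == alignment &
                     eigen_table$t_center >= t_start - 1e-9 &
                     eigen_table$t_center <= t_end + 1e-9, ]
  agg <- aggregate(d[c("lambda1", "lambda2")],
                   by = d[c("pid", "group", "age")],
                   FUN = mean, na.rm = TRUE)
  agg$alignment <- alignment
  agg
}

#' Bonferroni-corrected pairwise contrasts
#'
#' Wald contrasts between all level pairs of a factor (optionally within the
#' levels of another factor), via emmeans on the fitted mixed model;
#' p-values are multiplied by the number of comparisons and capped at 1.
#'
#' @param fit result of [fit_lme()] (or an lmerModLmerTest).
#' @param factor_name factor whose levels are compared.
#' @param by optional conditioning factor name.
#' @return data.frame of contrasts with Bonferroni-adjusted p-values.
#' @export
posthoc_contrasts <- function(fit, factor_name, by = NULL) {
  if (is.list(fit) && !is.null(fit$fit)) fit <- fit$fit
  if (!factor_name %in% all.vars(formula(fit)))
    stop("factor ", factor_name, " is not in the fitted model")
  em <- suppressMessages(emmeans::emmeans(fit, specs = factor_name, by = by,
                                          lmer.df = "satterthwaite"))
  as.data.frame(summary(suppressMessages(
    emmeans::contrast(em, method = "pairwise", adjust = "bonferroni"))))
}

#' Bootstrap mediation with BCa confidence intervals
#'
#' Simple three-variable mediation: OLS path coefficients
#' \eqn{m = a x}, \eqn{y = c' x + b m} (with intercepts), indirect effect
#' \eqn{ab}, total effect \eqn{c = c' + ab} (an exact identity for OLS point
#' estimates). Uncertainty by nonparametric case resampling; intervals are
#' bias-corrected and accelerated (bias from the bootstrap proportion below
#' the point estimate, acceleration from a jackknife).
#'
#' @param x exposure (continuous age, or 0/1 institutionalization).
#' @param m mediator (cluster-averaged eigenvalue).
#' @param y outcome (BIS).
#' @param n_boot bootstrap iterations.
#' @param seed integer seed (fixed seed gives identical CIs).
#' @param conf confidence level.
#' @return object of class `resdyn_mediation`: `estimates` (a, b, cprime,
#'   ab, c), `ci` (rows = paths), `n_boot`, `seed`.
#' @export
mediate <- function(x, m, y, n_boot = 5000, seed = 1L, conf = 0.95) {
  ok <- complete.cases(x, m, y)
  x <- x[ok]; m <- m[ok]; y <- y[ok]
  n <- length(x)
  if (n < 10) stop("mediation needs at least 10 complete cases")
  if (var(x) == 0 || var(m) == 0) stop("zero variance in exposure or mediator")
  paths <- function(x, m, y) {
    xc <- x - mean(x); mc <- m - mean(m); yc <- y - mean(y)
    vx <- sum(xc^2); vm <- sum(mc^2); vxm <- sum(xc * mc)
    a <- vxm / vx
    det <- vx * vm - vxm^2
    if (det <= 1e-12 * vx * vm) {
      # exposure and mediator collinear: the outcome model is unidentified,
      # so the shared effect is attributed to the mediator (full mediation)
      b <- sum(mc * yc) / vm; cp <- 0
    } else {
      cp <- (vm * sum(xc * yc) - vxm * sum(mc * yc)) / det
      b <- (vx * sum(mc * yc) - vxm * sum(xc * yc)) / det
    }
    c(a = a, b = b, cprime = cp, ab = a * b, c = sum(xc * yc) / vx)
  }
  est <- paths(x, m, y)
  set.seed(seed)
  boot <- matrix(NA_real_, n_boot, 5, dimnames = list(NULL, names(est)))
  for (i in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    boot[i, ] <- tryCatch(paths(x[idx], m[idx], y[idx]),
                          error = function(e) rep(NA_real_, 5))
  }
  jack <- matrix(NA_real_, n, 5)
  for (i in seq_len(n)) jack[i, ] <- paths(x[-i], m[-i], y[-i])
  alpha <- (1 - conf) / 2
  ci <- matrix(NA_real_, 5, 2, dimnames = list(names(est), c("lower", "upper")))
  for (k in 1:5) {
    bk <- boot[, k]; bk <- bk[is.finite(bk)]
    B <- length(bk)
    p0 <- min(max(mean(bk < est[k]), 1 / (B + 1)), B / (B + 1))
    z0 <- qnorm(p0)
    jm <- mean(jack[, k]); d <- jm - jack[, k]
    denom <- 6 * sum(d^2)^1.5
    acc <- if (denom > 0) sum(d^3) / denom else 0
    zl <- qnorm(alpha); zu <- qnorm(1 - alpha)
    a1 <- pnorm(z0 + (z0 + zl) / (1 - acc * (z0 + zl)))
    a2 <- pnorm(z0 + (z0 + zu) / (1 - acc * (z0 + zu)))
    ci[k, ] <- quantile(bk, c(a1, a2), names = FALSE, type = 7)
  }
  structure(list(estimates = est, ci = ci, n_boot = n_boot, seed = seed,
                 conf = conf, n = n),
            class = "resdyn_mediation")
}

#' @export
print.resdyn_mediation <- function(x, ...) {
  cat(sprintf("Mediation (n = %d, %d bootstrap draws, %.0f%% BCa CIs):\n",
              x$n, x$n_boot, 100 * x$conf))
  tab <- cbind(estimate = x$estimates, x$ci)
  print(round(tab, 4))
  invisible(x)
}
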