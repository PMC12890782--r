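#' Per-condition accuracy and reaction time for one session
#'
#' Test trials only. Accuracy is the proportion of correct responses per
#' condition; mean RT is computed over correct trials only (standard Flanker
#' scoring). Conditions with zero trials yield missing cells.
#'
#' @param events event table from [simulate_behavior_session()] (or the same
#'   dialect read from disk).
#' @return data.frame: condition, n_trials, accuracy, rt_mean_s.
#' @export
summarize_behavior <- function(events) {
  ev <- events[events$phase == "test", , drop = FALSE]
  conds <- c("congruent", "incongruent")
  out <- data.frame(condition = conds, n_trials = NA_integer_,
                    accuracy = NA_real_, rt_mean_s = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(conds)) {
    d <- ev[ev$condition == conds[i], , drop = FALSE]
    if (nrow(d) == 0) next
    out$n_trials[i] <- nrow(d)
    out$accuracy[i] <- mean(d$correct)
    ok <- d$correct == 1
    out$rt_mean_s[i] <- if (any(ok)) mean(d$rt_s[ok]) else NA_real_
  }
  out
}

#' Behavioural summary table for a whole cohort
#'
#' @param cohort a [build_cohort()] object.
#' @return long data.frame: pid, group, age, condition, n_trials, accuracy,
#'   rt_mean_s.
#' @export
cohort_behavior <- function(cohort) {
  rows <- lapply(seq_len(nrow(cohort$visits)), function(i) {
    v <- cohort$visits[i, ]
    s <- summarize_behavior(cohort$events[[paste0(v$pid, "@", v$age)]])
    cbind(pid = v$pid, group = v$group, age = v$age, s,
          stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Balanced Integration Score
#'
#' BIS integrates standardized accuracy and standardized RT with equal
#' weighting: \eqn{BIS = z(accuracy) - z(RT)}, so higher values mean faster
#' *and* more accurate responding. Z-scores use the sample SD (n - 1) across
#' participants within each standardization stratum (default: age x
#' condition), which makes BIS insensitive to overall speed-accuracy
#' trade-off differences between strata.
#'
#' @param behavior long table from [cohort_behavior()].
#' @param strata character vector of column names defining the
#'   standardization sample.
#' @return `behavior` with a `bis` column appended.
#' @export
compute_bis <- function(behavior, strata = c("age", "condition")) {
  key <- interaction(behavior[strata], drop = TRUE)
  bis <- rep(NA_real_, nrow(behavior))
  for (k in levels(key)) {
    idx <- which(key == k & complete.cases(behavior[c("accuracy", "rt_mean_s")]))
    if (length(idx) < 2) stop("standardization stratum ", k, " has < 2 participants")
    sa <- sd(behavior$accuracy[idx]); sr <- sd(behavior$rt_mean_s[idx])
    if (sa == 0 || sr == 0) stop("zero variance in stratum ", k)
    bis[idx] <- (behavior$accuracy[idx] - mean(behavior$accuracy[idx])) / sa -
      (behavior$rt_mean_s[idx] - mean(behavior$rt_mean_s[idx])) / sr
  }
  behavior$bis <- bis
  behavior
}

#' Assemble the long analysis table
#'
#' Joins behavioural summaries (per participant x age x condition) with
#' cluster-averaged eigenvalues (per participant x age x alignment).
#' Missing visits stay absent (never imputed); id mismatches between the two
#' tables are an error listing the orphan keys.
#'
#' @param behavior table from [compute_bis()].
#' @param eigen_means data.frame: pid, age, alignment, lambda1, lambda2
#'   (cluster means); may be NULL to return behaviour only.
#' @return merged long data.frame with factors coded for modelling
#'   (age as ordered levels 12/16/21, group with NIG reference).
#' @export
build_long_table <- function(behavior, eigen_means = NULL) {
  out <- behavior
  if (!is.null(eigen_means)) {
    bk <- unique(paste0(behavior$pid, "@", behavior$age))
    ek <- unique(paste0(eigen_means$pid, "@", eigen_means$age))
    orphans <- setdiff(ek, bk)
    if (length(orphans))
      stop("eigenvalue table has ids with no behavioural rows: ",
           paste(head(orphans, 5), collapse = ", "))
    out <- merge(behavior, eigen_means, by = c("pid", "age"), all.x = TRUE)
  }
  out$age_f <- factor(out$age, levels = sort(unique(out$age)))
  out$group <- factor(out$group, levels = c("NIG", "FCG", "CAUG"))
  if (!is.null(out$condition)) out$condition <- factor(out$condition)
  out
}
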