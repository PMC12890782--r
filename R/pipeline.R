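#' Pipeline configuration
#'
#' Bundles every tunable of the analysis chain with its default. Unknown
#' keys are rejected so config files cannot silently misspell a parameter.
#'
#' @param generator a [generator_config()].
#' @param min_trials minimum trials per condition cell (ERP and residual
#'   pools).
#' @param window_ms,step_ms AR moving-window parameters.
#' @param min_pairs minimum pooled transition pairs per AR window.
#' @param alpha significance level for FDR-adjusted timewise tests.
#' @param n_boot mediation bootstrap iterations.
#' @return list of class `resdyn_pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(), min_trials = 6,
                            window_ms = 200, step_ms = 25, min_pairs = 50,
                            alpha = 0.05, n_boot = 5000) {
  structure(list(generator = generator, min_trials = min_trials,
                 window_ms = window_ms, step_ms = step_ms,
                 min_pairs = min_pairs, alpha = alpha, n_boot = n_boot),
            class = "resdyn_pipeline_config")
}

#' Write / read a pipeline configuration as JSON
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @export
write_config <- function(config, path) {
  g <- config$generator
  if (is.function(g$eigen_base))
    stop("functional eigen_base trajectories cannot be serialized to JSON")
  plain <- unclass(config)
  plain$generator <- unclass(plain$generator)
  # jsonlite drops names of atomic vectors; keep them via lists
  plain$generator$n_per_group <- as.list(plain$generator$n_per_group)
  plain$generator$eigen_group_offset <- as.list(plain$generator$eigen_group_offset)
  plain$generator$observer$incong_group_offset <-
    as.list(plain$generator$observer$incong_group_offset)
  plain$generator$observer$rt_group_offset <-
    as.list(plain$generator$observer$rt_group_offset)
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known_top <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  g <- raw$generator
  unknown_g <- setdiff(names(g), names(formals(generator_config)))
  if (length(unknown_g)) stop("unknown generator keys: ", paste(unknown_g, collapse = ", "))
  g$n_per_group <- unlist(g$n_per_group)
  g$eigen_group_offset <- unlist(g$eigen_group_offset)
  g$innovation_cov <- matrix(unlist(g$innovation_cov), 2, 2)
  g$observer <- lapply(g$observer, function(v) if (is.list(v)) unlist(v) else v)
  g$erp_templates <- lapply(g$erp_templates, function(cell) {
    if (is.data.frame(cell))     # simplified row-per-bump form
      cell <- lapply(seq_len(nrow(cell)), function(i) as.list(cell[i, ]))
    lapply(cell, function(b) { b$dim <- as.integer(b$dim); b })
  })
  gen <- do.call(generator_config, g)
  args <- raw[setdiff(names(raw), "generator")]
  do.call(pipeline_config, c(list(generator = gen), args))
}

# Pass 2 worker: everything from z-scored epochs to the eigen series of one
# visit. Returns eigen rows plus the recovery error against ground truth.
visit_dynamics <- function(cohort, pid, age, space, config) {
  ep <- simulate_visit_epochs(cohort, pid, age)
  z <- zscore_channels(ep$flanker, ep$response)
  rows <- list()
  for (k in 1:2) {
    lat <- project_trials(z[[k]], space)
    res <- residuals_latent(lat, min_trials = config$min_trials)
    fits <- fit_window_ar(res, config$window_ms, config$step_ms, config$min_pairs)
    es <- eigen_series(fits)
    es$pid <- pid; es$age <- age
    es$group <- cohort$visits$group[cohort$visits$pid == pid][1]
    es$alignment <- z[[k]]$alignment
    rows[[k]] <- es
  }
  do.call(rbind, rows)
}

#' Run the full analysis end to end on a synthetic cohort
#'
#' simulate -> (z-score, ERPs) -> grand PCA state space -> residuals ->
#' moving-window AR(1) eigen series -> behaviour/BIS -> timewise LMEs with
#' FDR -> cluster averaging -> cluster-level LMEs with Bonferroni post hocs
#' -> bootstrap mediation -> ground-truth recovery report. Deterministic
#' given the generator seed. The EEG of each visit is generated on demand
#' from its seed (twice: once for the state-space pass, once for the
#' dynamics pass) so the cohort never sits in memory whole.
#'
#' @param config a [pipeline_config()].
#' @param progress print stage messages.
#' @return results bundle (list) with elements `space`, `explained_var2`,
#'   `eigen_table`, `behavior`, `timewise`, `clusters`, `cluster_means`,
#'   `eigen_fit`, `posthoc`, `bis_fit`, `mediation`, `recovery`, `config`.
#' @export
run_all <- function(config = pipeline_config(), progress = TRUE) {
  say <- function(...) if (progress) message(...)
  cohort <- build_cohort(config$generator)
  vis <- cohort$visits

  say("state-space pass over ", nrow(vis), " visits")
  erp_list <- vector("list", nrow(vis))
  for (i in seq_len(nrow(vis))) {
    ep <- simulate_visit_epochs(cohort, vis$pid[i], vis$age[i])
    z <- zscore_channels(ep$flanker, ep$response)
    erp_list[[i]] <- condition_erps(list(flanker = z[[1]], response = z[[2]]),
                                    min_trials = config$min_trials)
  }
  grand <- build_grand_matrix(erp_list)
  space <- pca_space(grand)
  say(sprintf("PC1+PC2 explained variance: %.1f%%",
              100 * sum(space$explained_var[1:2])))

  say("dynamics pass")
  eig_rows <- vector("list", nrow(vis))
  for (i in seq_len(nrow(vis)))
    eig_rows[[i]] <- visit_dynamics(cohort, vis$pid[i], vis$age[i], space, config)
  eigen_table <- do.call(rbind, eig_rows)

  say("behaviour")
  behavior <- compute_bis(cohort_behavior(cohort))

  say("timewise mixed models")
  timewise <- list()
  clusters <- list()
  cluster_means <- list()
  for (resp in c("lambda1", "lambda2")) {
    tw <- timewise_test(eigen_table, resp, "group_age", alpha = config$alpha)
    timewise[[resp]] <- tw
    for (al in unique(tw$alignment)) for (ef in c("group", "age_f")) {
      sub <- tw[tw$alignment == al & tw$effect == ef, ]
      sub <- sub[order(sub$t_center), ]
      cl <- find_clusters(sub$significant, sub$t_center)
      key <- paste(resp, al, ef, sep = ".")
      clusters[[key]] <- cl
      if (nrow(cl)) {
        top <- cl[cl$longest, ]
        cm <- cluster_average(eigen_table, al, top$t_start, top$t_end)
        cm$response <- resp; cm$effect <- ef
        cluster_means[[key]] <- cm
      }
    }
  }

  # Cluster-level models and post hocs on the group-effect cluster of lambda1
  # (flanker alignment), mirroring the cluster-averaged group comparison.
  say("cluster-level models, post hocs, mediation")
  bis_pa <- aggregate(bis ~ pid + group + age, data = behavior, FUN = mean)
  eigen_fit <- list(); posthoc <- list(); bis_fit <- list(); mediation <- list()
  for (key in names(cluster_means)) {
    cm <- cluster_means[[key]]
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    resp <- parts[1]
    d <- merge(cm, bis_pa, by = c("pid", "group", "age"))
    d$age_f <- factor(d$age)
    d$group <- factor(d$group, levels = c("NIG", "FCG", "CAUG"))
    d$lambda <- d[[resp]]
    fit <- fit_lme(lambda ~ group * age_f + (1 + age_f | pid), d)
    eigen_fit[[key]] <- fit
    posthoc[[key]] <- list(group = posthoc_contrasts(fit, "group"),
                           age = posthoc_contrasts(fit, "age_f"))
    bis_fit[[key]] <- fit_lme(eigen_bis_formula("lambda"), d)
    med_seed <- cohort$config$seed + 1000L
    mediation[[key]] <- list(
      age = mediate(d$age, d$lambda, d$bis, config$n_boot, seed = med_seed),
      institutionalization = mediate(as.numeric(d$group != "NIG"), d$lambda,
                                     d$bis, config$n_boot, seed = med_seed + 1L))
  }

  recovery <- recovery_report(cohort, eigen_table)
  say(sprintf("ground-truth recovery RMSE (flanker, lambda1): %.3f",
              recovery$rmse_lambda1))
  structure(list(space = space, explained_var2 = sum(space$explained_var[1:2]),
                 eigen_table = eigen_table, behavior = behavior,
                 timewise = timewise, clusters = clusters,
                 cluster_means = cluster_means, eigen_fit = eigen_fit,
                 posthoc = posthoc, bis_fit = bis_fit, mediation = mediation,
                 recovery = recovery, config = config, cohort = cohort),
            class = "resdyn_results")
}

#' Compare estimated eigenvalue series against the generator's ground truth
#'
#' @param cohort the cohort the eigen series came from.
#' @param eigen_table long eigen series table.
#' @return list with per-visit RMSEs and cohort-level summaries.
#' @export
recovery_report <- function(cohort, eigen_table) {
  d <- eigen_table[eigen_table$alignment == "flanker", ]
  keys <- unique(d[c("pid", "age")])
  rmse <- matrix(NA_real_, nrow(keys), 2)
  for (i in seq_len(nrow(keys))) {
    sub <- d[d$pid == keys$pid[i] & d$age == keys$age[i], ]
    sub <- sub[order(sub$t_center), ]
    tr <- true_lambda(cohort, keys$pid[i], keys$age[i], sub$t_center)
    rmse[i, 1] <- sqrt(mean((sub$lambda1 - tr[1, ])^2, na.rm = TRUE))
    rmse[i, 2] <- sqrt(mean((sub$lambda2 - tr[2, ])^2, na.rm = TRUE))
  }
  list(per_visit = cbind(keys, rmse_lambda1 = rmse[, 1], rmse_lambda2 = rmse[, 2]),
       rmse_lambda1 = mean(rmse[, 1], na.rm = TRUE),
       rmse_lambda2 = mean(rmse[, 2], na.rm = TRUE))
}

#' Human-readable summary of a results bundle
#'
#' @param results a [run_all()] bundle.
#' @return character vector of markdown lines (also printed invisibly).
#' @export
report <- function(results) {
  out <- c("# Residual-dynamics analysis report", "",
           sprintf("- Explained variance (PC1+PC2): %.1f%%",
                   100 * results$explained_var2), "")
  out <- c(out, "## Significant time clusters (group / age effects)")
  for (key in names(results$clusters)) {
    cl <- results$clusters[[key]]
    out <- c(out, if (nrow(cl))
      sprintf("- %s: longest cluster %.3f to %.3f s (%d windows)",
              key, cl$t_start[cl$longest], cl$t_end[cl$longest],
              cl$n_points[cl$longest])
      else sprintf("- %s: no clusters", key))
  }
  out <- c(out, "", "## Mediation (indirect effects a x b)")
  for (key in names(results$mediation)) for (nm in names(results$mediation[[key]])) {
    md <- results$mediation[[key]][[nm]]
    out <- c(out, sprintf("- %s, x = %s: ab = %.4f [%.4f, %.4f]",
                          key, nm, md$estimates["ab"],
                          md$ci["ab", 1], md$ci["ab", 2]))
  }
  if (!is.null(results$recovery))
    out <- c(out, "", "## Ground-truth recovery",
             sprintf("- mean RMSE lambda1: %.3f; lambda2: %.3f",
                     results$recovery$rmse_lambda1, results$recovery$rmse_lambda2))
  cat(paste(out, collapse = "\n"), "\n")
  invisible(out)
}
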