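#!/usr/bin/env Rscript
# Inferential stage: time-resolved mixed models on the eigenvalue series
# (Group x Age, random intercept per participant with the documented
# fallback), Benjamini-Hochberg FDR over time within each effect x
# alignment, contiguous significant clusters, cluster-averaged eigenvalues,
# Bonferroni post hocs, the eigenvalue-BIS coupling model, and bootstrap
# mediation (age -> eigenvalue -> BIS; institutionalization -> eigenvalue ->
# BIS) with BCa intervals.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_common.R"))

cfg <- study_config()
cohort <- readRDS(res_path("cohort.rds"))
eigen_table <- read_tsv(res_path("eigen_series.tsv"))
behavior <- read_tsv(res_path("behavior_bis.tsv"))
bis_pa <- aggregate(bis ~ pid + group + age, data = behavior, FUN = mean)

all_tw <- list(); all_cl <- list(); med_out <- list(); ph_out <- list()
for (resp in c("lambda1", "lambda2")) {
  message("timewise LME for ", resp)
  tw <- timewise_test(eigen_table, resp, "group_age", alpha = cfg$alpha)
  tw$response <- resp
  all_tw[[resp]] <- tw
  for (al in unique(tw$alignment)) for (ef in c("group", "age_f")) {
    sub <- tw[tw$alignment == al & tw$effect == ef, ]
    sub <- sub[order(sub$t_center), ]
    cl <- find_clusters(sub$significant, sub$t_center)
    if (!nrow(cl)) { message("  no clusters: ", resp, " ", al, " ", ef); next }
    key <- paste(resp, al, ef, sep = ".")
    all_cl[[key]] <- cbind(response = resp, alignment = al, effect = ef, cl)
    top <- cl[cl$longest, ]
    cm <- cluster_average(eigen_table, al, top$t_start, top$t_end)
    d <- merge(cm, bis_pa, by = c("pid", "group", "age"))
    d$age_f <- factor(d$age); d$group <- factor(d$group, c("NIG", "FCG", "CAUG"))
    d$lambda <- d[[resp]]
    fit <- fit_lme(lambda ~ group * age_f + (1 + age_f | pid), d)
    ph <- posthoc_contrasts(fit, "group")
    ph_out[[key]] <- cbind(key = key, ph)
    bisfit <- fit_lme(eigen_bis_formula("lambda"), d)
    bis_beta <- lme4::fixef(bisfit$fit)[["bis"]]
    for (xnm in c("age", "institutionalization")) {
      x <- if (xnm == "age") d$age else as.numeric(d$group != "NIG")
      md <- mediate(x, d$lambda, d$bis, n_boot = cfg$n_boot,
                    seed = cfg$generator$seed + 7L)
      med_out[[paste(key, xnm, sep = ".")]] <- data.frame(
        key = key, exposure = xnm, t(md$estimates),
        ab_lo = md$ci["ab", 1], ab_hi = md$ci["ab", 2])
    }
    message(sprintf("  %s: cluster %.3f..%.3f s; BIS slope %.4f; NIG contrasts p = %s",
                    key, top$t_start, top$t_end, bis_beta,
                    paste(signif(ph$p.value[grepl("NIG", ph$contrast)], 2),
                          collapse = ", ")))
  }
}

write_tsv(do.call(rbind, all_tw), res_path("timewise_tests.tsv"))
write_tsv(do.call(rbind, all_cl), res_path("clusters.tsv"))
write_tsv(do.call(rbind, ph_out), res_path("posthoc_group.tsv"))
write_tsv(do.call(rbind, med_out), res_path("mediation.tsv"))
message("wrote timewise_tests / clusters / posthoc_group / mediation TSVs")
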