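#!/usr/bin/env Rscript
# Build the shared 2D principal-component state space: per-visit z-scored
# epochs -> four condition-cell ERPs x two alignments -> time-concatenated
# grand-average channels x (2 x 4 x 80) matrix -> channel covariance -> PCA.
# The first two components define the space every trial is projected into.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_common.R"))

cfg <- study_config()
cohort <- readRDS(res_path("cohort.rds"))
vis <- cohort$visits

erp_list <- vector("list", nrow(vis))
for (i in seq_len(nrow(vis))) {
  ep <- simulate_visit_epochs(cohort, vis$pid[i], vis$age[i])
  z <- zscore_channels(ep$flanker, ep$response)
  erp_list[[i]] <- condition_erps(list(flanker = z[[1]], response = z[[2]]),
                                  min_trials = cfg$min_trials)
  if (i %% 100 == 0) message("  ", i, "/", nrow(vis), " visits")
}
grand <- build_grand_matrix(erp_list)
space <- pca_space(grand)
print(space)

saveRDS(space, res_path("space.rds"))
write_tsv(data.frame(component = seq_along(space$explained_var),
                     explained_var = space$explained_var,
                     cumulative = cumsum(space$explained_var)),
          res_path("explained_variance.tsv"))
w <- data.frame(channel = space$channel_names, pc1 = space$weights[, 1],
                pc2 = space$weights[, 2])
write_tsv(w, res_path("pc_weights.tsv"))

usable <- colMeans(do.call(rbind, lapply(erp_list, function(e) as.vector(e$usable))))
message(sprintf("PC1+PC2 explain %.2f%% of grand-ERP channel variance; %.0f%% of condition cells usable",
                100 * sum(space$explained_var[1:2]), 100 * mean(usable)))
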