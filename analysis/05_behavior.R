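#!/usr/bin/env Rscript
# Score the behavioural sessions: per-condition accuracy, correct-trial mean
# RT, and the Balanced Integration Score (z(accuracy) - z(RT), standardized
# across participants within age x condition).

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_common.R"))

cohort <- readRDS(res_path("cohort.rds"))
behavior <- compute_bis(cohort_behavior(cohort))
write_tsv(behavior, res_path("behavior_bis.tsv"))

message("accuracy by age x condition:")
print(round(tapply(behavior$accuracy, behavior[c("age", "condition")], mean), 3))
message("correct-trial RT (s) by age:")
print(round(tapply(behavior$rt_mean_s, behavior$age, mean, na.rm = TRUE), 3))
message("incongruent accuracy by group at age 12:")
b12 <- behavior[behavior$age == 12 & behavior$condition == "incongruent", ]
print(round(tapply(b12$accuracy, b12$group, mean), 3))
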