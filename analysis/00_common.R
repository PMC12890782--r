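# Shared setup for the analysis drivers: output locations and the study
# configuration. Pass --small on any driver's command line to run a reduced
# cohort (9 participants) for a quick end-to-end exercise.

suppressMessages(library(resdyn))

res_dir <- "results"
dir.create(res_dir, showWarnings = FALSE)

small <- "--small" %in% commandArgs(trailingOnly = TRUE)
study_config <- function() {
  gen <- if (small)
    generator_config(n_per_group = c(NIG = 3, FCG = 3, CAUG = 3), seed = 20240901)
  else generator_config(seed = 20240901)
  pipeline_config(generator = gen, n_boot = 5000)
}

res_path <- function(...) file.path(res_dir, ...)
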