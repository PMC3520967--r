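#!/usr/bin/env Rscript

# Stage 3: the same three-analysis workflow on the heterogeneous-
# subpopulations survey, where each detection method misses a different
# segment of the population. Outputs under results/heterogeneous_subpopulations/.

library(multinmix)

data_dir <- "results/data/heterogeneous_subpopulations"
out_dir <- "results/heterogeneous_subpopulations"
logfile <- "results/run.log"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

source("analysis/fit_common.R")
fit_scenario(data_dir, out_dir, logfile, seed = 20260903L)
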