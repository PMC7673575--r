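#!/usr/bin/env Rscript
# Stage 5: error-trial analysis -- do target-selective cells follow the
# position the animal chose or the instructed correct position on error
# trials?  Partial correlations of error-trial rates with the
# correct-trial templates of the chosen (X) vs missed (Y) positions.

suppressPackageStartupMessages(library(cmpunit))
cfg <- load_config("analysis/config.yaml")
ses <- load_session("results/session")
scr <- read.csv("results/selectivity.csv")

target_sel <- scr$neuron_id[scr$target & scr$included]
ep <- error_population(ses, target_sel,
                       min_errors = cfg$analysis$min_errors)
if (!is.null(ep$per_neuron)) {
  write.csv(ep$per_neuron, "results/error_analysis.csv", row.names = FALSE)
  cat(sprintf("Error analysis over %d target-selective neurons with >= %d error trials:\n",
              nrow(ep$per_neuron), cfg$analysis$min_errors))
  cat(sprintf("  median partial r: choice %.2f vs correct position %.2f (signed-rank p = %.2g).\n",
              ep$median_choice, ep$median_correct, ep$p))
} else cat("No neuron qualified for the error analysis.\n")
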