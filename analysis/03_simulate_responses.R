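#!/usr/bin/env Rscript
# Step 3 -- behavioural simulation.
#
# Simulates the full two-version cohort (81 simple + 51 challenging
# participants, orders counterbalanced by alternation) through the
# equal-variance SDT observer with the packaged default condition
# sensitivities, and writes the trial-level response log.

library(voicelearn)

seed <- 20260926L
out_dir <- "results/study"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

config <- generative_config()
sim <- simulate_study(config, seed = seed)
write_response_log(sim$log, file.path(out_dir, "response_log.csv"))
write_generative_config(config, file.path(out_dir, "config.yaml"))

cat(sprintf("simulated %d participants, %d answered trials\n",
            length(unique(sim$log$participant_id)), nrow(sim$log)))
print(table(sim$log$version, sim$log$trial_type))
cat(sprintf("written under %s\n", out_dir))
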