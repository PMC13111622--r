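#!/usr/bin/env Rscript
# Step 5 -- mixed-effects models of recognition sensitivity.
#
# Fits the additive model
#   dprime ~ awareness + load + phase + (1 | participant)
# by maximum likelihood with Satterthwaite p-values, plus the full
# three-way interaction model, on the step-4 recognition scores.
# Factor coding makes every term's direction explicit: positive
# `awarenessimplicit` = implicit advantage; positive `loadsimple` =
# simple (low-load) advantage.

library(voicelearn)

out_dir <- "results/models"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
rec <- utils::read.csv("results/analysis/recognition_scores.csv",
                       stringsAsFactors = FALSE)
md <- prepare_model_data(rec)

cat("== Additive model ==\n")
fit <- suppressMessages(fit_lmm(md))
print(fit)
utils::write.csv(fit$terms, file.path(out_dir, "additive_terms.csv"),
                 row.names = FALSE)
jsonlite::write_json(list(terms = fit$terms, varcorr = fit$varcorr,
                          singular = fit$singular, p_method = fit$p_method),
                     file.path(out_dir, "additive_fit.json"),
                     auto_unbox = TRUE, digits = NA)

cat("\n== Interaction model (three-way factorial) ==\n")
fit_x <- suppressMessages(suppressWarnings(fit_lmm(md, interactions = TRUE)))
print(fit_x)
utils::write.csv(fit_x$terms, file.path(out_dir, "interaction_terms.csv"),
                 row.names = FALSE)
cat(sprintf("\nwritten under %s\n", out_dir))
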