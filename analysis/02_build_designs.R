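#!/usr/bin/env Rscript
# Step 2 -- counterbalanced experiment plans.
#
# Builds the two-phase plans (exposure + old-new recognition) for both
# versions and both task orders from the step-1 assignments, and checks
# the structural counts: 60 discrimination trials and 60 recognition
# trials in the challenging version, 24 recognition trials in the
# simple version, 8 exposure appearances and 12 distinct snippets per
# voice, no snippet reused anywhere in a plan.

library(voicelearn)

seed <- 20260926L
out_dir <- "results/designs"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

for (version in c("simple", "challenging")) {
  asg <- utils::read.csv(sprintf("results/selection/assignment_%s.csv",
                                 version), stringsAsFactors = FALSE)
  for (ord in c("IE", "EI")) {
    plan <- build_plan(asg, version, ord, seed = derive_seed(seed, 200L))
    stopifnot(anyDuplicated(plan_snippets(plan)) == 0)
    write_plan(plan,
      json_path = file.path(out_dir, sprintf("plan_%s_%s.json", version, ord)),
      csv_stem = file.path(out_dir, sprintf("plan_%s_%s", version, ord)))
    disc_ph <- which(vapply(plan$phases, function(p) p$task == "implicit",
                            logical(1)))
    n_disc <- nrow(plan$phases[[disc_ph]]$exposure)
    n_rec <- nrow(plan$phases[[1]]$recognition)
    cat(sprintf("%s %s: %d discrimination trials, %d recognition trials per phase\n",
                version, ord, n_disc, n_rec))
  }
}
cat(sprintf("written under %s\n", out_dir))
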